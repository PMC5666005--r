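## Subclone trees under the sum rule.
##
## A structure at one timepoint is a forest over the mutation clusters,
## rooted at a "normal" root of CCF 1, in which the children of every node
## have CCFs summing to at most the node's own CCF (plus a noise tolerance).
## All valid structures are enumerated; structures at successive timepoints
## are merged into longitudinal histories under the evolutionary consistency
## rule that ancestry, once established, is permanent.

#' Enumerate all subclone structures consistent with the sum rule
#'
#' Exhaustively enumerates parent assignments of the clusters (each cluster
#' attaches to the root or to another cluster) such that at every node the
#' children's CCFs sum to at most the parent's CCF + `tolerance`. An edge
#' from a parent with CCF below the child's CCF - `tolerance` is impossible
#' and is pruned. Returned trees are annotated with the total sum-rule
#' residual and sorted by residual, then by depth (shallower first).
#'
#' @param ccf named numeric vector of cluster CCFs at one timepoint, each in
#'   [0, 1].
#' @param tolerance sum-rule slack in CCF units (default 0.05; read noise at
#'   60x depth demands some).
#' @param max_clusters guard on the exhaustive enumeration.
#' @return list of trees; each tree is a list with `parent` (named character
#'   vector, cluster -> parent cluster or `"root"`), `ccf`, `residual`,
#'   and `depth`.
#' @export
enumerate_structures <- function(ccf, tolerance = 0.05, max_clusters = 12L) {
  stopifnot(all(ccf >= 0 & ccf <= 1))
  n <- length(ccf)
  if (n > max_clusters)
    stop("more than ", max_clusters,
         " clusters: pre-merge clusters before enumeration", call. = FALSE)
  ids <- names(ccf) %||% paste0("C", seq_len(n))
  names(ccf) <- ids
  if (n == 0L) return(list())
  ord <- order(-ccf)
  results <- list()
  parent <- integer(n)          # 0 = root, else cluster index
  child_sum <- numeric(n + 1L)  # index 1 = root, 1 + i = cluster i
  node_ccf <- c(1, unname(ccf))
  recurse <- function(k) {
    if (k > n) {
      results[[length(results) + 1L]] <<- parent
      return(invisible())
    }
    i <- ord[k]
    for (j in c(0L, setdiff(seq_len(n), i))) {
      if (j > 0L && ccf[j] < ccf[i] - tolerance - 1e-9) next
      anc <- j
      cyc <- FALSE
      while (anc > 0L) {
        if (anc == i) { cyc <- TRUE; break }
        anc <- parent[anc]
      }
      if (cyc) next
      if (child_sum[j + 1L] + ccf[i] > node_ccf[j + 1L] + tolerance + 1e-9) next
      parent[i] <<- j
      child_sum[j + 1L] <<- child_sum[j + 1L] + ccf[i]
      recurse(k + 1L)
      child_sum[j + 1L] <<- child_sum[j + 1L] - ccf[i]
      parent[i] <<- 0L
    }
    invisible()
  }
  recurse(1L)
  trees <- lapply(results, function(p) {
    pa <- setNames(c("root", ids)[p + 1L], ids)
    tree_from_parent(pa, ccf, tolerance)
  })
  res <- vapply(trees, `[[`, numeric(1), "residual")
  dep <- vapply(trees, `[[`, numeric(1), "depth")
  trees[order(res, dep)]
}

tree_from_parent <- function(parent, ccf, tolerance = 0.05) {
  ids <- names(parent)
  depth_of <- function(id) {
    d <- 0L
    while (id != "root") { id <- parent[[id]]; d <- d + 1L }
    d
  }
  depths <- vapply(ids, depth_of, integer(1))
  sums <- tapply(unname(ccf[ids]), factor(unname(parent),
                                          levels = c("root", ids)), sum)
  sums[is.na(sums)] <- 0
  cap <- c(root = 1, ccf)[c("root", ids)]
  residual <- sum(pmax(0, sums - cap))
  list(parent = parent, ccf = ccf, residual = residual,
       depth = if (length(depths)) max(depths) else 0L)
}

#' Check the sum rule for a tree
#'
#' Independent post-hoc check that at every node (including the root, whose
#' CCF is 1) the children's CCFs sum to at most the node's CCF plus
#' `tolerance`.
#'
#' @param tree a tree as returned by [enumerate_structures()].
#' @param tolerance sum-rule slack.
#' @return TRUE/FALSE.
#' @export
validate_tree <- function(tree, tolerance = 0.05) {
  nodes <- c("root", names(tree$parent))
  ccf <- c(root = 1, tree$ccf)
  all(vapply(nodes, function(nd) {
    kids <- names(tree$parent)[tree$parent == nd]
    sum(ccf[kids]) <= ccf[[nd]] + tolerance + 1e-9
  }, logical(1)))
}

tree_ancestor_matrix <- function(parent) {
  ids <- names(parent)
  anc <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (id in ids) {
    p <- parent[[id]]
    while (p != "root") {
      anc[p, id] <- TRUE
      p <- parent[[p]]
    }
  }
  anc  # anc[a, b] TRUE when a is an ancestor of b
}

#' Merge per-timepoint structures into longitudinal histories
#'
#' Considers every combination of one structure per timepoint and keeps the
#' combinations consistent with clonal evolution: ancestry is a permanent
#' property of a lineage, so (i) for any two clusters present in two
#' timepoints' trees the ancestor/descendant/unrelated relation must be
#' identical, and (ii) once a cluster is a descendant of another, its
#' ancestor must be present (CCF > 0) at every timepoint where the cluster
#' itself is present. This subsumes the pairwise no-inversion rule.
#'
#' @param structures list over timepoints; each element a list of trees
#'   from [enumerate_structures()] for the clusters present then.
#' @return list of consistent histories, each a list with `trees` (one per
#'   timepoint) and `choice` (structure index per timepoint). When no
#'   combination is consistent the empty list carries a `conflicts`
#'   attribute describing a failing pair for each combination examined.
#' @export
merge_timepoints <- function(structures) {
  stopifnot(length(structures) >= 1L)
  if (any(lengths(structures) == 0L))
    stop("every timepoint needs at least one valid structure", call. = FALSE)
  if (length(structures) == 1L)
    return(lapply(seq_along(structures[[1]]), function(i)
      list(trees = structures[[1]][i], choice = i)))
  combos <- expand.grid(lapply(structures, seq_along))
  histories <- list()
  conflicts <- character(0)
  anc_cache <- lapply(structures, function(tr)
    lapply(tr, function(t) tree_ancestor_matrix(t$parent)))
  for (r in seq_len(nrow(combos))) {
    choice <- as.integer(combos[r, ])
    ok <- TRUE
    why <- NULL
    for (t1 in seq_along(structures)) {
      for (t2 in seq_along(structures)) {
        if (t2 <= t1) next
        a1 <- anc_cache[[t1]][[choice[t1]]]
        a2 <- anc_cache[[t2]][[choice[t2]]]
        shared <- intersect(rownames(a1), rownames(a2))
        if (length(shared) >= 2L &&
            !identical(a1[shared, shared], a2[shared, shared])) {
          ok <- FALSE
          why <- sprintf("timepoints %d/%d: ancestry relation changes", t1, t2)
          break
        }
        # an ancestor must accompany its descendant wherever it is present
        for (b in shared) {
          anc_b <- rownames(a1)[a1[, b]]
          missing <- setdiff(anc_b, rownames(a2))
          if (length(missing) > 0L) {
            ok <- FALSE
            why <- sprintf(
              "timepoints %d/%d: %s present without its ancestor %s",
              t1, t2, b, missing[1])
            break
          }
        }
        for (b in shared) {
          anc_b2 <- rownames(a2)[a2[, b]]
          missing <- setdiff(anc_b2, rownames(a1))
          if (length(missing) > 0L) {
            ok <- FALSE
            why <- sprintf(
              "timepoints %d/%d: %s present without its ancestor %s",
              t2, t1, b, missing[1])
            break
          }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) {
      histories[[length(histories) + 1L]] <- list(
        trees = Map(function(tr, i) tr[[i]], structures, choice),
        choice = choice)
    } else conflicts <- c(conflicts, why)
  }
  if (length(histories) == 0L) attr(histories, "conflicts") <- conflicts
  histories
}

#' Per-timepoint structure enumeration from a cluster CCF matrix
#'
#' Enumerates the sum-rule-consistent structures at each timepoint over the
#' clusters present there (CCF > 0), preserving cluster identities, ready
#' for [merge_timepoints()].
#'
#' @param ccf clusters x timepoints CCF matrix (e.g. `cluster_ccfs()$ccf`).
#' @param tolerance sum-rule slack.
#' @param max_clusters per-timepoint enumeration bound.
#' @return list over timepoints of structure lists.
#' @export
timepoint_structures <- function(ccf, tolerance = 0.05, max_clusters = 12L) {
  lapply(seq_len(ncol(ccf)), function(t) {
    present <- ccf[, t] > 0
    enumerate_structures(setNames(ccf[present, t], rownames(ccf)[present]),
                         tolerance = tolerance, max_clusters = max_clusters)
  })
}
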