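## Single-cell pathway phenotype screening.
##
## Each cell is scored against a gene-set collection by ssGSEA: genes are
## ranked by expression, and the enrichment score is the integrated
## difference between the weighted in-set and uniform out-of-set running
## ECDFs. Scores are then screened across conditions by t-test (2 groups)
## or one-way ANOVA (>2), with no multiple-testing adjustment -- ranks of
## -log10 p carry the signal, with attention on the most significant tail.

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each cell, genes are sorted by decreasing expression (ties broken by
#' stable gene order) and assigned rank weights `r = N..1`. Walking down
#' the sorted list, the in-set running sum steps up by `r^tau` normalized
#' over in-set genes, the out-of-set sum steps up by `1/(N - n_set)`; the
#' enrichment score is the sum over all positions of their difference.
#' Scores depend on expression only through ranks, so any strictly
#' increasing per-cell transform leaves them unchanged.
#'
#' @param expr genes x cells non-negative expression matrix (TPM), gene
#'   rownames.
#' @param gene_sets a `gene_set_collection` or named list of gene vectors.
#' @param tau rank-weight exponent (default 0.25).
#' @param min_overlap sets overlapping the gene universe by fewer genes are
#'   skipped (recorded in `attr(, "skipped")`).
#' @param normalize when TRUE, scores are min-max normalized across the
#'   whole matrix (display convention; off by default so tests compare raw
#'   scores).
#' @return sets x cells numeric matrix of enrichment scores.
#' @export
ssgsea <- function(expr, gene_sets, tau = 0.25, min_overlap = 5,
                   normalize = FALSE) {
  N <- nrow(expr)
  if (N < 2L) stop("need at least 2 genes", call. = FALSE)
  universe <- rownames(expr)
  overlap <- lapply(gene_sets, function(g) which(universe %in% g))
  skipped <- names(gene_sets)[lengths(overlap) < min_overlap]
  keep <- setdiff(names(gene_sets), skipped)
  if (length(keep) == 0L) stop("no gene set overlaps the expression matrix",
                               call. = FALSE)
  rank_val <- N:1                      # weight of sorted positions
  w <- abs(rank_val)^tau
  v <- N:1                             # tail length at each position
  total_v <- N * (N + 1) / 2
  es <- matrix(NA_real_, length(keep), ncol(expr),
               dimnames = list(keep, colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(expr[, j], decreasing = TRUE)  # stable: ties keep gene order
    pos_of <- integer(N)
    pos_of[ord] <- seq_len(N)
    for (snm in keep) {
      i <- pos_of[overlap[[snm]]]
      n_set <- length(i)
      # ES = sum_p [P_in(p) - P_out(p)]; each term a_i enters N - i + 1 sums
      es[snm, j] <- sum(w[i] * v[i]) / sum(w[i]) -
        (total_v - sum(v[i])) / (N - n_set)
    }
  }
  if (normalize) es <- (es - min(es)) / (max(es) - min(es))
  attr(es, "skipped") <- skipped
  es
}

#' Screen gene sets for group differences in enrichment scores
#'
#' Per gene set, compares scores between groups by two-tailed Student's
#' t-test (2 groups) or one-way ANOVA (more). P-values are not adjusted for
#' multiple comparisons; instead ranks are reported with the plotting
#' convention that the most significant set gets the highest rank, and the
#' lowest-5% band is flagged.
#'
#' @param scores sets x cells matrix (e.g. from [ssgsea()]).
#' @param groups factor/character of group labels, one per cell.
#' @return data.frame of class `screen_result`: per set `statistic`, `p`,
#'   `neg_log10_p`, `rank` (higher = more significant), `top5` flag, and
#'   group means. Sets where a group has < 2 cells get NA and are flagged.
#' @export
screen <- function(scores, groups) {
  groups <- factor(groups)
  if (ncol(scores) != length(groups))
    stop("one group label per cell is required", call. = FALSE)
  sizes <- table(groups)
  degenerate <- any(sizes < 2L)
  if (degenerate) warning("group(s) with fewer than 2 cells: results NA")
  one_set <- function(y) {
    if (degenerate) return(c(statistic = NA_real_, p = NA_real_))
    if (nlevels(groups) == 2L) {
      a <- y[groups == levels(groups)[1]]
      b <- y[groups == levels(groups)[2]]
      if (mean(a) == mean(b) && (sd(a) == 0 || sd(b) == 0))
        return(c(statistic = 0, p = 1))
      tt <- t.test(a, b, var.equal = TRUE)
      c(statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      if (all(tapply(y, groups, function(v) sd(v) == 0)) &&
          length(unique(tapply(y, groups, mean))) == 1L)
        return(c(statistic = 0, p = 1))
      ow <- oneway.test(y ~ groups, var.equal = TRUE)
      c(statistic = unname(ow$statistic), p = ow$p.value)
    }
  }
  res <- t(apply(scores, 1L, one_set))
  means <- t(apply(scores, 1L, tapply, groups, mean))
  colnames(means) <- paste0("mean_", colnames(means))
  p <- res[, "p"]
  rnk <- rep(NA_real_, length(p))
  rnk[!is.na(p)] <- rank(-p[!is.na(p)], ties.method = "first")
  out <- data.frame(gene_set = rownames(scores) %||%
                      paste0("set", seq_len(nrow(scores))),
                    statistic = res[, "statistic"], p = p,
                    neg_log10_p = -log10(p), rank = rnk,
                    top5 = !is.na(rnk) & rnk > (1 - 0.05) * sum(!is.na(p)),
                    means, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Compare expressing-cell fractions between groups
#'
#' The fraction of cells with expression above `detect_threshold` is
#' compared between two groups by the pooled two-proportion z test
#' ([two_proportion_test()]).
#'
#' @param expr genes x cells expression matrix.
#' @param gene gene to test (must be a rowname of `expr`).
#' @param groups two-level factor/character, one label per cell.
#' @param detect_threshold expression strictly above this counts as
#'   expressing (default 0, i.e. any nonzero TPM).
#' @return list with per-group `fraction`, `n`, and the test's `z`, `p`,
#'   `log10_p`.
#' @export
expressing_fraction_test <- function(expr, gene, groups,
                                     detect_threshold = 0) {
  if (!gene %in% rownames(expr))
    stop("gene not in expression matrix: ", gene, call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required",
                                  call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  expressing <- expr[gene, ] > detect_threshold
  x <- tapply(expressing, groups, sum)
  n <- tapply(expressing, groups, length)
  test <- two_proportion_test(unname(x[1]), unname(n[1]),
                              unname(x[2]), unname(n[2]))
  list(fraction = x / n, n = n, z = test$z, p = test$p,
       log10_p = test$log10_p)
}

#' Center enrichment scores on a baseline group
#'
#' Subtracts, per gene set, the mean score of the baseline (e.g.
#' pre-treatment) cells, so baseline cells average 0 and other groups show
#' their shift directly.
#'
#' @param scores sets x cells matrix.
#' @param groups label per cell.
#' @param baseline the baseline group label.
#' @return centered matrix of the same shape.
#' @export
relative_scores <- function(scores, groups, baseline) {
  idx <- groups == baseline
  if (!any(idx)) stop("baseline group is empty", call. = FALSE)
  sweep(scores, 1L, rowMeans(scores[, idx, drop = FALSE]))
}

#' Log2 fold changes from a baseline sample with a shared pseudo-count
#'
#' The pseudo-count is the minimum nonzero expression over the gene list
#' (all samples); the fold change of gene g in sample s is
#' `log2((x_gs + pc) / (x_g,baseline + pc))`, finite even for zero
#' baselines.
#'
#' @param expr genes x samples expression matrix.
#' @param baseline baseline sample (column) name.
#' @param genes gene list (rownames of `expr`).
#' @return genes x samples matrix of log2 fold changes.
#' @export
log2fc_from_baseline <- function(expr, baseline, genes) {
  if (!baseline %in% colnames(expr))
    stop("baseline sample not in matrix: ", baseline, call. = FALSE)
  x <- expr[genes, , drop = FALSE]
  nz <- x[x > 0]
  if (length(nz) == 0L) stop("gene list has no nonzero expression",
                             call. = FALSE)
  pc <- min(nz)
  log2(sweep(x + pc, 1L, x[, baseline] + pc, "/"))
}
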