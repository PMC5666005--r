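## Mutation clusters and cancer cell fractions.
##
## Copy-neutral somatic variants are grouped by the timepoints in which they
## are present (VAF >= 0.05); each cluster's per-timepoint consensus VAF is
## the mode of a Gaussian KDE, and CCF = ploidy factor x consensus VAF,
## capped at 1.

#' Keep somatic variants by germline-VAF filter
#'
#' Retains variants whose germline VAF is strictly below `germline_max`
#' (default 0.001), removing residual germline polymorphisms.
#'
#' @param variants a `variant_table` with `germline_vaf` populated.
#' @param germline_max exclusive upper bound on germline VAF.
#' @return filtered `variant_table`.
#' @export
filter_somatic <- function(variants, germline_max = 0.001) {
  if (all(is.na(variants$germline_vaf)))
    stop("germline_vaf is not populated", call. = FALSE)
  keep <- !is.na(variants$germline_vaf) &
    variants$germline_vaf < germline_max
  variants[keep, , drop = FALSE]
}

#' Keep variants at copy-neutral loci
#'
#' Copy-neutral means locus absolute copy in [1.5, 2.5] for a diploid
#' genome, or [3.6, 4.4] for a pseudo-tetraploid (genome-doubled) one;
#' bounds inclusive.
#'
#' @param variants a `variant_table` with `locus_copy` populated.
#' @param ploidy_mode `"diploid"` or `"tetraploid"`.
#' @return filtered `variant_table`.
#' @export
filter_copy_neutral <- function(variants,
                                ploidy_mode = c("diploid", "tetraploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  bounds <- if (ploidy_mode == "diploid") c(1.5, 2.5) else c(3.6, 4.4)
  keep <- !is.na(variants$locus_copy) &
    variants$locus_copy >= bounds[1] & variants$locus_copy <= bounds[2]
  variants[keep, , drop = FALSE]
}

ploidy_factor <- function(ploidy_mode = c("diploid", "tetraploid")) {
  if (match.arg(ploidy_mode) == "diploid") 2 else 4
}

#' Cluster variants by cross-timepoint presence pattern
#'
#' A variant is present at a timepoint when its VAF there is at least
#' `presence_threshold`. One cluster is formed per distinct presence
#' pattern; clusters are ranked by size and those with fewer than
#' `min_cluster_size` members are reported but marked not retained (they are
#' excluded from tree building). Variants absent everywhere are dropped.
#'
#' @param variants a `variant_table`; the `adj_vaf` column is used when
#'   present, otherwise `raw_vaf`.
#' @param presence_threshold minimum VAF to count as present (inclusive).
#' @param min_cluster_size minimum members for a cluster to enter trees.
#' @return object of class `mutation_clusters`: list with `clusters`
#'   (data.frame: cluster_id, pattern, n, retained), `membership`
#'   (variant_id -> cluster_id), `vaf` (variant x timepoint matrix), and
#'   `samples`.
#' @export
cluster_by_presence <- function(variants, presence_threshold = 0.05,
                                min_cluster_size = 20) {
  vaf_col <- if ("adj_vaf" %in% names(variants)) "adj_vaf" else "raw_vaf"
  samples <- unique(variants$sample)
  vids <- unique(variants$variant_id)
  vaf <- matrix(NA_real_, length(vids), length(samples),
                dimnames = list(vids, samples))
  vaf[cbind(match(variants$variant_id, vids),
            match(variants$sample, samples))] <- variants[[vaf_col]]
  if (length(vids) == 0L)
    return(structure(list(clusters = data.frame(cluster_id = character(0),
                                                pattern = character(0),
                                                n = integer(0),
                                                retained = logical(0)),
                          membership = character(0), vaf = vaf,
                          samples = samples),
                     class = "mutation_clusters"))
  present <- !is.na(vaf) & vaf >= presence_threshold
  pattern <- apply(present, 1L, function(p) paste(as.integer(p),
                                                  collapse = ""))
  keep <- rowSums(present) > 0L
  pattern <- pattern[keep]
  tab <- sort(table(pattern), decreasing = TRUE)
  clusters <- data.frame(cluster_id = paste0("C", seq_along(tab)),
                         pattern = names(tab), n = as.integer(tab),
                         retained = as.integer(tab) >= min_cluster_size,
                         stringsAsFactors = FALSE)
  membership <- setNames(
    clusters$cluster_id[match(pattern, clusters$pattern)], names(pattern))
  structure(list(clusters = clusters, membership = membership,
                 vaf = vaf[keep, , drop = FALSE], samples = samples),
            class = "mutation_clusters")
}

#' Consensus VAF of a mutation cluster at one timepoint
#'
#' The mode of a Gaussian KDE (Silverman bandwidth, 0.005-spaced grid over
#' [0, 1]) of the member VAFs. Any secondary local maximum whose density
#' reaches 50% of the global maximum is flagged: two peaks indicate
#' sub-clusters and possibly additional subclones. With fewer than 3
#' members the median is returned with a warning.
#'
#' @param vafs member VAFs at one timepoint, in [0, 1].
#' @return list with `mode`, `secondary` (logical flag), and
#'   `secondary_peaks` (locations of flagged secondary maxima).
#' @export
consensus_vaf <- function(vafs) {
  vafs <- vafs[!is.na(vafs)]
  if (any(vafs < 0 | vafs > 1)) stop("VAFs must lie in [0, 1]",
                                     call. = FALSE)
  if (length(vafs) < 3L) {
    warning("fewer than 3 members; falling back to the median VAF")
    return(list(mode = median(vafs), secondary = FALSE,
                secondary_peaks = numeric(0)))
  }
  peaks <- kde_peaks(vafs, from = 0, to = 1, by = 0.005)
  secondary <- peaks[-1, , drop = FALSE]
  secondary <- secondary[secondary$density >= 0.5 * peaks$density[1], ,
                         drop = FALSE]
  list(mode = peaks$location[1], secondary = nrow(secondary) > 0L,
       secondary_peaks = secondary$location)
}

#' Cancer cell fraction from a consensus VAF
#'
#' For copy-neutral heterozygous mutations, CCF = f x VAF with ploidy
#' factor f = 2 (diploid) or 4 (pseudo-tetraploid), capped at 1.
#'
#' @param v consensus VAF in [0, 1] (adjusted scale).
#' @param ploidy_mode `"diploid"` or `"tetraploid"`.
#' @return CCF in [0, 1].
#' @export
ccf_from_vaf <- function(v, ploidy_mode = c("diploid", "tetraploid")) {
  stopifnot(all(v >= 0 & v <= 1, na.rm = TRUE))
  pmin(ploidy_factor(ploidy_mode) * v, 1)  # first arg keeps dim/names
}

#' Cancer cell fraction from a copy-number alteration
#'
#' The fraction of cancer cells carrying a CNA follows from the bulk mean
#' copy of the region: a mean of 2.5 over a region that is 2 copies in
#' non-carriers and 3 in carriers implies 50% carriers. Computed as
#' `(mean_copy - base_copy) / (altered_copy - base_copy)`, clipped to
#' [0, 1].
#'
#' @param mean_copy observed mean absolute copy of the region.
#' @param base_copy copy state of cells without the alteration.
#' @param altered_copy copy state of carrier cells.
#' @param tolerance how far outside [base, altered] the mean may fall
#'   before it is an error rather than clipped.
#' @return CCF in [0, 1].
#' @export
ccf_from_cna <- function(mean_copy, base_copy, altered_copy,
                         tolerance = 0.25) {
  if (any(altered_copy == base_copy))
    stop("degenerate region: altered and base copy are equal",
         call. = FALSE)
  lo <- pmin(base_copy, altered_copy) - tolerance
  hi <- pmax(base_copy, altered_copy) + tolerance
  if (any(mean_copy < lo | mean_copy > hi))
    stop("mean copy is not between the base and altered states",
         call. = FALSE)
  pmin(1, pmax(0, (mean_copy - base_copy) / (altered_copy - base_copy)))
}

#' Consensus VAFs and CCFs for all clusters
#'
#' Runs [consensus_vaf()] per retained cluster and timepoint where the
#' cluster is present (absent timepoints get VAF 0) and converts to CCF via
#' [ccf_from_vaf()]. A per-cluster CCF override (e.g. from an index
#' resistance mutation or from [ccf_from_cna()]) may be supplied for
#' timepoints where the KDE consensus is unreliable.
#'
#' @param clusters a `mutation_clusters` object.
#' @param ploidy_mode `"diploid"` or `"tetraploid"`.
#' @param override optional named list: cluster_id -> numeric vector of
#'   per-timepoint CCFs (NA entries keep the computed value).
#' @return list with matrices `vaf` and `ccf` (retained clusters x
#'   timepoints) and logical matrix `secondary`.
#' @export
cluster_ccfs <- function(clusters, ploidy_mode = c("diploid", "tetraploid"),
                         override = NULL) {
  ploidy_mode <- match.arg(ploidy_mode)
  cl <- clusters$clusters[clusters$clusters$retained, , drop = FALSE]
  samples <- clusters$samples
  vaf <- matrix(0, nrow(cl), length(samples),
                dimnames = list(cl$cluster_id, samples))
  secondary <- matrix(FALSE, nrow(cl), length(samples),
                      dimnames = dimnames(vaf))
  for (i in seq_len(nrow(cl))) {
    members <- names(clusters$membership)[clusters$membership ==
                                            cl$cluster_id[i]]
    pat <- as.integer(strsplit(cl$pattern[i], "")[[1]]) == 1L
    for (t in which(pat)) {
      cv <- consensus_vaf(clusters$vaf[members, t])
      vaf[i, t] <- cv$mode
      secondary[i, t] <- cv$secondary
    }
  }
  ccf <- ccf_from_vaf(vaf, ploidy_mode)
  for (id in names(override %||% list())) {
    o <- override[[id]]
    ccf[id, !is.na(o)] <- o[!is.na(o)]
  }
  list(vaf = vaf, ccf = ccf, secondary = secondary)
}

#' Pairwise co-occurrence of mutations across single cells
#'
#' Two-sided Fisher exact test on the 2x2 presence table for every mutation
#' pair in a cell x mutation presence matrix (a mutation is present in a
#' cell when at least one mutant read was observed). Mutations seen in no
#' cell are excluded with a warning.
#'
#' @param presence logical (or 0/1) matrix, cells x mutations, >= 2
#'   mutations.
#' @return data.frame with one row per pair: `mut1`, `mut2`, the 2x2
#'   counts `n11`, `n10`, `n01`, `n00`, and the Fisher `p`.
#' @export
scdna_cooccurrence <- function(presence) {
  presence <- as.matrix(presence) > 0
  if (ncol(presence) < 2L)
    stop("need at least 2 mutations to test co-occurrence", call. = FALSE)
  empty <- colSums(presence) == 0L
  if (any(empty)) {
    warning("mutation(s) observed in zero cells excluded: ",
            paste(colnames(presence)[empty], collapse = ", "))
    presence <- presence[, !empty, drop = FALSE]
    if (ncol(presence) < 2L)
      stop("fewer than 2 testable mutations remain", call. = FALSE)
  }
  muts <- colnames(presence) %||% paste0("M", seq_len(ncol(presence)))
  pairs <- utils::combn(seq_len(ncol(presence)), 2L)
  out <- apply(pairs, 2L, function(ij) {
    a <- presence[, ij[1]]; b <- presence[, ij[2]]
    n11 <- sum(a & b); n10 <- sum(a & !b)
    n01 <- sum(!a & b); n00 <- sum(!a & !b)
    c(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
      p = fisher.test(matrix(c(n11, n10, n01, n00), 2L))$p.value)
  })
  data.frame(mut1 = muts[pairs[1, ]], mut2 = muts[pairs[2, ]],
             t(out), stringsAsFactors = FALSE)
}
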