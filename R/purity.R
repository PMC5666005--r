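## Tumor purity from gene-level absolute copy, by peak matching.
##
## A perfectly pure aneuploid tumor shows copy peaks at integers 1, 2, 3, 4;
## normal contamination collapses the profile toward 2. After centering the
## dominant peak at 2, stretching around the 2-axis by a multiplier m undoes
## the collapse; the m that places the most genes within 0.1 of 1, 3 or 4
## gives purity = 1/m.

#' Convert a log2 copy ratio to absolute copy
#'
#' Absolute copy is `2^(n+1)` where `n` is the log2 fold change from the
#' diploid state (so 0 -> 2 copies, 1 -> 4, -1 -> 1).
#'
#' @param log2_ratio numeric log2 fold change from diploid.
#' @return absolute copy number (same length).
#' @export
copy_from_log2 <- function(log2_ratio) {
  stopifnot(all(is.finite(log2_ratio)))
  2^(log2_ratio + 1)
}

#' Center the 2-copy peak of a copy profile at 2
#'
#' Finds the dominant mode of the gene-level absolute-copy distribution by
#' Gaussian KDE (Silverman bandwidth, 0.01-spaced grid over [0, 8]) and
#' shifts the profile so that mode sits at exactly 2. Ties in peak density
#' are broken toward the peak nearer 2.
#'
#' @param copies numeric vector of gene-level absolute copies (>= 200 genes).
#' @return list with `copies` (shifted profile), `shift`, and `mode`
#'   (the pre-shift peak location).
#' @export
center_two_copy_peak <- function(copies) {
  if (length(copies) < 200L)
    stop("need at least 200 genes to locate the 2-copy peak", call. = FALSE)
  peaks <- kde_peaks(copies, from = 0, to = 8, by = 0.01)
  top <- peaks[peaks$density >= peaks$density[1] - 1e-9, , drop = FALSE]
  mode <- top$location[which.min(abs(top$location - 2))]
  list(copies = copies - (mode - 2), shift = 2 - mode, mode = mode)
}

#' Estimate tumor purity by copy-peak matching
#'
#' Transforms a 2-centered profile as `c' = 2 + m * (c - 2)` over a grid of
#' multipliers and returns the multiplier that maximizes the number of genes
#' falling within `window` of the integer states 1, 3 and 4. Purity is
#' `1 / m`. Ties across the grid resolve to the smallest multiplier (least
#' correction).
#'
#' @param copies 2-centered gene-level absolute copies (see
#'   [center_two_copy_peak()]).
#' @param m_grid multipliers searched; default 1.00-5.00 step 0.01
#'   (purity down to 0.2).
#' @param window match tolerance around the target states.
#' @param targets integer copy states matched against.
#' @return object of class `purity_estimate`: list with `multiplier`,
#'   `purity`, `n_genes_matched`, and the full `grid` (m vs matched count)
#'   for diagnostics.
#' @export
estimate_purity <- function(copies, m_grid = seq(1, 5, by = 0.01),
                            window = 0.1, targets = c(1, 3, 4)) {
  n_aneuploid <- sum(abs(copies - 2) > 0.25)
  if (n_aneuploid < max(10, 0.01 * length(copies)))
    stop("profile has essentially only 2-copy genes; purity indeterminate",
         call. = FALSE)
  dev <- copies - 2
  counts <- vapply(m_grid, function(m) {
    cp <- 2 + m * dev
    d <- abs(cp - targets[1])
    for (k in targets[-1]) d <- pmin(d, abs(cp - k))
    sum(d <= window)
  }, numeric(1))
  best <- which.max(counts)  # first maximum = smallest m on an ascending grid
  structure(list(multiplier = m_grid[best], purity = 1 / m_grid[best],
                 n_genes_matched = counts[best],
                 grid = data.frame(m = m_grid, n_matched = counts)),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("purity estimate: %.3f (multiplier %.2f, %d genes matched)\n",
              x$purity, x$multiplier, x$n_genes_matched))
  invisible(x)
}

#' One-step purity estimation from a raw copy profile
#'
#' Convenience wrapper: centers the 2-copy peak, then runs the multiplier
#' search.
#'
#' @inheritParams estimate_purity
#' @return a `purity_estimate` with the centering `shift` attached.
#' @export
purity_from_copy <- function(copies, m_grid = seq(1, 5, by = 0.01),
                             window = 0.1, targets = c(1, 3, 4)) {
  centered <- center_two_copy_peak(copies)
  est <- estimate_purity(centered$copies, m_grid, window, targets)
  est$shift <- centered$shift
  est
}

#' Adjust a VAF for normal contamination
#'
#' Multiplies the raw variant allele frequency by the sample's multiplier
#' (1 / purity), capping at 1.
#'
#' @param raw_vaf raw VAF in [0, 1].
#' @param m multiplier, >= 1.
#' @return adjusted VAF in [0, 1].
#' @export
adjust_vaf <- function(raw_vaf, m) {
  if (any(raw_vaf < 0 | raw_vaf > 1, na.rm = TRUE))
    stop("raw_vaf outside [0, 1]", call. = FALSE)
  if (any(m < 1)) stop("multiplier must be >= 1", call. = FALSE)
  pmin(1, raw_vaf * m)
}

#' Apply per-sample VAF adjustment to a variant table
#'
#' Adds an `adj_vaf` column; downstream presence clustering and consensus
#' VAFs use it when present.
#'
#' @param variants a `variant_table`.
#' @param multipliers named numeric vector, one multiplier per sample.
#'   Samples left out (e.g. ones the correction is deliberately skipped
#'   for) keep their raw VAF.
#' @return the variant table with `adj_vaf` filled.
#' @export
adjust_variant_vafs <- function(variants, multipliers) {
  m <- multipliers[variants$sample]
  m[is.na(m)] <- 1
  variants$adj_vaf <- adjust_vaf(variants$raw_vaf, m)
  variants
}
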