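## 96-channel mutation spectra, catalog deconvolution, and proportion tests.
##
## Channels follow the standard catalog layout: substitutions C>A, C>G, C>T,
## T>A, T>C, T>G (pyrimidine-centered), each crossed with the 16 flanking-base
## combinations, 5' base varying slowest, both flanks ordered A, C, G, T.

.BASES <- c("A", "C", "G", "T")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Channel labels of the 96 trinucleotide mutation classes
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`, in fixed
#'   catalog order.
#' @export
channel_labels <- function() {
  unlist(lapply(.SUBS, function(s)
    as.vector(t(outer(.BASES, .BASES, function(f5, f3)
      sprintf("%s[%s]%s", f5, s, f3))))))
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical trinucleotide context and channel of an SNV
#'
#' Classifies a single-nucleotide variant into one of the 96 pyrimidine-
#' centered substitution/context channels. When the mutated (reference) base
#' is a purine the whole triplet and the alternate allele are
#' reverse-complemented, so a variant and its opposite-strand representation
#' always land in the same channel.
#'
#' @param ref,alt reference and alternate base (single characters, unequal).
#' @param flank5,flank3 bases immediately 5' and 3' of the variant on the
#'   reference strand.
#' @return list with `context` (e.g. `"ACG"`), `label` (e.g. `"A[C>T]G"`)
#'   and `channel` (integer 1-96). Vectorized over all arguments.
#' @export
trinucleotide_context <- function(ref, alt, flank5, flank3) {
  bases <- c(ref, alt, flank5, flank3)
  if (!all(bases %in% .BASES))
    stop("ambiguous or non-ACGT base in trinucleotide context", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, .COMPLEMENT[ref], ref)
  a <- ifelse(flip, .COMPLEMENT[alt], alt)
  f5 <- ifelse(flip, .COMPLEMENT[flank3], flank5)
  f3 <- ifelse(flip, .COMPLEMENT[flank5], flank3)
  sub <- paste0(r, ">", a)
  label <- sprintf("%s[%s]%s", f5, sub, f3)
  channel <- (match(sub, .SUBS) - 1L) * 16L +
    (match(f5, .BASES) - 1L) * 4L + match(f3, .BASES)
  list(context = paste0(f5, r, f3), label = unname(label),
       channel = unname(channel))
}

#' Build a 96-channel mutation spectrum
#'
#' Counts contexted SNVs per channel. Variants without a channel (indels,
#' uncontexted records) are ignored.
#'
#' @param variants a `variant_table` with `channel96` filled (see
#'   [fetch_context()]), or an integer vector of channels 1-96.
#' @return object of class `mutation_spectrum`: list with integer `counts`
#'   (length 96, named by channel label), `proportions`, and `total`.
#' @export
spectrum <- function(variants) {
  ch <- if (is.data.frame(variants)) {
    unique(variants[, c("variant_id", "channel96")])$channel96
  } else as.integer(variants)
  ch <- ch[!is.na(ch)]
  if (length(ch) == 0L) stop("no contexted SNVs to build a spectrum from",
                             call. = FALSE)
  counts <- tabulate(ch, nbins = 96L)
  names(counts) <- channel_labels()
  structure(list(counts = counts, proportions = counts / sum(counts),
                 total = sum(counts)),
            class = "mutation_spectrum")
}

#' Deconvolve a spectrum against a signature catalog
#'
#' Estimates non-negative signature weights by greedy forward selection: at
#' each iteration the single signature whose weight change most reduces the
#' squared error between the observed channel proportions and the
#' catalog-weighted reconstruction is updated, subject to weights >= 0 and
#' total weight <= 1. Iteration stops when the error improvement falls below
#' `improvement_tol`. Weights below `min_weight` are then zeroed without
#' renormalization; the unassigned remainder is reported as unknown.
#'
#' @param spec a `mutation_spectrum` (or a length-96 non-negative vector).
#' @param catalog numeric matrix, 96 channels x K signatures, each column
#'   summing to 1 (see [simulate_catalog()] for a synthetic example).
#' @param min_weight prune threshold on final weights.
#' @param improvement_tol minimum squared-error improvement to continue.
#' @return object of class `signature_exposure`: list with `weights` (named,
#'   length K), `unknown` (1 - sum of weights), and `error` (sum of squared
#'   channel differences of the pruned reconstruction).
#' @export
deconvolve <- function(spec, catalog, min_weight = 0.06,
                       improvement_tol = 1e-3) {
  s <- if (inherits(spec, "mutation_spectrum")) spec$proportions
       else as.numeric(spec) / sum(spec)
  catalog <- as.matrix(catalog)
  if (ncol(catalog) == 0L) stop("empty signature catalog", call. = FALSE)
  if (nrow(catalog) != 96L) stop("catalog must have 96 channel rows",
                                 call. = FALSE)
  if (any(catalog < 0)) stop("catalog profiles must be non-negative",
                             call. = FALSE)
  if (any(abs(colSums(catalog) - 1) > 1e-6))
    stop("catalog columns must each sum to 1", call. = FALSE)
  if (inherits(spec, "mutation_spectrum") && spec$total < 50)
    warning("spectrum has fewer than 50 mutations; weights will be noisy")
  K <- ncol(catalog)
  w <- setNames(numeric(K), colnames(catalog) %||% paste0("S", seq_len(K)))
  recon <- as.numeric(catalog %*% w)
  err <- sum((s - recon)^2)
  csq <- colSums(catalog^2)
  repeat {
    r <- s - recon
    delta <- as.numeric(crossprod(catalog, r)) / csq
    delta <- pmax(-w, pmin(delta, 1 - sum(w)))  # keep w_k >= 0, sum(w) <= 1
    new_err <- vapply(seq_len(K), function(k)
      sum((r - delta[k] * catalog[, k])^2), numeric(1))
    k <- which.min(new_err)
    if (err - new_err[k] < improvement_tol) break
    w[k] <- w[k] + delta[k]
    recon <- recon + delta[k] * catalog[, k]
    err <- new_err[k]
  }
  w[w < min_weight] <- 0
  recon <- as.numeric(catalog %*% w)
  structure(list(weights = w, unknown = 1 - sum(w),
                 error = sum((s - recon)^2)),
            class = "signature_exposure")
}

#' Fraction of SNVs at APOBEC target motifs
#'
#' The APOBEC3 deaminase family targets cytosines in a TCW motif (W = A or
#' T), producing C>T and C>G changes (the processes behind catalog signatures
#' 2 and 13). This reports the fraction of contexted SNVs whose canonical
#' channel lies in that motif set.
#'
#' @param variants `variant_table` with channels, or integer channel vector.
#' @param motifs channel labels counted as APOBEC-associated; defaults to
#'   the TCW set.
#' @return list with `fraction` (NA when no contexted SNVs), `count`, `total`.
#' @export
apobec_fraction <- function(variants,
                            motifs = c("T[C>T]A", "T[C>T]T",
                                       "T[C>G]A", "T[C>G]T")) {
  ch <- if (is.data.frame(variants)) {
    unique(variants[, c("variant_id", "channel96")])$channel96
  } else as.integer(variants)
  ch <- ch[!is.na(ch)]
  idx <- match(motifs, channel_labels())
  if (anyNA(idx)) stop("unknown motif label", call. = FALSE)
  if (length(ch) == 0L)
    return(list(fraction = NA_real_, count = 0L, total = 0L))
  list(fraction = mean(ch %in% idx), count = sum(ch %in% idx),
       total = length(ch))
}

#' Two-sample proportion test (pooled z, two-tailed)
#'
#' Pooled-variance z statistic without continuity correction, so that
#' z^2 equals the 1-df chi-square statistic. The p-value is computed in log
#' space and remains reportable (via `log10_p`) far below double underflow.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `z`, `p` (two-tailed; 0 if underflowed), and `log10_p`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("successes must lie in [0, n]", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) return(list(z = 0, p = 1, log10_p = 0))
  expected <- c(n1, n2) * pp
  if (min(expected, c(n1, n2) * (1 - pp)) < 5)
    warning("expected cell count below 5; normal approximation is rough")
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  log_p <- log(2) + pnorm(-abs(z), log.p = TRUE)
  list(z = z, p = exp(log_p), log10_p = log_p / log(10))
}
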