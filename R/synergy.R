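## Dose-response normalization, 4PL fitting, and Bliss synergy.
##
## Plates carry a cancer + fibroblast condition and a fibroblast-only
## background; cancer-only signal is the difference, normalized to the
## vehicle (DMSO) mean. Bliss independence is computed on inhibition
## fractions i = 1 - viability/100, where it is a probabilistic
## independence model; viability-space "Bliss" is not.

#' Normalize plate signal to percent viability
#'
#' Per dose d: `100 * (CF_d - mean(F_d)) / (mean(CF_vehicle) -
#' mean(F_vehicle))`, where CF is the cancer + fibroblast signal and F the
#' fibroblast-only background at the matched dose.
#'
#' @param plate a `dose_response_table` (see [read_dose_response()]) with
#'   both conditions.
#' @return data.frame with one row per treated cancer + fibroblast well:
#'   `drug`, `dose`, `replicate`, `viability` (percent of vehicle).
#' @export
normalize_viability <- function(plate) {
  cf <- plate[plate$condition == "cancer+fibroblast", ]
  f <- plate[plate$condition == "fibroblast-only", ]
  if (nrow(cf) == 0L || nrow(f) == 0L)
    stop("plate must contain cancer+fibroblast and fibroblast-only rows",
         call. = FALSE)
  f_mean <- tapply(f$signal, paste(f$drug, f$dose), mean)
  veh_cancer <- mean(cf$signal[cf$dose == 0]) - mean(f$signal[f$dose == 0])
  if (veh_cancer <= 0)
    stop("vehicle cancer-only signal is not positive; cannot normalize",
         call. = FALSE)
  key <- paste(cf$drug, cf$dose)
  if (anyNA(f_mean[key]))
    stop("fibroblast-only background missing for some doses", call. = FALSE)
  data.frame(drug = cf$drug, dose = cf$dose, replicate = cf$replicate,
             viability = 100 * (cf$signal - f_mean[key]) / veh_cancer,
             stringsAsFactors = FALSE, row.names = NULL)
}

## 4PL: viability(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)
four_pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit (Levenberg-Marquardt, initialized from data
#' quantiles, bounds top in [50, 150], bottom in [-10, 60], hill in
#' (0, 10]). The IC50 is reported "unmet" when the fit does not converge,
#' the fitted curve never crosses 50% within the tested range, or the
#' fitted IC50 exceeds the maximum tested dose.
#'
#' @param doses tested doses (>= 4 distinct nonzero values).
#' @param viability normalized percent viability, same length.
#' @return object of class `dose_response_curve`: list with `params`
#'   (top, bottom, ic50, hill), `ic50` (NA when unmet), `unmet` flag,
#'   `note`, and `residuals`.
#' @export
fit_curve <- function(doses, viability) {
  pos <- doses > 0
  d <- doses[pos]
  y <- viability[pos]
  if (length(unique(d)) < 4L)
    stop("need at least 4 distinct nonzero doses", call. = FALSE)
  unmet <- function(note, params = NULL)
    structure(list(params = params, ic50 = NA_real_, unmet = TRUE,
                   note = note, residuals = NULL),
              class = "dose_response_curve")
  means <- tapply(y, d, mean)
  dose_lv <- as.numeric(names(means))
  rho <- suppressWarnings(stats::cor(dose_lv, as.numeric(means),
                                     method = "spearman"))
  if (!is.na(rho) && rho > 0)
    warning("viability increases with dose; no inhibitory response")
  ic50_start <- try(exp(stats::approx(
    x = as.numeric(means), y = log(dose_lv), xout = 50,
    rule = 2, ties = mean)$y), silent = TRUE)
  if (inherits(ic50_start, "try-error") || !is.finite(ic50_start))
    ic50_start <- stats::median(d)
  start <- list(top = min(max(quantile(y, 0.9), 50), 150),
                bottom = max(min(quantile(y, 0.1), 60), -10),
                ic50 = ic50_start,
                hill = 1)
  fit <- try(minpack.lm::nlsLM(
    y ~ four_pl(d, top, bottom, ic50, hill),
    start = start,
    lower = c(top = 50, bottom = -10, ic50 = min(d) / 100, hill = 1e-3),
    upper = c(top = 150, bottom = 60, ic50 = max(d) * 100, hill = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(unmet("fit did not converge"))
  p <- as.list(coef(fit))
  if (p$bottom >= 50 || four_pl(max(d), p$top, p$bottom, p$ic50, p$hill) > 50)
    return(unmet("curve does not cross 50% in the tested range",
                 params = p))
  if (p$ic50 > max(d))
    return(unmet("fitted IC50 exceeds the maximum tested dose", params = p))
  structure(list(params = p, ic50 = p$ic50, unmet = FALSE, note = NULL,
                 residuals = stats::residuals(fit)),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  if (x$unmet) cat("IC50: unmet (", x$note, ")\n", sep = "")
  else cat(sprintf(
    "IC50: %.3g uM (top %.1f%%, bottom %.1f%%, hill %.2f)\n",
    x$ic50, x$params$top, x$params$bottom, x$params$hill))
  invisible(x)
}

#' Bliss-independence expected combination inhibition
#'
#' For single-agent inhibition fractions a and b, the expected combined
#' inhibition under independence is `a + b - a * b`.
#'
#' @param a,b inhibition fractions in [0, 1] (1 - viability/100).
#' @return expected inhibition E in [max(a, b), 1].
#' @export
bliss_expected <- function(a, b) {
  if (any(a < 0 | a > 1 | b < 0 | b > 1))
    stop("inhibition fractions must lie in [0, 1]", call. = FALSE)
  a + b - a * b
}

#' Test combination synergy against the Bliss expectation
#'
#' One-sample two-sided t-test of the observed combination inhibition
#' replicates against the Bliss expectation from the single-agent
#' inhibitions (treated as fixed). The signed excess (observed mean minus
#' expected) is positive for synergy.
#'
#' @param observed combination inhibition fractions, >= 2 replicates.
#' @param a,b single-agent inhibition fractions (means, or per-replicate
#'   vectors when `two_sample = TRUE`).
#' @param two_sample when TRUE, per-replicate expected inhibitions
#'   `bliss_expected(a, b)` are compared with the observed replicates by a
#'   Welch two-sample t-test, propagating single-agent uncertainty instead
#'   of treating the expectation as fixed.
#' @return object of class `synergy_assessment`: list with `expected`,
#'   `observed_mean`, `excess`, `t`, `p`.
#' @export
synergy_test <- function(observed, a, b, two_sample = FALSE) {
  if (length(observed) < 2L) stop("need at least 2 combination replicates",
                                  call. = FALSE)
  if (two_sample) {
    e_reps <- bliss_expected(a, b)
    if (length(e_reps) < 2L)
      stop("two-sample test needs per-replicate single-agent inhibitions",
           call. = FALSE)
    tt <- t.test(observed, e_reps)
    return(structure(list(expected = mean(e_reps),
                          observed_mean = mean(observed),
                          excess = mean(observed) - mean(e_reps),
                          t = unname(tt$statistic), p = tt$p.value),
                     class = "synergy_assessment"))
  }
  e <- bliss_expected(a, b)
  if (sd(observed) == 0) {
    t_stat <- if (mean(observed) == e) 0 else Inf * sign(mean(observed) - e)
    p <- if (mean(observed) == e) 1 else 0
  } else {
    tt <- t.test(observed, mu = e)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(expected = e, observed_mean = mean(observed),
                 excess = mean(observed) - e, t = t_stat, p = p),
            class = "synergy_assessment")
}

#' @export
print.synergy_assessment <- function(x, ...) {
  cat(sprintf(
    "Bliss expected %.3f, observed %.3f (excess %+.3f), t = %.2f, p = %.3g\n",
    x$expected, x$observed_mean, x$excess, x$t, x$p))
  invisible(x)
}
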