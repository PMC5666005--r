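## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian KDE peaks on a fixed evaluation grid
#'
#' Evaluates a Gaussian kernel density (Silverman bandwidth) on an evenly
#' spaced grid and returns all local maxima, sorted by decreasing density.
#' Grid endpoints count as peaks when the density is decreasing away from
#' them, so point masses at a boundary are not lost.
#'
#' @param x numeric observations.
#' @param from,to,by grid limits and step.
#' @return data.frame with columns `location` and `density`, one row per
#'   local maximum, ordered by decreasing density.
#' @keywords internal
kde_peaks <- function(x, from, to, by) {
  stopifnot(length(x) >= 2L)
  bw <- bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-3, by)
  n_grid <- round((to - from) / by) + 1L
  d <- density(x, bw = bw, from = from, to = to, n = n_grid)
  y <- d$y
  n <- length(y)
  is_peak <- c(y[1] > y[2], y[2:(n - 1)] >= y[1:(n - 2)] &
                 y[2:(n - 1)] > y[3:n], y[n] > y[n - 1])
  out <- data.frame(location = d$x[is_peak], density = y[is_peak])
  out[order(-out$density), , drop = FALSE]
}

## centered moving average keeping full windows only; returns NA elsewhere
moving_average <- function(x, w) {
  stopifnot(w %% 2L == 1L, w >= 1L)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

## run code with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}
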