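# Tracer clearance kinetics: baseline adjustment, normalization to the first
# post-injection timepoint, one-phase exponential decay fitting
# (normalized intensity = exp(-k t)), and half-life ln(2)/k.

#' Normalize a tracer time series to tissue enhancement
#'
#' Enhancement is raw intensity minus the pre-injection baseline; normalized
#' intensity is enhancement divided by the enhancement at the first
#' post-injection timepoint, and fitting time is re-origined so that first
#' timepoint is t = 0 (where normalized intensity is 1 by construction).
#'
#' @param raw post-injection intensities.
#' @param baseline pre-injection baseline intensity (scalar).
#' @param timepoints_h post-injection times in hours, strictly increasing.
#' @return a `clearance_series`: data frame `time_h` (original),
#'   `fit_time_h` (re-origined), `raw`, `enhancement`, `normalized`.
#' @export
normalize_series <- function(raw, baseline, timepoints_h) {
  stopifnot(length(raw) == length(timepoints_h), length(baseline) == 1L,
            all(diff(timepoints_h) > 0))
  enh <- raw - baseline
  if (enh[1] <= 0) {
    stop("non-informative series: first post-injection intensity does not exceed baseline")
  }
  out <- data.frame(time_h = timepoints_h,
                    fit_time_h = timepoints_h - timepoints_h[1],
                    raw = raw, enhancement = enh,
                    normalized = enh / enh[1])
  class(out) <- c("clearance_series", class(out))
  out
}

#' Build a clearance series from a generated / recorded table
#'
#' Convenience for tables in the [generate_clearance_series()] layout
#' (`time_h`, `intensity`, `is_baseline`).
#'
#' @param tab data frame with columns time_h, intensity, is_baseline.
#' @return a `clearance_series` (see [normalize_series()]).
#' @export
as_clearance_series <- function(tab) {
  stopifnot(all(c("time_h", "intensity", "is_baseline") %in% names(tab)))
  base <- mean(tab$intensity[tab$is_baseline])
  post <- tab[!tab$is_baseline, , drop = FALSE]
  post <- post[order(post$time_h), , drop = FALSE]
  normalize_series(post$intensity, base, post$time_h)
}

#' Fit a one-phase exponential decay
#'
#' Minimizes `sum((normalized - exp(-k t))^2)` over k by nonlinear least
#' squares, initialized from the log-linear regression slope.  The model is a
#' pure exponential with no plateau; an optional plateau term
#' `c + (1 - c) exp(-k t)` is available behind `plateau = TRUE` but off by
#' default.  If the optimizer fails, the log-linear estimate is returned with
#' `converged = FALSE` and a warning.
#'
#' @param series a `clearance_series` from [normalize_series()].
#' @param plateau include a plateau term (default FALSE).
#' @return a `clearance_fit`: `k` (per hour), `half_life_h`, `rss`,
#'   `converged`, `plateau` (NA unless fitted).
#' @export
fit_decay <- function(series, plateau = FALSE) {
  stopifnot(inherits(series, "clearance_series"))
  t <- series$fit_time_h
  y <- series$normalized
  if (length(t) < 3L) stop("need >= 3 timepoints to fit a decay")
  pos <- y > 0
  k0 <- if (sum(pos) >= 2L) {
    max(-stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[[2]], 1e-6)
  } else 1e-6
  # direct least squares on the normalized scale; Brent for the pure
  # exponential (robust even at zero residual, where nls fails), Nelder-Mead
  # when a plateau is requested
  if (plateau) {
    obj2 <- function(par) sum((y - (par[2] + (1 - par[2]) * exp(-par[1] * t)))^2)
    opt <- tryCatch(stats::optim(c(k0, max(min(y), 0)), obj2), error = function(e) NULL)
    if (is.null(opt)) {
      warning("decay fit did not converge; returning log-linear estimate")
      k <- k0; c0 <- NA_real_; conv <- FALSE
      rss <- sum((y - exp(-k * t))^2)
    } else {
      k <- opt$par[1]; c0 <- opt$par[2]; conv <- opt$convergence == 0L
      rss <- opt$value
    }
  } else {
    obj <- function(k) sum((y - exp(-k * t))^2)
    # coarse log-grid bracket first: the objective flattens for large k, which
    # can strand a golden-section search on the plateau
    grid <- k0 * 2^seq(-7, 7, by = 0.5)
    kb <- grid[which.min(vapply(grid, obj, numeric(1)))]
    opt <- tryCatch(
      stats::optimize(obj, interval = c(kb / 2, kb * 2), tol = 1e-12),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$minimum) || opt$minimum <= 0) {
      warning("decay fit did not converge; returning log-linear estimate")
      k <- k0; conv <- FALSE
    } else {
      k <- opt$minimum; conv <- TRUE
    }
    c0 <- NA_real_
    rss <- obj(k)
  }
  structure(list(k = k, half_life_h = half_life(k), rss = rss,
                 converged = conv, plateau = c0),
            class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat(sprintf("<clearance_fit> k = %.4f /h, half-life = %.3f h (rss %.3g%s)\n",
              x$k, x$half_life_h, x$rss,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Half-life from a decay constant
#'
#' `ln(2) / k`.
#'
#' @param k decay constant in reciprocal hours (> 0).
#' @return half-life in hours.
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("decay constant k must be > 0")
  log(2) / k
}
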