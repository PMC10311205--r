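#' Default FHR modulation bands (cycles/min)
#'
#' Four bands spanning the time scales of accelerations and decelerations:
#' 0--0.1, 0.1--1, 1--3 and 3--7 cycles/min (event durations of roughly
#' 9 s to beyond 10 min).
#' @return a list of length-2 numeric band edges.
#' @export
default_bands <- function() list(c(0, 0.1), c(0.1, 1), c(1, 3), c(3, 7))

#' Stability variables of an FHR series
#'
#' Computes the 8 per-sample predictors of signal stability: the absolute
#' first difference (finite differences, bpm per sample) of the FHR filtered
#' into each of the four modulation bands, and the absolute analytic-signal
#' envelope of each of those derivatives. High derivatives mark the slopes
#' of accelerations/decelerations; the envelope stays high across an entire
#' event, including its trough, which the derivative alone cannot separate
#' from baseline.
#'
#' @param fhr gap-free numeric FHR series (bpm).
#' @param sample_rate Hz (default 4).
#' @param bands list of band edges in cycles/min (default [default_bands()]).
#' @return numeric matrix, `length(fhr)` rows and 8 columns
#'   (`d_band1..d_band4`, `env_band1..env_band4`).
#' @export
stability_variables <- function(fhr, sample_rate = 4, bands = default_bands()) {
  n <- length(fhr)
  out <- matrix(0, n, 2 * length(bands))
  colnames(out) <- c(paste0("d_band", seq_along(bands)),
                     paste0("env_band", seq_along(bands)))
  for (j in seq_along(bands)) {
    b <- bands[[j]]
    xf <- bandpass(fhr, b[1], b[2], sample_rate = sample_rate)
    d <- c(diff(xf), 0)            # forward difference, last sample padded
    d[n] <- d[n - 1]
    out[, j] <- abs(d)
    out[, length(bands) + j] <- abs(analytic_envelope(d))
  }
  out
}

#' Fit the logistic stability model
#'
#' Trains the per-sample logistic model of signal stability on recordings
#' whose accelerations and decelerations are annotated: samples inside an
#' annotated event are the non-stable class, all others stable. Variables
#' are standardised and the fit carries a light ridge penalty so separable
#' training material cannot overflow.
#'
#' @param annotated a list; each element a list with `fhr` (numeric series)
#'   and `stable` (logical series of the same length, `TRUE` outside
#'   annotated events).
#' @param sample_rate Hz.
#' @param bands band edges in cycles/min.
#' @param lambda ridge strength (default 1e-3).
#' @param stride keep every `stride`-th sample when pooling training rows
#'   (default 1 = all samples).
#' @return a `stability_model`: coefficients for the 8 variables plus
#'   intercept, the scaler, and the band edges.
#' @export
fit_stability_model <- function(annotated, sample_rate = 4,
                                bands = default_bands(), lambda = 1e-3,
                                stride = 1L) {
  if (length(annotated) < 2)
    stop("need at least 2 annotated recordings")
  Xs <- list(); ys <- list()
  for (i in seq_along(annotated)) {
    a <- annotated[[i]]
    V <- stability_variables(a$fhr, sample_rate = sample_rate, bands = bands)
    keep <- seq(1, nrow(V), by = stride)
    Xs[[i]] <- V[keep, , drop = FALSE]
    ys[[i]] <- as.numeric(a$stable)[keep]
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  if (length(unique(y)) < 2)
    ctg_error("annotations contain a single stability class",
              "ctg_degenerate_fit_error")
  scaler <- fit_scaler(X)
  fit <- ridge_logistic(apply_scaler(X, scaler), y, lambda = lambda)
  structure(list(intercept = fit$intercept, coef = fit$coef,
                 scaler = scaler, bands = bands, sample_rate = sample_rate,
                 lambda = lambda),
            class = "stability_model")
}

#' @export
print.stability_model <- function(x, ...) {
  cat("<stability_model> logistic, 8 band variables; bands (cycles/min):",
      paste(vapply(x$bands, paste, "", collapse = "-"), collapse = ", "), "\n")
  invisible(x)
}

#' Predict the per-sample probability of stability
#'
#' @param model a `stability_model` (or `NULL` for the uninformative
#'   constant 1).
#' @param fhr gap-free FHR series.
#' @param sample_rate Hz.
#' @return numeric series of probabilities in \[0, 1\], aligned to `fhr`.
#' @export
predict_stability <- function(model, fhr, sample_rate = 4) {
  if (is.null(model)) return(rep(1, length(fhr)))
  stopifnot(inherits(model, "stability_model"))
  V <- stability_variables(fhr, sample_rate = sample_rate, bands = model$bands)
  eta <- model$intercept + drop(apply_scaler(V, model$scaler) %*% model$coef)
  stats::plogis(eta)
}

#' Lower weighted median
#'
#' The smallest value `v` whose cumulative weight (over values `<= v`)
#' reaches half the total weight. With equal weights this is the usual
#' lower sample median.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, same length; at least one must be
#'   strictly positive.
#' @return a single value from `values`.
#' @export
#' @examples
#' weighted_median(c(1, 2, 3), c(1, 1, 1))   # 2
#' weighted_median(c(0, 10), c(3, 1))        # 0
weighted_median <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  tot <- sum(weights)
  if (tot <= 0)
    ctg_error("all weights are zero: weighted median has no support",
              "ctg_no_support_error")
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= tot / 2)[1]]
}

#' Estimate the FHR baseline with a stability-weighted median filter
#'
#' The baseline at time t is the weighted median of the FHR over the window
#' `|t - t'| < T`, with weights
#' `W_t(t') = p_stab(t') * max(0, 1 - |t - t'| / T)`:
#' samples likely to belong to an acceleration or deceleration
#' (`p_stab ~ 0`) are excluded, and closer samples count more. Two modes set
#' the half-duration T:
#' \describe{
#'   \item{fixed}{`T = T0` (default 20 min).}
#'   \item{variable}{`T = T0 / (3 * pbar(t))` where `pbar(t)` is the mean of
#'     `p_stab` over `[t - T0, t + T0]`; an unstable stretch widens the
#'     window, a stable one shrinks it so the filter tracks genuine baseline
#'     shifts faster. The factor 3 keeps the average half-duration near T0.
#'     T is clamped to `t_clamp_s` (default \[300, 3600\] s) since the
#'     formula diverges as `pbar` approaches 0.}
#' }
#' Windows truncate at the segment edges. For tractability the median is
#' evaluated on a regular sample grid (`grid_stride` samples, default 4 =
#' one evaluation per second at 4 Hz) and linearly interpolated back to the
#' full rate; `grid_stride = 1` reproduces the exact per-sample definition.
#' A window whose total weight vanishes falls back to its unweighted median.
#'
#' @param fhr gap-free FHR series (bpm).
#' @param p_stab per-sample stability probabilities in \[0, 1\], aligned.
#' @param mode `"fixed"` or `"variable"`.
#' @param T0_s base half-duration in seconds (default 1200 = 20 min).
#' @param sample_rate Hz.
#' @param grid_stride evaluation stride in samples (default 4).
#' @param t_clamp_s length-2 clamp for the variable half-duration, seconds.
#' @return a `baseline_estimate`: `baseline` (bpm, aligned to `fhr`),
#'   `p_stab`, `half_duration` (seconds per sample), `mode`.
#' @export
estimate_baseline <- function(fhr, p_stab = NULL,
                              mode = c("fixed", "variable"),
                              T0_s = 1200, sample_rate = 4, grid_stride = 4L,
                              t_clamp_s = c(300, 3600)) {
  mode <- match.arg(mode)
  n <- length(fhr)
  if (is.null(p_stab)) p_stab <- rep(1, n)
  if (length(p_stab) != n) stop("fhr and p_stab must be aligned")
  if (any(p_stab < 0 | p_stab > 1)) stop("p_stab must lie in [0, 1]")
  if (T0_s <= 0) stop("T0_s must be > 0")
  fs <- sample_rate
  grid <- unique(c(seq(1L, n, by = as.integer(grid_stride)), n))

  if (mode == "variable") {
    # mean stability over [t - T0, t + T0], truncated at the edges
    w <- as.integer(round(T0_s * fs))
    cs <- c(0, cumsum(p_stab))
    lo <- pmax(grid - w, 1L); hi <- pmin(grid + w, n)
    pbar <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    T_grid <- T0_s / (3 * pmax(pbar, 1e-9))
    T_grid <- pmin(pmax(T_grid, t_clamp_s[1]), t_clamp_s[2])
  } else {
    T_grid <- rep(T0_s, length(grid))
  }

  b_grid <- numeric(length(grid))
  for (g in seq_along(grid)) {
    t <- grid[g]
    Tn <- T_grid[g] * fs                       # half-window in samples
    lo <- max(1L, as.integer(ceiling(t - Tn + 1e-9)))
    hi <- min(n, as.integer(floor(t + Tn - 1e-9)))
    idx <- lo:hi
    tri <- 1 - abs(idx - t) / Tn
    wts <- p_stab[idx] * tri
    b_grid[g] <- if (sum(wts) > 0) weighted_median(fhr[idx], wts)
                 else stats::median(fhr[idx])
  }
  baseline <- if (length(grid) == n) b_grid
              else stats::approx(grid, b_grid, xout = seq_len(n), rule = 2)$y
  half_dur <- if (length(grid) == n) T_grid
              else stats::approx(grid, T_grid, xout = seq_len(n), rule = 2)$y
  structure(list(baseline = baseline, p_stab = p_stab,
                 half_duration = half_dur, mode = mode,
                 sample_rate = fs, T0_s = T0_s),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf(
    "<baseline_estimate> %s half-duration; %d samples; baseline %.1f-%.1f bpm\n",
    x$mode, length(x$baseline), min(x$baseline), max(x$baseline)))
  invisible(x)
}
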