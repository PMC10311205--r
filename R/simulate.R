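#' Simulation parameters
#'
#' Defaults describe a realistic intrapartum cohort: a slowly drifting
#' baseline inside the normocardic range, accelerations and decelerations
#' at typical labor rates with amplitudes/durations spanning the detection
#' criteria, band-limited variability targeting an STV of roughly 2 bpm and
#' an LTV of 15-20 bpm, quasi-periodic bell-shaped contractions every 2-5
#' minutes over a ~5 mm Hg resting tone, occasional signal dropouts, and a
#' logistic outcome link on the four default model features with a 10%
#' acidosis prevalence.
#'
#' @param n_cases number of cases in a cohort.
#' @param duration_s record duration in seconds.
#' @param sample_rate Hz (default 4).
#' @param baseline_range admissible baseline range, bpm.
#' @param baseline_drift_bpm amplitude scale of the slow baseline drift.
#' @param accel_rate_per_h,decel_rate_per_h event rates (events/hour).
#' @param accel_amp_bpm,accel_dur_s acceleration amplitude (bpm) and
#'   duration (s) ranges. Injected events are Hann-shaped, whose mean
#'   deviation is half the peak, so the amplitude floor sits above 20 bpm:
#'   anything lower would not be an acceleration under the mean-deviation
#'   criterion of the detector.
#' @param decel_amp_bpm,decel_dur_s deceleration amplitude and duration
#'   ranges (same amplitude-floor reasoning).
#' @param decel_ctr_lock_prob probability that a deceleration is
#'   time-locked to a contraction peak.
#' @param decel_ctr_lag_s lag of a locked deceleration peak after the
#'   contraction peak, seconds.
#' @param var_band_amps standard deviations (bpm) of the band-limited
#'   variability components in the 0.1-1, 1-3 and 3-7 cycles/min bands.
#' @param fast_var_amp standard deviation (bpm) of the fast beat-to-beat
#'   component (0.05-0.5 Hz) driving short-term variability.
#' @param ctr_period_s contraction inter-peak period range, seconds.
#' @param ctr_peak_mmhg contraction peak pressure range, mm Hg.
#' @param ctr_sd_s contraction Gaussian half-width range, seconds.
#' @param uc_tone_mmhg resting uterine tone, mm Hg.
#' @param gap_rate_per_h dropout rate (gaps/hour).
#' @param gap_dur_s log-normal gap duration parameters `c(meanlog, sdlog)`;
#'   capped at 900 s.
#' @param outcome_beta true logistic coefficients over the standardised
#'   four default features (`b_min`, `b_max`, `acc_area`, `dec_area`).
#' @param prevalence target acidosis prevalence.
#' @param n_centers centers to tag cases with (round-robin).
#' @param seed base seed; each case derives its own stream from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_cases = 100, duration_s = 3600, sample_rate = 4,
                       baseline_range = c(110, 160), baseline_drift_bpm = 8,
                       accel_rate_per_h = 10,
                       accel_amp_bpm = c(22, 35), accel_dur_s = c(20, 60),
                       decel_rate_per_h = 12,
                       decel_amp_bpm = c(25, 60), decel_dur_s = c(30, 180),
                       decel_ctr_lock_prob = 0.5, decel_ctr_lag_s = 20,
                       var_band_amps = c(1.5, 1.5, 1.0), fast_var_amp = 1.0,
                       ctr_period_s = c(120, 300), ctr_peak_mmhg = c(30, 80),
                       ctr_sd_s = c(15, 25), uc_tone_mmhg = 5,
                       gap_rate_per_h = 2, gap_dur_s = c(log(60), 1),
                       outcome_beta = c(b_min = -0.8, b_max = 0.8,
                                        acc_area = 0.5, dec_area = 1.2),
                       prevalence = 0.10, n_centers = 1, seed = 1) {
  p <- as.list(environment())
  for (r in list(p$baseline_range, p$accel_amp_bpm, p$accel_dur_s,
                 p$decel_amp_bpm, p$decel_dur_s, p$ctr_period_s,
                 p$ctr_peak_mmhg, p$ctr_sd_s))
    if (length(r) != 2 || r[1] > r[2]) stop("ranges must be ordered pairs")
  if (p$accel_rate_per_h < 0 || p$decel_rate_per_h < 0 ||
      p$gap_rate_per_h < 0) stop("rates must be >= 0")
  # infeasible when the expected event occupancy leaves no room to place
  # non-overlapping bumps
  occ <- (p$accel_rate_per_h * mean(p$accel_dur_s) +
            p$decel_rate_per_h * mean(p$decel_dur_s)) / 3600
  if (occ > 0.8)
    stop("event rates infeasible: expected occupancy ", round(occ, 2),
         " leaves no room for non-overlapping events")
  structure(p, class = "sim_params")
}

hann_bump <- function(t, center, width, amp) {
  s <- (t - center) / width + 0.5
  ifelse(s > 0 & s < 1, amp * 0.5 * (1 - cos(2 * pi * s)), 0)
}

# Place n event intervals (center, width) rejecting overlaps with `busy`
# intervals (matrix with columns start, end).  Returns a matrix.
place_events <- function(n, centers_pool, widths, dur_range, t_max, busy) {
  placed <- matrix(numeric(0), ncol = 2)
  out <- list()
  for (i in seq_len(n)) {
    for (try in 1:50) {
      ctr <- centers_pool[i]
      if (is.na(ctr)) ctr <- stats::runif(1, 0, t_max)
      w <- widths[i]
      iv <- c(ctr - w / 2, ctr + w / 2)
      if (iv[1] < 0 || iv[2] > t_max) { centers_pool[i] <- NA; next }
      all_busy <- rbind(busy, placed)
      if (nrow(all_busy) == 0 ||
          all(iv[2] <= all_busy[, 1] | iv[1] >= all_busy[, 2])) {
        placed <- rbind(placed, iv)
        out[[length(out) + 1]] <- c(center = ctr, width = w)
        break
      }
      centers_pool[i] <- NA                   # retry at a uniform position
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2,
                                      dimnames = list(NULL, c("center", "width"))))
  do.call(rbind, out)
}

smooth_drift <- function(t, range, drift_amp) {
  b0 <- stats::runif(1, range[1] + drift_amp, range[2] - drift_amp)
  per1 <- stats::runif(1, 900, 2400); per2 <- stats::runif(1, 300, 900)
  a1 <- stats::runif(1, 0.4, 1) * drift_amp
  a2 <- stats::runif(1, 0.1, 0.4) * drift_amp
  b <- b0 + a1 * sin(2 * pi * t / per1 + stats::runif(1, 0, 2 * pi)) +
    a2 * sin(2 * pi * t / per2 + stats::runif(1, 0, 2 * pi))
  pmin(pmax(b, range[1]), range[2])
}

band_noise <- function(n, fs, low_bpm, high_bpm, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  y <- bandpass(x, low_bpm, high_bpm, sample_rate = fs)
  s <- stats::sd(y)
  if (s < 1e-12) return(numeric(n))
  y / s * sd_target
}

# Analytic truth features of one record over its final `seg_len_s` seconds.
truth_features <- function(t, true_baseline, acc, dec, ctr_df, params,
                           seg_len_s = 1800) {
  t_max <- max(t) + 1 / params$sample_rate
  w0 <- t_max - seg_len_s
  in_seg <- t >= w0
  clip <- function(ev) {
    if (nrow(ev) == 0) return(ev)
    s <- ev[, "center"] - ev[, "width"] / 2
    e <- ev[, "center"] + ev[, "width"] / 2
    ev[e > w0 & s < t_max, , drop = FALSE]
  }
  ev_feats <- function(ev, prefix) {
    if (nrow(ev) == 0)
      return(stats::setNames(c(0, 0, 0, 0),
                             paste0(prefix, c("_count", "_total_dur",
                                              "_area", "_max_depth"))))
    s <- pmax(ev[, "center"] - ev[, "width"] / 2, w0)
    e <- pmin(ev[, "center"] + ev[, "width"] / 2, t_max)
    # Hann bump area over [s, e]; full-support integral is amp * width / 2
    area <- vapply(seq_len(nrow(ev)), function(i) {
      f <- function(x) hann_bump(x, ev[i, "center"], ev[i, "width"],
                                 ev[i, "amp"])
      stats::integrate(f, s[i], e[i])$value
    }, 0)
    stats::setNames(c(nrow(ev), sum(e - s), sum(area), max(ev[, "amp"])),
                    paste0(prefix, c("_count", "_total_dur", "_area",
                                     "_max_depth")))
  }
  acc_c <- clip(acc); dec_c <- clip(dec)
  b <- true_baseline[in_seg]
  c(b_min = min(b), b_med = stats::median(b), b_max = max(b),
    ev_feats(acc_c, "acc"), ev_feats(dec_c, "dec"))
}

#' Simulate one CTG record with ground truth
#'
#' Builds the FHR as a smooth drifting baseline plus Hann-shaped
#' acceleration/deceleration bumps plus band-limited variability noise, and
#' the UC as resting tone plus Gaussian-bell contractions; decelerations
#' are optionally time-locked to contraction peaks with a lag. Dropout gaps
#' are then inserted as 0-valued runs (the raw missing-value convention).
#' Ground truth (true baseline, event intervals, per-sample stability
#' labels, analytic features of the final 30 min) is recorded before gap
#' insertion.
#'
#' @param params a [sim_params()] object.
#' @param case_seed integer seed for this record's random stream.
#' @return list with `record` (a `ctg_record`) and `truth` (list:
#'   `baseline`, `events` data frame with kind/center/width/amp, `stable`
#'   logical series, `features` named vector, `p_outcome`/`outcome` filled
#'   by [simulate_cohort()]).
#' @export
simulate_record <- function(params, case_seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(case_seed, {
    fs <- params$sample_rate
    n <- as.integer(params$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    t_max <- params$duration_s

    true_baseline <- smooth_drift(t, params$baseline_range,
                                  params$baseline_drift_bpm)

    # contractions: quasi-periodic peaks
    ctr <- list()
    pos <- stats::runif(1, 0, params$ctr_period_s[1])
    while (pos < t_max) {
      ctr[[length(ctr) + 1]] <-
        c(center = pos,
          peak = stats::runif(1, params$ctr_peak_mmhg[1],
                              params$ctr_peak_mmhg[2]),
          sd = stats::runif(1, params$ctr_sd_s[1], params$ctr_sd_s[2]))
      pos <- pos + stats::runif(1, params$ctr_period_s[1],
                                params$ctr_period_s[2])
    }
    ctr_df <- if (length(ctr)) do.call(rbind, ctr) else
      matrix(numeric(0), ncol = 3, dimnames = list(NULL,
                                                   c("center", "peak", "sd")))

    # decelerations, optionally locked to contraction peaks
    n_dec <- stats::rpois(1, params$decel_rate_per_h * t_max / 3600)
    dec_centers <- rep(NA_real_, n_dec)
    if (n_dec > 0 && nrow(ctr_df) > 0) {
      locked <- stats::runif(n_dec) < params$decel_ctr_lock_prob
      pick <- sample(nrow(ctr_df), n_dec, replace = TRUE)
      dec_centers[locked] <- ctr_df[pick[locked], "center"] +
        params$decel_ctr_lag_s
    }
    dec_w <- stats::runif(n_dec, params$decel_dur_s[1], params$decel_dur_s[2])
    dec <- place_events(n_dec, dec_centers, dec_w, params$decel_dur_s,
                        t_max, matrix(numeric(0), ncol = 2))
    if (nrow(dec) > 0)
      dec <- cbind(dec, amp = stats::runif(nrow(dec), params$decel_amp_bpm[1],
                                           params$decel_amp_bpm[2]))
    else dec <- cbind(dec, amp = numeric(0))

    # accelerations, avoiding decelerations
    n_acc <- stats::rpois(1, params$accel_rate_per_h * t_max / 3600)
    acc_w <- stats::runif(n_acc, params$accel_dur_s[1], params$accel_dur_s[2])
    busy <- if (nrow(dec) > 0)
      cbind(dec[, "center"] - dec[, "width"] / 2,
            dec[, "center"] + dec[, "width"] / 2)
    else matrix(numeric(0), ncol = 2)
    acc <- place_events(n_acc, rep(NA_real_, n_acc), acc_w,
                        params$accel_dur_s, t_max, busy)
    if (nrow(acc) > 0)
      acc <- cbind(acc, amp = stats::runif(nrow(acc), params$accel_amp_bpm[1],
                                           params$accel_amp_bpm[2]))
    else acc <- cbind(acc, amp = numeric(0))

    bumps <- numeric(n)
    for (i in seq_len(nrow(acc)))
      bumps <- bumps + hann_bump(t, acc[i, "center"], acc[i, "width"],
                                 acc[i, "amp"])
    for (i in seq_len(nrow(dec)))
      bumps <- bumps - hann_bump(t, dec[i, "center"], dec[i, "width"],
                                 dec[i, "amp"])

    bands <- default_bands()
    noise <- numeric(n)
    for (j in 2:4)    # skip the 0-0.1 band: that is baseline drift territory
      noise <- noise + band_noise(n, fs, bands[[j]][1], bands[[j]][2],
                                  params$var_band_amps[j - 1])
    noise <- noise + band_noise(n, fs, 0.05 * 60, 0.5 * 60,
                                params$fast_var_amp)

    fhr_clean <- true_baseline + bumps + noise

    uc <- rep(params$uc_tone_mmhg, n)
    for (i in seq_len(nrow(ctr_df)))
      uc <- uc + ctr_df[i, "peak"] *
        exp(-(t - ctr_df[i, "center"])^2 / (2 * ctr_df[i, "sd"]^2))
    uc <- pmax(uc + stats::rnorm(n, 0, 0.5), 0.5)

    # per-sample stability: complement of the union of accel/decel supports
    stable <- rep(TRUE, n)
    for (ev in list(acc, dec)) for (i in seq_len(nrow(ev))) {
      s <- ev[i, "center"] - ev[i, "width"] / 2
      e <- ev[i, "center"] + ev[i, "width"] / 2
      stable[t >= s & t < e] <- FALSE
    }

    feats <- truth_features(t, true_baseline, acc, dec, ctr_df, params,
                            seg_len_s = min(1800, params$duration_s))

    # dropout gaps (FHR and, independently, UC)
    fhr <- fhr_clean; ucg <- uc
    missing_fhr <- rep(FALSE, n); missing_uc <- rep(FALSE, n)
    n_gap <- stats::rpois(1, params$gap_rate_per_h * t_max / 3600)
    for (g in seq_len(n_gap)) {
      dur <- min(stats::rlnorm(1, params$gap_dur_s[1], params$gap_dur_s[2]),
                 900)
      s <- stats::runif(1, 0, t_max - dur)
      idx <- t >= s & t < s + dur
      if (stats::runif(1) < 0.5) {
        fhr[idx] <- 0; missing_fhr[idx] <- TRUE
      } else {
        ucg[idx] <- 0; missing_uc[idx] <- TRUE
      }
    }

    events <- rbind(
      if (nrow(acc)) data.frame(kind = "acceleration", center = acc[, "center"],
                                width = acc[, "width"], amp = acc[, "amp"]),
      if (nrow(dec)) data.frame(kind = "deceleration", center = dec[, "center"],
                                width = dec[, "width"], amp = dec[, "amp"]),
      if (nrow(ctr_df)) data.frame(kind = "contraction",
                                   center = ctr_df[, "center"],
                                   width = 4 * ctr_df[, "sd"],
                                   amp = ctr_df[, "peak"]))
    if (is.null(events))
      events <- data.frame(kind = character(), center = numeric(),
                           width = numeric(), amp = numeric())

    rec <- ctg_record(paste0("sim", case_seed), fhr, ucg, sample_rate = fs,
                      end_offset = 0,
                      missing_fhr = missing_fhr | fhr == 0,
                      missing_uc = missing_uc | ucg == 0)
    list(record = rec,
         truth = list(baseline = true_baseline, events = events,
                      stable = stable, features = feats,
                      fhr_clean = fhr_clean, uc_clean = uc))
  })
}

# Truth-only fast path: event placement + drift on a 1 Hz grid, no noise
# synthesis; used for large-n cohort generation where only the ground-truth
# features are needed.
simulate_record_features_only <- function(params, case_seed) {
  with_seed(case_seed, {
    fs_coarse <- 1                              # 1 Hz grid is enough for truth
    n <- as.integer(params$duration_s * fs_coarse)
    t <- (seq_len(n) - 1) / fs_coarse
    t_max <- params$duration_s
    true_baseline <- smooth_drift(t, params$baseline_range,
                                  params$baseline_drift_bpm)
    ctr_centers <- c()
    pos <- stats::runif(1, 0, params$ctr_period_s[1])
    while (pos < t_max) {
      ctr_centers <- c(ctr_centers, pos)
      stats::runif(2)                           # keep stream layout stable
      pos <- pos + stats::runif(1, params$ctr_period_s[1],
                                params$ctr_period_s[2])
    }
    n_dec <- stats::rpois(1, params$decel_rate_per_h * t_max / 3600)
    dec_centers <- rep(NA_real_, n_dec)
    if (n_dec > 0 && length(ctr_centers) > 0) {
      locked <- stats::runif(n_dec) < params$decel_ctr_lock_prob
      pick <- sample(length(ctr_centers), n_dec, replace = TRUE)
      dec_centers[locked] <- ctr_centers[pick[locked]] + params$decel_ctr_lag_s
    }
    dec_w <- stats::runif(n_dec, params$decel_dur_s[1], params$decel_dur_s[2])
    dec <- place_events(n_dec, dec_centers, dec_w, params$decel_dur_s,
                        t_max, matrix(numeric(0), ncol = 2))
    if (nrow(dec) > 0)
      dec <- cbind(dec, amp = stats::runif(nrow(dec), params$decel_amp_bpm[1],
                                           params$decel_amp_bpm[2]))
    else dec <- cbind(dec, amp = numeric(0))
    n_acc <- stats::rpois(1, params$accel_rate_per_h * t_max / 3600)
    acc_w <- stats::runif(n_acc, params$accel_dur_s[1], params$accel_dur_s[2])
    busy <- if (nrow(dec) > 0)
      cbind(dec[, "center"] - dec[, "width"] / 2,
            dec[, "center"] + dec[, "width"] / 2)
    else matrix(numeric(0), ncol = 2)
    acc <- place_events(n_acc, rep(NA_real_, n_acc), acc_w,
                        params$accel_dur_s, t_max, busy)
    if (nrow(acc) > 0)
      acc <- cbind(acc, amp = stats::runif(nrow(acc), params$accel_amp_bpm[1],
                                           params$accel_amp_bpm[2]))
    else acc <- cbind(acc, amp = numeric(0))
    truth_features(t, true_baseline, acc, dec, NULL, params,
                   seg_len_s = min(1800, params$duration_s))
  })
}

#' Simulate a labeled cohort
#'
#' Generates `n_cases` cases and draws the acidosis outcome through a known
#' logistic link on the true (ground-truth) values of the four default
#' model features, standardised across the cohort. The intercept is tuned
#' by bisection on the simulated feature distribution so the achieved
#' prevalence matches the target. `mode = "features"` skips 4 Hz signal
#' synthesis and generates event placements and drift only (fast, used for
#' model-recovery studies at large n); `mode = "signals"` returns full
#' records as well.
#'
#' @param params a [sim_params()].
#' @param mode `"features"` or `"signals"`.
#' @return a list with `dataset` (data frame: `case_id`, `center`, `ph`,
#'   `outcome`, `p_outcome`, `eta`, and the true feature columns),
#'   `truth` (per-case ground-truth list, `signals` mode only), `records`
#'   (`signals` mode only), `beta0` (the tuned intercept), `scaler`.
#' @export
simulate_cohort <- function(params, mode = c("features", "signals")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "sim_params"))
  seeds <- params$seed * 100000L + seq_len(params$n_cases)
  if (mode == "signals") {
    sims <- lapply(seeds, function(s) simulate_record(params, s))
    feats <- do.call(rbind, lapply(sims, function(s) s$truth$features))
  } else {
    sims <- NULL
    feats <- do.call(rbind, lapply(seeds, function(s)
      simulate_record_features_only(params, s)))
  }
  fn <- names(params$outcome_beta)
  X <- feats[, fn, drop = FALSE]
  scaler <- fit_scaler(X)
  Z <- apply_scaler(X, scaler)
  eta_x <- drop(Z %*% params$outcome_beta)
  # bisection on the intercept for the target prevalence
  f <- function(b0) mean(stats::plogis(b0 + eta_x)) - params$prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("unattainable prevalence target")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  beta0 <- (lo + hi) / 2
  p_out <- stats::plogis(beta0 + eta_x)
  outcome <- with_seed(params$seed + 777L,
                       stats::runif(params$n_cases) < p_out)
  ph <- with_seed(params$seed + 778L,
                  ifelse(outcome, stats::runif(params$n_cases, 6.85, 7.049),
                         stats::runif(params$n_cases, 7.06, 7.40)))
  dataset <- data.frame(case_id = paste0("case", seq_len(params$n_cases)),
                        center = paste0("center",
                                        (seq_len(params$n_cases) - 1) %%
                                          params$n_centers + 1),
                        ph = ph, outcome = outcome, p_outcome = p_out,
                        eta = beta0 + eta_x,
                        stringsAsFactors = FALSE)
  dataset <- cbind(dataset, as.data.frame(feats))
  rownames(dataset) <- NULL
  list(dataset = dataset,
       records = if (mode == "signals") lapply(sims, `[[`, "record"),
       truth = if (mode == "signals") lapply(sims, `[[`, "truth"),
       beta0 = beta0, scaler = scaler, beta = params$outcome_beta)
}

#' Simulate an annotated calibration set
#'
#' Generates FHRMA-style training material for [fit_stability_model()] and
#' for baseline-error evaluation: clean (gap-free) FHR traces with the true
#' baseline and per-sample stability labels, the labels being exactly the
#' complement of the injected acceleration/deceleration supports.
#'
#' @param params a [sim_params()].
#' @param n_records number of recordings (default 66, split downstream).
#' @return list of length `n_records`; each element has `fhr`, `stable`,
#'   `true_baseline`.
#' @export
simulate_annotated_set <- function(params, n_records = 66) {
  p <- params
  p$gap_rate_per_h <- 0
  seeds <- p$seed * 1000L + seq_len(n_records)
  lapply(seeds, function(s) {
    sim <- simulate_record(p, s)
    list(fhr = sim$truth$fhr_clean, stable = sim$truth$stable,
         true_baseline = sim$truth$baseline)
  })
}
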