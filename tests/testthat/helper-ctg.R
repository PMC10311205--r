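# Shared fixture builders (everything generated in code; no stored data).

fs_default <- 4

# Hann-shaped bump evaluated on a time axis (seconds).
hann_at <- function(t, center, width, amp) {
  s <- (t - center) / width + 0.5
  ifelse(s > 0 & s < 1, amp * 0.5 * (1 - cos(2 * pi * s)), 0)
}

# A flat-baseline segment with optional injected bumps; returns the pieces
# the detectors and feature extractor need.
flat_segment <- function(dur_s = 1800, base = 140, fs = fs_default,
                         bumps = NULL, uc = NULL) {
  n <- dur_s * fs
  t <- (seq_len(n) - 1) / fs
  fhr <- rep(base, n)
  if (!is.null(bumps)) {
    for (i in seq_len(nrow(bumps)))
      fhr <- fhr + hann_at(t, bumps$center[i], bumps$width[i], bumps$amp[i])
  }
  if (is.null(uc)) uc <- rep(5, n)
  seg <- structure(list(case_id = "fix", fhr = fhr, uc = uc,
                        sample_rate = fs, start_index = 1L,
                        end_index = n + 1L, start_before_delivery = dur_s,
                        meta = case_meta()),
                   class = "ctg_segment")
  list(segment = seg, t = t, baseline = rep(base, n))
}

# Record with prescribed missing runs (given in seconds, [start, end)).
record_with_gaps <- function(dur_s, fhr_fun = function(t) 140 + 0 * t,
                             gaps_fhr = NULL, gaps_uc = NULL,
                             fs = fs_default, end_offset = 0) {
  n <- dur_s * fs
  t <- (seq_len(n) - 1) / fs
  fhr <- fhr_fun(t)
  uc <- rep(20, n)
  mf <- rep(FALSE, n); mu <- rep(FALSE, n)
  mark <- function(mask, gaps) {
    if (!is.null(gaps))
      for (i in seq_len(nrow(gaps)))
        mask[t >= gaps[i, 1] & t < gaps[i, 2]] <- TRUE
    mask
  }
  mf <- mark(mf, gaps_fhr); mu <- mark(mu, gaps_uc)
  fhr[mf] <- 0; uc[mu] <- 0
  ctg_record("gaps", fhr, uc, sample_rate = fs, end_offset = end_offset,
             missing_fhr = mf, missing_uc = mu)
}

# O(n^2) brute-force lower weighted median oracle.
brute_weighted_median <- function(values, weights) {
  tot <- sum(weights)
  cands <- sort(values)
  for (v in cands) {
    if (sum(weights[values <= v]) >= tot / 2) return(v)
  }
  stop("unreachable")
}

# A ctg_model with identity scaler and prescribed coefficients.
toy_model <- function(beta, beta0 = 0) {
  fn <- names(beta)
  structure(list(feature_names = fn, beta0 = beta0, beta = beta,
                 scaler = list(center = stats::setNames(rep(0, length(fn)), fn),
                               scale = stats::setNames(rep(1, length(fn)), fn)),
                 lambda = 0, outcome_threshold = 7.05),
            class = "ctg_model")
}

# Feature data frame with a planted logistic relationship (for protocol
# tests that do not need the simulator).
toy_dataset <- function(n, beta = c(f1 = 1, f2 = -1), beta0 = -2, seed = 1,
                        centers = 1) {
  ctgtools:::with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, names(beta)))
    p <- plogis(beta0 + drop(X %*% beta))
    out <- data.frame(case_id = paste0("c", seq_len(n)),
                      center = paste0("ctr", (seq_len(n) - 1) %% centers + 1),
                      outcome = runif(n) < p)
    cbind(out, as.data.frame(X))
  })
}
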