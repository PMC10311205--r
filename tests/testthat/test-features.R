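test_that("STV matches closed-form cases", {
  expect_equal(compute_stv(rep(142, 1200)), 0)
  # alternate 140/150 per full 3.75-s epoch
  x <- rep(rep(c(140, 150), each = 15), 40)
  expect_equal(compute_stv(x), 10)
  y <- 130 + sin(seq_len(2400) / 11)
  expect_equal(compute_stv(y + 25), compute_stv(y))
  expect_error(compute_stv(rep(140, 10)), class = "ctg_length_error")
})

test_that("LTV matches closed-form cases", {
  expect_equal(compute_ltv(rep(120, 960)), 0)
  t <- (seq_len(7200) - 1) / 4
  A <- 7
  expect_equal(compute_ltv(140 + A * sin(2 * pi * t / 20)), 2 * A,
               tolerance = 0.02)
  x <- c(140 + 2.5 * rep(c(-1, 1), each = 5, length.out = 240),
         140 + 7.5 * rep(c(-1, 1), each = 5, length.out = 240))
  expect_equal(compute_ltv(x), 10)
  expect_error(compute_ltv(rep(140, 100)), class = "ctg_length_error")
})

test_that("joint deceleration-contraction features follow interval arithmetic", {
  n <- 1800 * 4
  t <- (seq_len(n) - 1) / 4
  fhr <- rep(140, n); fhr[t >= 100 & t < 160] <- 110
  bl <- rep(140, n)
  dec <- detect_decelerations(fhr, bl)
  mk_ctr <- function(ivals) {
    uc <- rep(5, n)
    for (iv in ivals) uc[t >= iv[1] & t < iv[2]] <- 50
    detect_contractions(uc)
  }
  # deceleration fully inside one contraction
  j1 <- joint_dec_contraction(dec, mk_ctr(list(c(80, 200))), fhr, bl)
  expect_equal(unname(j1["dec_no_ctr_dur"]), 0)
  expect_equal(unname(j1["dec_no_ctr_area"]), 0)
  # contraction [130, 200) leaves 30 s of the deceleration outside
  j2 <- joint_dec_contraction(dec, mk_ctr(list(c(130, 200))), fhr, bl)
  expect_equal(unname(j2["dec_no_ctr_dur"]), 30, tolerance = 0.5)
  expect_equal(unname(j2["dec_no_ctr_area"]), 30 * 30, tolerance = 0.02 * 900)
  # nearest-peak time difference against two well-separated contractions
  ctr <- mk_ctr(list(c(90, 150), c(270, 330)))
  pk <- dec$peak_s
  expected <- min(abs(pk - ctr$peak_s))
  j3 <- joint_dec_contraction(dec, ctr, fhr, bl)
  expect_equal(unname(j3["dec_ctr_peak_timediff"]), expected)
  # no contractions at all: peak-time features are zero
  j4 <- joint_dec_contraction(dec, detect_contractions(rep(5, n)), fhr, bl)
  expect_equal(unname(j4["dec_ctr_peak_timediff"]), 0)
  expect_equal(unname(j4["dec_no_ctr_dur"]), 60, tolerance = 0.5)
})

test_that("a degenerate constant segment yields all-zero event features", {
  fx <- flat_segment()
  fv <- compute_features(fx$segment, fx$baseline)
  expect_named(fv, ctg_feature_names())
  expect_equal(unname(fv[c("b_min", "b_med", "b_max")]), rep(140, 3))
  zero <- setdiff(ctg_feature_names(), c("b_min", "b_med", "b_max"))
  expect_equal(unname(fv[zero]), rep(0, length(zero)))
})

test_that("injected events are counted and measured within tolerance", {
  fx <- flat_segment(bumps = data.frame(center = c(400, 1200),
                                        width = c(30, 40),
                                        amp = c(20, 25)))
  fv <- compute_features(fx$segment, fx$baseline)
  expect_equal(unname(fv["acc_count"]), 2)
  analytic <- 20 * 30 / 2 + 25 * 40 / 2
  expect_equal(unname(fv["acc_area"]), analytic, tolerance = 0.05)
  expect_equal(unname(fv["acc_max_depth"]), 25, tolerance = 1e-3)

  # a 150-s deceleration is counted both as deceleration and late deceleration
  fx2 <- flat_segment(bumps = data.frame(center = 900, width = 150, amp = -30))
  fv2 <- compute_features(fx2$segment, fx2$baseline)
  expect_equal(unname(fv2["dec_count"]), 1)
  expect_equal(unname(fv2["late_dec_count"]), 1)
  expect_gte(unname(fv2["dec_total_dur"]), 120)
})

test_that("late and outside-contraction features never exceed their totals", {
  for (seed in c(2, 9)) {
    sim <- simulate_record(sim_params(duration_s = 1800, seed = seed,
                                      gap_rate_per_h = 0), seed)
    fx <- list(segment = structure(list(case_id = "s",
                                        fhr = sim$truth$fhr_clean,
                                        uc = sim$record$uc, sample_rate = 4,
                                        start_index = 1L,
                                        end_index = length(sim$record$uc) + 1L,
                                        start_before_delivery = 1800,
                                        meta = case_meta()),
                                   class = "ctg_segment"))
    fv <- compute_features(fx$segment, sim$truth$baseline)
    expect_lte(fv["late_dec_area"], fv["dec_area"] + 1e-9)
    expect_lte(fv["late_dec_total_dur"], fv["dec_total_dur"] + 1e-9)
    expect_lte(fv["dec_no_ctr_dur"], fv["dec_total_dur"] + 1e-9)
    expect_lte(fv["dec_no_ctr_area"], fv["dec_area"] + 1e-9)
    expect_lte(fv["late_dec_no_ctr_dur"], fv["dec_no_ctr_dur"] + 1e-9)
  }
})

test_that("shifting FHR and baseline together shifts only the baseline stats", {
  sim <- simulate_record(sim_params(duration_s = 1800, seed = 13,
                                    gap_rate_per_h = 0), 5)
  seg <- structure(list(case_id = "s", fhr = sim$truth$fhr_clean,
                        uc = sim$record$uc, sample_rate = 4,
                        start_index = 1L,
                        end_index = length(sim$record$uc) + 1L,
                        start_before_delivery = 1800, meta = case_meta()),
                   class = "ctg_segment")
  fv1 <- compute_features(seg, sim$truth$baseline)
  seg2 <- seg; seg2$fhr <- seg$fhr + 12
  fv2 <- compute_features(seg2, sim$truth$baseline + 12)
  expect_equal(unname(fv2[c("b_min", "b_med", "b_max")]),
               unname(fv1[c("b_min", "b_med", "b_max")]) + 12)
  others <- setdiff(ctg_feature_names(), c("b_min", "b_med", "b_max"))
  expect_equal(fv2[others], fv1[others], tolerance = 1e-9)
})
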