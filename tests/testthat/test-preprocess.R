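test_that("short gaps are linearly interpolated, long gaps left masked", {
  rec <- record_with_gaps(3600, fhr_fun = function(t) 140 + t / 360,
                          gaps_fhr = rbind(c(600, 900),    # 5 min
                                           c(1500, 2220))) # 12 min
  out <- interpolate_gaps(rec)
  t <- (seq_along(out$fhr) - 1) / 4
  in5 <- t >= 600 & t < 900
  expect_false(any(out$missing_fhr[in5]))
  # linear ramp between the anchors
  i0 <- max(which(t < 600)); i1 <- min(which(t >= 900))
  expected <- approx(c(t[i0], t[i1]), c(out$fhr[i0], out$fhr[i1]),
                     xout = t[in5])$y
  expect_equal(out$fhr[in5], expected, tolerance = 1e-10)
  in12 <- t >= 1500 & t < 2220
  expect_true(all(out$missing_fhr[in12]))
  expect_equal(out$fhr[in12], rep(0, sum(in12)))
})

test_that("gap interpolation never modifies observed samples", {
  rec <- record_with_gaps(1200, fhr_fun = function(t) 140 + 10 * sin(t / 60),
                          gaps_fhr = rbind(c(100, 160), c(400, 430),
                                           c(0, 20), c(1190, 1200)))
  for (method in c("linear", "cubic_hermite")) {
    out <- interpolate_gaps(rec, method = method)
    obs <- !rec$missing_fhr
    expect_identical(out$fhr[obs], rec$fhr[obs])
    # boundary gaps have no anchor and must stay masked
    expect_true(all(out$missing_fhr[rec$missing_fhr &
                                      (seq_along(rec$fhr) <= 80)]))
    expect_true(all(out$missing_fhr[rec$missing_fhr &
                                      (seq_along(rec$fhr) > 1200 * 4 - 40)]))
  }
  norec <- record_with_gaps(600)
  expect_identical(interpolate_gaps(norec)$fhr, norec$fhr)
})

test_that("linear and Hermite fills agree where the signal is linear and both clear the same masks", {
  rec <- record_with_gaps(1200, fhr_fun = function(t) 120 + t / 100,
                          gaps_fhr = rbind(c(100, 100.25), c(300, 360)))
  lin <- interpolate_gaps(rec, method = "linear")
  her <- interpolate_gaps(rec, method = "cubic_hermite")
  expect_identical(lin$missing_fhr, her$missing_fhr)
  # on an affine signal the Hermite slopes equal the secant: exact agreement
  expect_equal(her$fhr, lin$fhr, tolerance = 1e-9)
  # on a smooth curved signal the Hermite fill is at least as accurate
  rec2 <- record_with_gaps(1200,
                           fhr_fun = function(t) 140 + 12 * sin(t / 45),
                           gaps_fhr = rbind(c(300, 420)))
  truth <- 140 + 12 * sin(((seq_len(4800) - 1) / 4) / 45)
  bad <- rec2$missing_fhr
  e_lin <- mean(abs(interpolate_gaps(rec2, method = "linear")$fhr[bad] -
                      truth[bad]))
  e_her <- mean(abs(interpolate_gaps(rec2,
                                     method = "cubic_hermite")$fhr[bad] -
                      truth[bad]))
  expect_lt(e_her, e_lin)
})

test_that("the latest clean window is selected at sample granularity", {
  rec <- record_with_gaps(2400, gaps_fhr = rbind(c(2300, 2350)))
  rec <- interpolate_gaps(rec)          # 50 s gap gets filled
  seg <- select_segment(rec)
  expect_s3_class(seg, "ctg_segment")
  expect_equal(seg$end_index - seg$start_index, 1800 * 4)
  expect_equal(seg$start_index, 2400 * 4 - 1800 * 4 + 1)
  expect_equal(seg$start_before_delivery, 1800)
  expect_false(anyNA(seg$fhr))

  # brute-force all-windows oracle on a short record with awkward gaps
  rec2 <- record_with_gaps(300, gaps_fhr = rbind(c(120, 122)),
                           gaps_uc = rbind(c(200, 203)))
  L <- 60 * 4
  ok <- !(rec2$missing_fhr | rec2$missing_uc)
  starts <- which(vapply(seq_len(length(ok) - L + 1),
                         function(s) all(ok[s:(s + L - 1)]), TRUE))
  seg2 <- select_segment(rec2, seg_len_s = 60, max_start_s = 1e9)
  expect_equal(seg2$start_index, max(starts))
})

test_that("cases without an admissible window are discarded with a reason", {
  # only clean 30-min window starts 95 min before delivery
  rec <- record_with_gaps(6000, gaps_fhr = rbind(c(2100, 6000)))
  d <- select_segment(rec)
  expect_true(is_discard(d))
  expect_equal(d$reason, "too_early")

  # unfilled 12-min gap in the last 35 min, nothing clean before
  rec2 <- record_with_gaps(2400, gaps_fhr = rbind(c(100, 300),
                                                  c(1600, 2320)))
  rec2 <- interpolate_gaps(rec2)
  d2 <- select_segment(rec2)
  expect_true(is_discard(d2))
  expect_equal(d2$reason, "no_window")
})

test_that("segment cleanliness requires both FHR and UC", {
  rec <- record_with_gaps(2400, gaps_uc = rbind(c(1000, 2400)))
  d <- select_segment(rec)
  expect_true(is_discard(d))   # UC gap blocks every late window; earlier
  expect_equal(d$reason, "no_window")
})
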