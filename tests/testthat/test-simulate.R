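test_that("the generator is deterministic and honours degenerate settings", {
  p <- sim_params(duration_s = 600, seed = 2)
  a <- simulate_record(p, 7)
  b <- simulate_record(p, 7)
  expect_identical(a$record$fhr, b$record$fhr)
  expect_identical(a$record$uc, b$record$uc)
  expect_identical(a$truth$features, b$truth$features)

  quiet <- sim_params(duration_s = 600, seed = 2, accel_rate_per_h = 0,
                      decel_rate_per_h = 0, var_band_amps = c(0, 0, 0),
                      fast_var_amp = 0, gap_rate_per_h = 0)
  q <- simulate_record(quiet, 3)
  expect_equal(q$record$fhr, q$truth$baseline)
  expect_true(all(q$truth$stable))
})

test_that("event counts follow the requested Poisson rate", {
  p <- sim_params(duration_s = 3600, seed = 5, accel_rate_per_h = 6,
                  decel_rate_per_h = 0, gap_rate_per_h = 0,
                  var_band_amps = c(0, 0, 0), fast_var_amp = 0)
  counts <- vapply(1:80, function(s) {
    tr <- simulate_record(p, s)$truth
    sum(tr$events$kind == "acceleration")
  }, 0)
  expect_lt(abs(mean(counts) - 6), 1)   # se = sqrt(6/80) ~ 0.27
})

test_that("stability labels are the complement of the event supports", {
  sim <- simulate_record(sim_params(duration_s = 1200, seed = 3,
                                    gap_rate_per_h = 0), 11)
  t <- (seq_along(sim$truth$stable) - 1) / 4
  ev <- sim$truth$events
  ev <- ev[ev$kind != "contraction", ]
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(ev)))
    inside <- inside | (t >= ev$center[i] - ev$width[i] / 2 &
                          t < ev$center[i] + ev$width[i] / 2)
  expect_identical(sim$truth$stable, !inside)
})

test_that("gap insertion never changes unmasked samples", {
  p <- sim_params(duration_s = 1800, seed = 6, gap_rate_per_h = 30)
  sim <- simulate_record(p, 4)
  rec <- sim$record
  keep <- !rec$missing_fhr
  expect_equal(rec$fhr[keep], sim$truth$fhr_clean[keep])
  expect_true(all(rec$fhr[rec$missing_fhr] == 0))
})

test_that("cohort prevalence tracks the target through the tuned intercept", {
  coh <- simulate_cohort(sim_params(n_cases = 2000, duration_s = 1800,
                                    seed = 14, prevalence = 0.10))
  prev <- mean(coh$dataset$outcome)
  expect_gte(prev, 0.07); expect_lte(prev, 0.13)
  expect_true(all(coh$dataset$outcome == (coh$dataset$ph < 7.05)))
  # byte-identical rerun
  coh2 <- simulate_cohort(sim_params(n_cases = 2000, duration_s = 1800,
                                     seed = 14, prevalence = 0.10))
  expect_identical(coh$dataset, coh2$dataset)
})

test_that("a null outcome link gives chance-level downstream AUC", {
  p <- sim_params(n_cases = 800, duration_s = 1800, seed = 21,
                  outcome_beta = c(b_min = 0, b_max = 0, acc_area = 0,
                                   dec_area = 0))
  coh <- simulate_cohort(p)
  cv <- kfold_eval(coh$dataset, seed = 1)
  expect_lt(abs(cv$pooled_auc - 0.5), 0.07)
})

test_that("ground-truth features agree with the features module on clean records", {
  p <- sim_params(duration_s = 2400, seed = 33, gap_rate_per_h = 0,
                  var_band_amps = c(0, 0, 0), fast_var_amp = 0,
                  accel_rate_per_h = 6, decel_rate_per_h = 6)
  sim <- simulate_record(p, 1)
  # fixture guard: no event straddles the analysis-window boundary
  ev <- sim$truth$events[sim$truth$events$kind != "contraction", ]
  w0 <- 2400 - 1800
  expect_true(all(ev$center - ev$width / 2 > w0 + 1 |
                    ev$center + ev$width / 2 < w0 - 1))
  rec <- sim$record
  seg <- select_segment(rec)
  fv <- compute_features(seg, sim$truth$baseline[(w0 * 4 + 1):(2400 * 4)])
  tf <- sim$truth$features
  for (f in c("b_min", "b_med", "b_max"))
    expect_equal(unname(fv[f]), unname(tf[f]), tolerance = 0.01)
  for (f in c("acc_count", "dec_count"))
    expect_equal(unname(fv[f]), unname(tf[f]))
  for (f in c("acc_area", "dec_area", "acc_total_dur", "dec_total_dur",
              "acc_max_depth", "dec_max_depth"))
    expect_equal(unname(fv[f]), unname(tf[f]), tolerance = 0.05)
})

test_that("annotated sets mirror the train/test protocol material", {
  p <- sim_params(duration_s = 900, seed = 44)
  ann <- simulate_annotated_set(p, n_records = 5)
  expect_length(ann, 5)
  for (a in ann) {
    expect_length(a$stable, length(a$fhr))
    expect_length(a$true_baseline, length(a$fhr))
    expect_false(any(a$fhr == 0))          # gap-free by construction
  }
})

test_that("infeasible event rates are rejected up front", {
  expect_error(sim_params(decel_rate_per_h = 40, decel_dur_s = c(120, 180)),
               "infeasible")
})
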