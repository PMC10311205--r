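test_that("class balancing gives each class equal total weight", {
  y <- rep(c(FALSE, TRUE), c(90, 10))
  w <- ifelse(y, length(y) / (2 * sum(y)), length(y) / (2 * sum(!y)))
  expect_equal(sum(w[y]), sum(w[!y]))
  expect_equal(w[y][1] / w[!y][1], 9)

  df <- toy_dataset(200, seed = 3)
  m <- fit_acidosis_model(df, feature_names = c("f1", "f2"))
  expect_s3_class(m, "ctg_model")
  expect_error(fit_acidosis_model(transform(df, outcome = FALSE),
                                  feature_names = c("f1", "f2")),
               class = "ctg_degenerate_fit_error")
  expect_error(fit_acidosis_model(df, feature_names = c("f1", "nope")),
               class = "ctg_name_error")
})

test_that("duplicating cases while halving their weight leaves the fit unchanged", {
  df <- toy_dataset(120, seed = 8)
  X <- as.matrix(df[, c("f1", "f2")])
  y <- as.numeric(df$outcome)
  w <- ifelse(y == 1, 2.5, 1)
  f1 <- ctgtools:::ridge_logistic(X, y, weights = w, lambda = 1e-3)
  dup <- y == 1
  X2 <- rbind(X, X[dup, ]); y2 <- c(y, y[dup])
  w2 <- c(ifelse(y == 1, 1.25, 1), rep(1.25, sum(dup)))
  f2 <- ctgtools:::ridge_logistic(X2, y2, weights = w2, lambda = 1e-3)
  expect_lt(max(abs(f1$coef - f2$coef)), 1e-6)
  expect_lt(abs(f1$intercept - f2$intercept), 1e-6)
})

test_that("the ridge solver agrees with glm when the penalty vanishes", {
  df <- toy_dataset(400, seed = 5)
  X <- as.matrix(df[, c("f1", "f2")])
  y <- as.numeric(df$outcome)
  ours <- ctgtools:::ridge_logistic(X, y, lambda = 1e-10)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(ours$coef), unname(coef(ref)[-1]), tolerance = 1e-6)
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
})

test_that("risk and contributions follow the logistic decomposition", {
  m <- toy_model(c(a = 1, b = 1))
  p0 <- predict(m, c(a = 0, b = 0))
  expect_equal(p0$risk, 0.5)

  m2 <- toy_model(c(a = 2, b = 2))
  p <- predict(m2, c(a = 1, b = 1))
  expect_equal(unname(p$contributions), c(0.5, 0.5))
  expect_equal(p$risk, plogis(4))

  m3 <- toy_model(c(a = 3, b = -1, c = 1))
  p3 <- predict(m3, c(a = 1, b = 1, c = 1), variant = "positive_only")
  expect_equal(unname(p3$contributions), c(0.75, 0, 0.25))
  p3s <- predict(m3, c(a = 1, b = 1, c = 1), variant = "signed")
  expect_equal(sum(p3s$contributions), 1)
  expect_error(predict(m3, c(a = 1, b = 1)), class = "ctg_name_error")
})

test_that("risk increases in any feature with a positive coefficient", {
  df <- toy_dataset(500, seed = 12)
  m <- fit_acidosis_model(df, feature_names = c("f1", "f2"))
  base <- c(f1 = 0, f2 = 0)
  s <- unname(sign(m$beta["f1"]))
  r1 <- predict(m, base)$risk
  r2 <- predict(m, c(f1 = s * 1, f2 = 0))$risk
  expect_gt(r2, r1)
})

test_that("AUC matches the Mann-Whitney statistic and is rank-invariant", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), class = "ctg_single_class_error")
  ctgtools:::with_seed(7, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      s <- round(runif(n), 2)               # ties likely
      y <- runif(n) < 0.4
      if (length(unique(y)) < 2) next
      u <- wilcox.test(s[y], s[!y], exact = FALSE)$statistic
      expect_equal(auc(s, y), unname(u) / (sum(y) * sum(!y)))
      expect_equal(auc(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y), auc(s, y))
    }
    big_s <- runif(10000); big_y <- runif(10000) < 0.5
    expect_lt(abs(auc(big_s, big_y) - 0.5), 0.02)
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  ctgtools:::with_seed(19, {
    s <- rnorm(300); y <- runif(300) < plogis(s)
    ref <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
    expect_equal(auc(s, y), as.numeric(ref), tolerance = 1e-10)
  })
})

test_that("k-fold evaluation is deterministic per seed and validates fold counts", {
  df <- toy_dataset(300, seed = 4)
  a <- kfold_eval(df, feature_names = c("f1", "f2"), seed = 42)
  b <- kfold_eval(df, feature_names = c("f1", "f2"), seed = 42)
  expect_identical(a$fold, b$fold)
  expect_identical(a$pooled_auc, b$pooled_auc)
  c_ <- kfold_eval(df, feature_names = c("f1", "f2"), seed = 43)
  expect_false(identical(a$fold, c_$fold))

  tiny <- toy_dataset(40, beta0 = -3.2, seed = 6)
  if (sum(tiny$outcome) >= 1 && sum(tiny$outcome) < 5)
    expect_error(kfold_eval(tiny, feature_names = c("f1", "f2"), k = 5),
                 class = "ctg_fold_error")
})

test_that("leave-one-center-out never mixes cases and handles degenerate centers", {
  df <- toy_dataset(300, seed = 9, centers = 3)
  res <- cross_center_eval(df, feature_names = c("f1", "f2"))
  expect_named(res, paste0("ctr", 1:3), ignore.order = TRUE)
  expect_true(all(res > 0.5))   # exchangeable centers share the signal
  expect_lt(max(res) - min(res), 0.25)

  df2 <- toy_dataset(240, seed = 10, centers = 3)
  df2$outcome[df2$center == "ctr3"] <- FALSE
  expect_warning(res2 <- cross_center_eval(df2, feature_names = c("f1", "f2")),
                 "single-class")
  expect_true(is.na(res2["ctr3"]))
})
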