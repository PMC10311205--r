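#' Default model features
#'
#' The four-feature subset used by the default acidosis model: minimum and
#' maximum baseline, acceleration area and deceleration area. It is the
#' simplest subset and generalises best across centers.
#' @return character vector.
#' @export
default_model_features <- function() c("b_min", "b_max", "acc_area", "dec_area")

check_dataset <- function(dataset, feature_names) {
  if (!is.data.frame(dataset)) stop("dataset must be a data frame")
  if (!"outcome" %in% names(dataset))
    stop("dataset needs a logical 'outcome' column")
  miss <- setdiff(feature_names, names(dataset))
  if (length(miss))
    ctg_error(paste("unknown feature(s):", paste(miss, collapse = ", ")),
              "ctg_name_error")
  invisible(TRUE)
}

#' Fit the class-balanced logistic acidosis model
#'
#' Fits a logistic regression of the binary acidosis outcome (umbilical pH
#' below `outcome_threshold`) on a feature subset. Cases are weighted
#' `N / (2 * N_class)` so the pathological and normal classes carry equal
#' total weight, which the heavily imbalanced clinical cohorts require.
#' Features are standardised with center/scale taken from the training data
#' (stored in the model, so predictions accept raw features) and the fit
#' carries a light ridge penalty to keep small or separable cohorts finite.
#'
#' @param dataset data frame with a logical `outcome` column and one column
#'   per feature (e.g. from [simulate_cohort()] or [extract_feature_table()]).
#' @param feature_names features to use (default [default_model_features()]).
#' @param lambda ridge strength (default 1e-4).
#' @param outcome_threshold the pH cutoff the outcome encodes (default 7.05).
#' @return a `ctg_model`: `feature_names`, `beta0`, `beta` (standardised
#'   scale), `scaler`, `lambda`, `outcome_threshold`.
#' @export
fit_acidosis_model <- function(dataset,
                               feature_names = default_model_features(),
                               lambda = 1e-4, outcome_threshold = 7.05) {
  check_dataset(dataset, feature_names)
  y <- as.numeric(dataset$outcome)
  if (length(unique(y)) < 2)
    ctg_error("outcome has a single class", "ctg_degenerate_fit_error")
  X <- as.matrix(dataset[, feature_names, drop = FALSE])
  n <- length(y); n1 <- sum(y); n0 <- n - n1
  w <- ifelse(y == 1, n / (2 * n1), n / (2 * n0))
  scaler <- fit_scaler(X)
  fit <- ridge_logistic(apply_scaler(X, scaler), y, weights = w,
                        lambda = lambda)
  structure(list(feature_names = feature_names,
                 beta0 = fit$intercept,
                 beta = stats::setNames(fit$coef, feature_names),
                 scaler = scaler, lambda = lambda,
                 outcome_threshold = outcome_threshold),
            class = "ctg_model")
}

#' @export
print.ctg_model <- function(x, ...) {
  cat(sprintf("<ctg_model> logistic acidosis model (pH < %g), %d features\n",
              x$outcome_threshold, length(x$feature_names)))
  cat(sprintf("  beta0 = %.4f\n", x$beta0))
  for (f in x$feature_names)
    cat(sprintf("  %-28s %+0.4f\n", f, x$beta[f]))
  invisible(x)
}

#' Predict acidosis risk with per-feature contributions
#'
#' Computes the risk `p = plogis(beta0 + sum_i beta_i x_i)` on the
#' standardised features, and the contribution of each feature,
#' `c_i = beta_i x_i / sum_j beta_j x_j`. The `"signed"` variant reports
#' these directly (they sum to 1 whenever the denominator is nonzero); the
#' `"positive_only"` variant keeps only terms with `beta_i x_i > 0` and
#' renormalises, giving nonnegative contributions that sum to 1 whenever
#' any positive term exists.
#'
#' @param object a `ctg_model`.
#' @param x named numeric feature vector, or a data frame / matrix of
#'   feature columns (one prediction per row).
#' @param variant `"signed"` or `"positive_only"`.
#' @param ... unused.
#' @return for a named vector, a `ctg_prediction` (fields `risk`,
#'   `contributions`, `variant`); for a data frame or matrix, a list of
#'   `ctg_prediction`s, one per row.
#' @export
predict.ctg_model <- function(object, x, variant = c("signed", "positive_only"),
                              ...) {
  variant <- match.arg(variant)
  if (is.data.frame(x) || is.matrix(x)) {
    miss <- setdiff(object$feature_names, colnames(x))
    if (length(miss))
      ctg_error(paste("missing feature(s):", paste(miss, collapse = ", ")),
                "ctg_name_error")
    X <- as.matrix(as.data.frame(x)[, object$feature_names, drop = FALSE])
    return(lapply(seq_len(nrow(X)), function(i)
      predict(object, X[i, ], variant = variant)))
  }
  miss <- setdiff(object$feature_names, names(x))
  if (length(miss))
    ctg_error(paste("missing feature(s):", paste(miss, collapse = ", ")),
              "ctg_name_error")
  z <- (as.numeric(x[object$feature_names]) - object$scaler$center) /
    object$scaler$scale
  terms <- object$beta * z
  eta <- object$beta0 + sum(terms)
  denom <- sum(terms)
  if (variant == "signed") {
    contrib <- if (denom != 0) terms / denom
               else stats::setNames(rep(NA_real_, length(terms)),
                                    object$feature_names)
    if (denom != 0) stopifnot(abs(sum(contrib) - 1) < 1e-8)
  } else {
    pos <- pmax(terms, 0)
    pos[terms <= 0] <- 0
    s <- sum(pos)
    contrib <- if (s > 0) pos / s
               else stats::setNames(rep(0, length(terms)),
                                    object$feature_names)
  }
  structure(list(risk = stats::plogis(eta),
                 contributions = stats::setNames(contrib,
                                                 object$feature_names),
                 variant = variant, eta = eta),
            class = "ctg_prediction")
}

#' @export
print.ctg_prediction <- function(x, ...) {
  cat(sprintf("<ctg_prediction> risk = %.3f (%s contributions)\n",
              x$risk, x$variant))
  for (f in names(x$contributions))
    cat(sprintf("  %-28s %+0.3f\n", f, x$contributions[f]))
  invisible(x)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (equivalent to the
#' Mann-Whitney U statistic scaled by `n1 * n0`); tied scores contribute
#' one half.
#'
#' @param scores numeric risk scores.
#' @param labels logical (or 0/1) outcomes.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    ctg_error("AUC undefined: both classes must be present",
              "ctg_single_class_error")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Evaluate a block of code under a temporary RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validated AUC
#'
#' Assigns cases to `k` stratified folds from a seeded shuffle, refits the
#' model on each training split, scores the held-out fold, and reports both
#' per-fold AUCs and the AUC of the pooled out-of-fold scores.
#'
#' @inheritParams fit_acidosis_model
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return list with `fold_auc`, `pooled_auc`, `scores` (out-of-fold),
#'   `fold` (assignment), `k`, `seed`.
#' @export
kfold_eval <- function(dataset, feature_names = default_model_features(),
                       k = 5, seed = 1, lambda = 1e-4,
                       outcome_threshold = 7.05) {
  check_dataset(dataset, feature_names)
  y <- as.logical(dataset$outcome)
  if (min(sum(y), sum(!y)) < k)
    ctg_error(sprintf("cannot build %d stratified folds: minority class has %d cases",
                      k, min(sum(y), sum(!y))), "ctg_fold_error")
  fold <- stratified_folds(y, k, seed)
  scores <- numeric(nrow(dataset))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- dataset[fold != f, , drop = FALSE]
    te <- dataset[fold == f, , drop = FALSE]
    m <- fit_acidosis_model(tr, feature_names, lambda = lambda,
                            outcome_threshold = outcome_threshold)
    s <- vapply(predict(m, te[, feature_names, drop = FALSE]),
                function(p) p$risk, 0)
    scores[fold == f] <- s
    fold_auc[f] <- auc(s, te$outcome)
  }
  list(fold_auc = fold_auc, pooled_auc = auc(scores, y),
       scores = scores, fold = fold, k = k, seed = seed)
}

#' Leave-one-center-out evaluation
#'
#' For every center, fits the model on all other centers and scores the
#' held-out center, estimating the performance expected when deploying the
#' model in a new site. A held-out center with a single outcome class gets
#' `NA` with a warning (its AUC is undefined).
#'
#' @inheritParams fit_acidosis_model
#' @return named numeric vector of per-center AUCs.
#' @export
cross_center_eval <- function(dataset, feature_names = default_model_features(),
                              lambda = 1e-4, outcome_threshold = 7.05) {
  check_dataset(dataset, feature_names)
  if (!"center" %in% names(dataset))
    stop("dataset needs a 'center' column")
  centers <- unique(dataset$center)
  if (length(centers) < 2) stop("need at least 2 centers")
  out <- stats::setNames(rep(NA_real_, length(centers)), centers)
  for (ct in centers) {
    tr <- dataset[dataset$center != ct, , drop = FALSE]
    te <- dataset[dataset$center == ct, , drop = FALSE]
    if ("case_id" %in% names(dataset))
      stopifnot(length(intersect(tr$case_id, te$case_id)) == 0)
    m <- fit_acidosis_model(tr, feature_names, lambda = lambda,
                            outcome_threshold = outcome_threshold)
    s <- vapply(predict(m, te[, feature_names, drop = FALSE]),
                function(p) p$risk, 0)
    if (length(unique(te$outcome)) < 2) {
      warning("center ", ct, ": single-class labels, AUC undefined")
      next
    }
    out[ct] <- auc(s, te$outcome)
  }
  out
}

#' Save / load a fitted acidosis model
#'
#' Serialises the model as versioned structured text (JSON key-value tree)
#' with full-precision decimal numbers, so coefficients round-trip
#' bit-exactly and the file stays diffable and language-neutral.
#'
#' @param model a `ctg_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ctg_model"))
  obj <- list(schema = "ctg_model/1",
              feature_names = model$feature_names,
              beta0 = model$beta0,
              beta = as.list(model$beta),
              scaler = list(center = as.list(model$scaler$center),
                            scale = as.list(model$scaler$scale)),
              lambda = model$lambda,
              outcome_threshold = model$outcome_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the `ctg_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) ctg_error(paste("no such file:", path), "ctg_io_error")
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) ctg_error(paste("unreadable model file:",
                                                      conditionMessage(e)),
                                                "ctg_load_error"))
  if (is.null(obj$schema) || obj$schema != "ctg_model/1")
    ctg_error("unsupported model schema version", "ctg_load_error")
  need <- c("feature_names", "beta0", "beta", "scaler", "outcome_threshold")
  if (!all(need %in% names(obj)))
    ctg_error(paste("model file missing block(s):",
                    paste(setdiff(need, names(obj)), collapse = ", ")),
              "ctg_load_error")
  fn <- unlist(obj$feature_names)
  if (length(obj$beta) != length(fn) ||
      length(obj$scaler$center) != length(fn))
    ctg_error("model file inconsistent: beta/scaler/feature_names lengths differ",
              "ctg_load_error")
  structure(list(feature_names = fn,
                 beta0 = as.numeric(obj$beta0),
                 beta = stats::setNames(as.numeric(unlist(obj$beta)), fn),
                 scaler = list(
                   center = stats::setNames(as.numeric(unlist(obj$scaler$center)), fn),
                   scale = stats::setNames(as.numeric(unlist(obj$scaler$scale)), fn)),
                 lambda = if (is.null(obj$lambda)) 0 else as.numeric(obj$lambda),
                 outcome_threshold = as.numeric(obj$outcome_threshold)),
            class = "ctg_model")
}
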