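# Brain-age estimation: feature assembly, linear SVR, cross-validation,
# bias adjustment, Brain-PAD, and evaluation metrics.

#' Assemble the brain-age feature matrix
#'
#' Columns follow the fixed schema: GM voxel intensities, WM voxel
#' intensities, CSF voxel intensities (in-mask voxels only, all subjects on a
#' common mask), then total GM/WM/CSF volumes and TIV (ml), sex (F = 0,
#' M = 1), scanner-vendor indicator columns (one-hot, first level dropped;
#' a single vendor keeps one constant indicator so the attribute always
#' occupies a column), and field strength. With V in-mask voxels and a single
#' vendor level the matrix has 3V + 7 columns.
#'
#' @param maps Named list per subject of `gm`/`wm`/`csf` [voxel_grid]s.
#' @param pheno Phenotype table; rows define subject order.
#' @param volumes Optional named list of precomputed [tissue_volumes()]
#'   results; computed from `maps` when `NULL`.
#' @return Numeric matrix with attribute `schema` (column block descriptor).
#' @export
assemble_features <- function(maps, pheno, volumes = NULL) {
  if (nrow(pheno) == 0) stop("no subjects to assemble features for", call. = FALSE)
  ids <- pheno$subject_id
  for (id in ids) {
    m <- maps[[id]]
    if (is.null(m) || !all(c("gm", "wm", "csf") %in% names(m)))
      stop("subject missing a tissue map: ", id, call. = FALSE)
  }
  gm <- stack_maps(maps, "gm", ids)
  wm <- stack_maps(maps, "wm", ids)
  csf <- stack_maps(maps, "csf", ids)
  if (is.null(volumes)) {
    volumes <- lapply(ids, function(id)
      tissue_volumes(maps[[id]]$gm, maps[[id]]$wm, maps[[id]]$csf))
    names(volumes) <- ids
  }
  vol <- t(vapply(ids, function(id)
    unlist(volumes[[id]][c("gm_ml", "wm_ml", "csf_ml", "tiv_ml")]),
    numeric(4)))
  colnames(vol) <- c("gm_total", "wm_total", "csf_total", "tiv")
  sex <- as.numeric(pheno$sex == "M")
  vendors <- sort(unique(pheno$vendor))
  # drop-first indicators; a single level keeps its (constant) indicator so
  # the vendor attribute always occupies at least one column
  ind_levels <- if (length(vendors) > 1) vendors[-1] else vendors
  vend <- vapply(ind_levels, function(v) as.numeric(pheno$vendor == v),
                 numeric(nrow(pheno)))
  vend <- matrix(vend, nrow = nrow(pheno),
                 dimnames = list(NULL, paste0("vendor_", ind_levels)))
  V <- ncol(gm)
  colnames(gm) <- sprintf("gm_v%04d", seq_len(V))
  colnames(wm) <- sprintf("wm_v%04d", seq_len(V))
  colnames(csf) <- sprintf("csf_v%04d", seq_len(V))
  X <- cbind(gm, wm, csf, vol, sex = sex, vend,
             field_strength = pheno$field_strength)
  rownames(X) <- ids
  structure(X, schema = list(n_voxels = V, vendors = vendors,
                             columns = colnames(X)),
            mask = attr(gm, "mask"), spacing = attr(gm, "spacing"))
}

#' Split healthy controls into training and hold-out sets
#'
#' Rounds `fraction` of the healthy subjects (groups beginning with `"HC"`)
#' into training; the rest are held out. Disjoint, exhaustive, deterministic
#' given `seed`.
#'
#' @param pheno Phenotype table.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed (sub-stream `"split"`).
#' @return List with `train` and `holdout` subject-id vectors.
#' @export
split_train_holdout <- function(pheno, fraction = 0.9, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  hc <- pheno$subject_id[startsWith(as.character(pheno$group), "HC")]
  if (length(hc) < 2) stop("need at least 2 healthy subjects to split", call. = FALSE)
  n_train <- round(length(hc) * fraction)
  n_train <- min(max(n_train, 1L), length(hc) - 1L)
  with_substream(seed, "split", {
    train <- sort(sample(hc, n_train))
    list(train = train, holdout = sort(setdiff(hc, train)))
  })
}

#' Train the linear support-vector age regressor
#'
#' Features are z-scored with training-set statistics (constant columns get
#' unit scale) and an epsilon-insensitive linear SVR is fit (default cost 1,
#' epsilon 0.1). The fitted model is stored as an explicit weight vector and
#' intercept, so predictions are a single matrix product.
#'
#' @param features Feature matrix (subjects x features).
#' @param ages Chronological ages, years, all positive.
#' @param hyperparams List with `cost` and `epsilon`.
#' @param seed Stored in the model metadata (training itself is
#'   deterministic).
#' @return An `age_model` with elements `weights`, `intercept`, `center`,
#'   `scale`, `bias_alpha`, `bias_beta` (NA until [fit_bias_adjustment()] is
#'   applied), and `meta`.
#' @export
train_age_model <- function(features, ages, hyperparams = list(cost = 1, epsilon = 0.1),
                            seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 10) stop("need at least 10 training subjects", call. = FALSE)
  if (length(ages) != n) stop("`ages` length must match rows of `features`", call. = FALSE)
  if (any(!is.finite(ages)) || any(ages <= 0)) stop("ages must be positive", call. = FALSE)
  if (stats::var(ages) == 0)
    stop("degenerate target: training ages are constant", call. = FALSE)
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(features, 2, center), 2, scale, "/")
  fit <- e1071::svm(x = Xs, y = ages, type = "eps-regression", kernel = "linear",
                    cost = hyperparams$cost %||% 1,
                    epsilon = hyperparams$epsilon %||% 0.1,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  structure(list(weights = w, intercept = -fit$rho,
                 center = center, scale = scale,
                 bias_alpha = NA_real_, bias_beta = NA_real_,
                 schema = attr(features, "schema"),
                 meta = list(n = n, seed = seed,
                             hyperparams = list(cost = hyperparams$cost %||% 1,
                                                epsilon = hyperparams$epsilon %||% 0.1))),
            class = "age_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname train_age_model
#' @param object An `age_model`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Predicted ages in years.
#' @export
predict.age_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights))
    stop("feature count mismatch with trained model", call. = FALSE)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  drop(Xs %*% object$weights) + object$intercept
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> linear SVR, %d features, n = %d, cost = %g, epsilon = %g\n",
              length(x$weights), x$meta$n, x$meta$hyperparams$cost,
              x$meta$hyperparams$epsilon))
  if (is.finite(x$bias_alpha))
    cat(sprintf("  bias adjustment: alpha = %.4f, beta = %.2f\n",
                x$bias_alpha, x$bias_beta))
  invisible(x)
}

#' k-fold cross-validated age-prediction metrics
#'
#' Subjects are partitioned into `k` seeded random folds; each subject is
#' predicted exactly once by a model trained without it, and metrics are
#' pooled over all out-of-fold predictions.
#'
#' @param features Feature matrix.
#' @param ages Ages in years.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed (sub-stream `"cv"`).
#' @param hyperparams Passed to [train_age_model()].
#' @return [evaluate_predictions()] metrics with attribute `predictions`
#'   (out-of-fold, in subject order).
#' @export
crossval_metrics <- function(features, ages, k = 10, seed = 1L,
                             hyperparams = list(cost = 1, epsilon = 0.1)) {
  n <- nrow(features)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (k > n) stop("`k` must not exceed the number of subjects", call. = FALSE)
  fold <- with_substream(seed, "cv", sample(rep_len(seq_len(k), n)))
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_age_model(features[!test, , drop = FALSE], ages[!test],
                             hyperparams = hyperparams, seed = seed)
    pred[test] <- predict(model, features[test, , drop = FALSE])
  }
  structure(evaluate_predictions(pred, ages), predictions = pred, folds = fold)
}

#' Fit the brain-age bias adjustment
#'
#' Ordinary least squares of the prediction offset (predicted minus actual
#' age) on actual age: `offset = alpha * actual + beta`. Intended to be fit on
#' the training set only and frozen for hold-out and disease-group
#' application; it removes the systematic age-dependence (regression
#' dilution) of the raw predictions.
#'
#' @param predicted,actual Ages in years, `n >= 3`, `var(actual) > 0`.
#' @return Named vector `c(alpha = , beta = )`.
#' @examples
#' a <- 40:60
#' fit_bias_adjustment(0.5 * a + 30, a) # alpha -0.5, beta 30
#' @export
fit_bias_adjustment <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch", call. = FALSE)
  if (length(actual) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (stats::var(actual) == 0) stop("zero age variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, actual), predicted - actual)
  c(alpha = unname(fit$coefficients[2]), beta = unname(fit$coefficients[1]))
}

#' @rdname fit_bias_adjustment
#' @param alpha,beta Coefficients from [fit_bias_adjustment()].
#' @return Bias-adjusted predicted ages: `predicted - (alpha * actual + beta)`.
#' @export
apply_bias_adjustment <- function(predicted, actual, alpha, beta) {
  if (length(predicted) != length(actual)) stop("length mismatch", call. = FALSE)
  predicted - (alpha * actual + beta)
}

#' Brain-predicted age difference
#'
#' Elementwise model-estimated (bias-adjusted) age minus actual age. Negative
#' values indicate a younger-looking brain, positive an older-looking brain.
#'
#' @param corrected_predicted,actual Ages in years, equal length.
#' @return Brain-PAD in years.
#' @examples
#' brainpad(65, 60) # +5, older-looking
#' @export
brainpad <- function(corrected_predicted, actual) {
  if (length(corrected_predicted) != length(actual))
    stop("length mismatch", call. = FALSE)
  corrected_predicted - actual
}

#' Age-prediction evaluation metrics
#'
#' MAE, RMSE, R-squared about the mean of `actual`, and the mean Brain-PAD
#' (predicted minus actual) with a normal-approximation 95% confidence
#' interval (mean +/- 1.96 * SE).
#'
#' @param predicted,actual Ages in years, `n >= 2`.
#' @return A `fit_metrics` list: `mae`, `rmse`, `r2`, `mean_pad`, `pad_ci95`
#'   (low, high), `n`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch", call. = FALSE)
  n <- length(actual)
  if (n < 2) stop("need at least 2 subjects (CI undefined)", call. = FALSE)
  err <- predicted - actual
  se <- stats::sd(err) / sqrt(n)
  sst <- sum((actual - mean(actual))^2)
  structure(list(mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 r2 = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
                 mean_pad = mean(err),
                 pad_ci95 = c(mean(err) - 1.96 * se, mean(err) + 1.96 * se),
                 n = n),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.2f y  RMSE = %.2f y  R2 = %.3f  mean PAD = %.2f y (95%% CI %.2f, %.2f)\n",
              x$n, x$mae, x$rmse, x$r2, x$mean_pad, x$pad_ci95[1], x$pad_ci95[2]))
  invisible(x)
}

# Model serialization ----------------------------------------------------------

#' Save / load an age model
#'
#' JSON header (schema, hyperparameters, bias coefficients) plus the weight
#' and standardization arrays, in one JSON file.
#'
#' @param model An `age_model`.
#' @param path Output path (`.json`).
#' @return `path` invisibly; `read_age_model` returns the `age_model`.
#' @export
write_age_model <- function(model, path) {
  stopifnot(inherits(model, "age_model"))
  payload <- list(header = list(schema = model$schema, meta = model$meta,
                                bias_alpha = model$bias_alpha,
                                bias_beta = model$bias_beta,
                                intercept = model$intercept),
                  weights = unname(model$weights),
                  center = unname(model$center),
                  scale = unname(model$scale),
                  feature_names = names(model$weights))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = stats::setNames(p$weights, p$feature_names),
                 intercept = p$header$intercept,
                 center = stats::setNames(p$center, p$feature_names),
                 scale = stats::setNames(p$scale, p$feature_names),
                 bias_alpha = p$header$bias_alpha %||% NA_real_,
                 bias_beta = p$header$bias_beta %||% NA_real_,
                 schema = p$header$schema, meta = p$header$meta),
            class = "age_model")
}
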