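test_that("feature assembly follows the fixed column schema", {
  maps <- tiny_maps(n_subjects = 3)
  pheno <- tiny_pheno_for(maps)
  X <- assemble_features(maps, pheno)
  V <- sum(maps[[1]]$gm$mask)
  expect_equal(ncol(X), 3 * V + 7) # single vendor: one (constant) indicator
  expect_equal(rownames(X), pheno$subject_id)
  sch <- attr(X, "schema")
  expect_equal(sch$n_voxels, V)
  expect_equal(utils::tail(sch$columns, 7),
               c("gm_total", "wm_total", "csf_total", "tiv", "sex",
                 "vendor_GE", "field_strength"))
  expect_equal(unname(X[, "sex"]), as.numeric(pheno$sex == "M"))

  # two vendors: one drop-first indicator, still 3V + 7
  pheno2 <- pheno
  pheno2$vendor <- c("GE", "Siemens", "Siemens")
  X2 <- assemble_features(maps, pheno2)
  expect_equal(ncol(X2), 3 * V + 7)
  expect_true("vendor_Siemens" %in% colnames(X2))

  expect_error(assemble_features(maps, pheno[0, ]), "no subjects")
  maps_broken <- maps
  maps_broken[[2]]$wm <- NULL
  expect_error(assemble_features(maps_broken, pheno), pheno$subject_id[2])
})

test_that("train/hold-out split is disjoint, exhaustive and reproducible", {
  pheno <- data.frame(subject_id = sprintf("H%04d", 1:1054),
                      group = "HC_train", stringsAsFactors = FALSE)
  sp <- split_train_holdout(pheno, 0.9, seed = 3)
  expect_length(sp$train, 949)
  expect_length(sp$holdout, 105)
  expect_length(intersect(sp$train, sp$holdout), 0)
  expect_setequal(c(sp$train, sp$holdout), pheno$subject_id)
  expect_identical(sp, split_train_holdout(pheno, 0.9, seed = 3))

  small <- pheno[1:10, ]
  sp10 <- split_train_holdout(small, 0.9, seed = 1)
  expect_length(sp10$train, 9)
  expect_length(sp10$holdout, 1)
  expect_error(split_train_holdout(pheno, 1.2), "fraction")
})

test_that("the linear SVR behaves like its generative limits", {
  withr::with_seed(31, {
    ages <- runif(120, 30, 80)
    # a single feature equal to age, negligible regularization: near identity
    X1 <- matrix(ages, ncol = 1)
    m1 <- train_age_model(X1, ages, hyperparams = list(cost = 100, epsilon = 0.1))
    expect_lt(max(abs(predict(m1, X1) - ages)), 0.5)

    # pure-noise features: hold-out MAE close to the best constant predictor
    # (brute-force oracle under absolute loss)
    Xn <- matrix(rnorm(120 * 5), 120)
    tr <- 1:80; ho <- 81:120
    mn <- train_age_model(Xn[tr, ], ages[tr])
    grid <- seq(min(ages), max(ages), by = 0.05)
    best_c <- grid[which.min(vapply(grid, function(cc)
      mean(abs(ages[tr] - cc)), numeric(1)))]
    oracle_mae <- mean(abs(ages[ho] - best_c))
    model_mae <- mean(abs(predict(mn, Xn[ho, ]) - ages[ho]))
    expect_lt(abs(model_mae - oracle_mae), 0.25 * oracle_mae)

    # duplicated feature columns leave predictions unchanged
    Xd <- cbind(X1, X1)
    md <- train_age_model(Xd, ages, hyperparams = list(cost = 100, epsilon = 0.1))
    expect_equal(predict(md, Xd), predict(m1, X1), tolerance = 1e-6)

    expect_error(train_age_model(X1, rep(50, 120)), "constant")
    expect_error(train_age_model(X1[1:5, , drop = FALSE], ages[1:5]), "10")
  })
})

test_that("cross-validation predicts every subject exactly once", {
  withr::with_seed(13, {
    ages <- runif(200, 30, 80)
    X <- matrix(ages + rnorm(200, 0, 0.01), ncol = 1)
    cv <- crossval_metrics(X, ages, k = 10, seed = 2,
                           hyperparams = list(cost = 100, epsilon = 0.1))
    folds <- attr(cv, "folds")
    expect_equal(sort(unique(folds)), 1:10)
    expect_true(all(table(folds) %in% c(20)))
    expect_true(all(is.finite(attr(cv, "predictions"))))
    # noiseless linear generative data: pooled MAE below 1 y
    expect_lt(cv$mae, 1)

    # leave-one-out boundary
    ages12 <- runif(12, 40, 60)
    X12 <- matrix(ages12, ncol = 1)
    loo <- crossval_metrics(X12, ages12, k = 12, seed = 1)
    expect_true(is.finite(loo$mae) && is.finite(loo$rmse))
    expect_error(crossval_metrics(X12, ages12, k = 13), "exceed")
    expect_error(crossval_metrics(X12, ages12, k = 1), "at least 2")
  })
})

test_that("bias adjustment solves the offset-on-age regression exactly", {
  a <- seq(35, 75, length.out = 21)
  expect_equal(fit_bias_adjustment(a, a), c(alpha = 0, beta = 0))
  expect_equal(fit_bias_adjustment(0.5 * a + 30, a), c(alpha = -0.5, beta = 30))
  expect_equal(fit_bias_adjustment(a + 2, a), c(alpha = 0, beta = 2))
  expect_error(fit_bias_adjustment(a[1:2], a[1:2]), "at least 3")
  expect_error(fit_bias_adjustment(rep(1, 5), rep(50, 5)), "variance")

  # algebraic substitution: correcting the 0.5a + 30 case recovers actual age
  ab <- fit_bias_adjustment(0.5 * a + 30, a)
  corrected <- apply_bias_adjustment(0.5 * a + 30, a, ab["alpha"], ab["beta"])
  expect_equal(unname(corrected), unname(a), tolerance = 1e-10)
  expect_equal(unname(brainpad(corrected, a)), rep(0, 21), tolerance = 1e-10)

  # identity when alpha = beta = 0
  expect_equal(apply_bias_adjustment(a + 1, a, 0, 0), a + 1)

  # OLS residual identity on arbitrary data
  withr::with_seed(7, {
    actual <- runif(50, 30, 80)
    pred <- 0.8 * actual + rnorm(50, 5, 3)
    ab2 <- fit_bias_adjustment(pred, actual)
    pad <- brainpad(apply_bias_adjustment(pred, actual, ab2["alpha"], ab2["beta"]),
                    actual)
    expect_lt(abs(mean(pad)), 1e-10)
    expect_lt(abs(cor(pad, actual)), 1e-10)
  })
})

test_that("Brain-PAD keeps the older-minus-younger sign convention", {
  expect_equal(brainpad(65, 60), 5)
  expect_equal(brainpad(55, 60), -5)
  expect_equal(brainpad(c(50, 60), c(50, 60)), c(0, 0))
  expect_error(brainpad(1:3, 1:2), "length")
})

test_that("evaluation metrics match direct arithmetic", {
  a <- c(50, 60, 70, 80)
  m0 <- evaluate_predictions(a, a)
  expect_equal(m0$mae, 0); expect_equal(m0$rmse, 0)
  expect_equal(m0$r2, 1); expect_equal(m0$mean_pad, 0)

  m1 <- evaluate_predictions(a + c(2, -2, 2, -2), a)
  expect_equal(m1$mae, 2)
  expect_equal(m1$rmse, 2)
  expect_equal(m1$mean_pad, 0)

  m2 <- evaluate_predictions(rep(mean(a), 4), a)
  expect_equal(m2$r2, 0)
  expect_error(evaluate_predictions(50, 50), "at least 2")
})

test_that("hold-out metrics are invariant to subject ordering", {
  withr::with_seed(17, {
    pred <- runif(40, 40, 80)
    act <- pred + rnorm(40)
    perm <- sample(40)
    m1 <- evaluate_predictions(pred, act)
    m2 <- evaluate_predictions(pred[perm], act[perm])
    expect_equal(m1[c("mae", "rmse", "r2", "mean_pad")],
                 m2[c("mae", "rmse", "r2", "mean_pad")])
  })
})

test_that("age models round-trip through JSON serialization", {
  withr::with_seed(23, {
    ages <- runif(30, 30, 80)
    X <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
    m <- train_age_model(X, ages)
    m$bias_alpha <- -0.1; m$bias_beta <- 4
    path <- tempfile(fileext = ".json")
    write_age_model(m, path)
    m2 <- read_age_model(path)
    expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
    expect_equal(m2$bias_alpha, -0.1)
    expect_equal(m2$meta$hyperparams$cost, 1)
  })
})
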