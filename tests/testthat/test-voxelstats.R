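# Small synthetic map stacks built directly as matrices, with grid metadata
# attached the way stack_maps() does.
make_stack <- function(n, shape = c(6L, 6L, 6L), spacing = 8, seed = 1,
                       signal = NULL, pad = NULL) {
  withr::with_seed(seed, {
    mask <- array(TRUE, shape)
    V <- prod(shape)
    Y <- matrix(rnorm(n * V, 0.4, 0.05), n, V)
    if (!is.null(signal)) Y <- Y + outer(pad, signal)
    affine <- rbind(cbind(diag(rep(spacing, 3)), -spacing * (shape - 1) / 2),
                    c(0, 0, 0, 1))
    structure(Y, mask = mask, spacing = rep(spacing, 3), affine = affine)
  })
}

test_that("single-voxel mass-univariate fits equal the OLS battery fit", {
  withr::with_seed(61, {
    n <- 40
    pad <- rnorm(n, 3, 2); age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
    Y <- make_stack(n, c(2L, 2L, 2L), seed = 62)
    design <- data.frame(intercept = 1, pad = pad, age = age, sex = sex)
    stat <- massuni_fit(Y, design, "pad")
    for (v in c(1, 5, 8)) {
      d <- data.frame(y = Y[, v], pad = pad, age = age, sex = sex)
      ref <- fit_ols("y", c("pad", "age", "sex"), d)
      expect_equal(stat$t[v], ref$t[ref$term == "pad"], tolerance = 1e-10)
      expect_equal(stat$beta[v], ref$b[ref$term == "pad"], tolerance = 1e-10)
      expect_equal(stat$df, attr(ref, "df_residual"))
    }
  })
})

test_that("null t-maps follow the Student t reference distribution", {
  withr::with_seed(63, {
    n <- 40
    pad <- rnorm(n); age <- runif(n, 40, 80)
    Y <- make_stack(n, c(8L, 8L, 8L), seed = 64)
    stat <- massuni_fit(Y, data.frame(intercept = 1, pad = pad, age = age),
                        "pad")
    df <- stat$df
    expect_lt(abs(mean(stat$t)), 0.1)
    expect_lt(abs(var(stat$t) - df / (df - 2)), 0.2)
  })
})

test_that("injected signal localizes and duplicate columns are rejected", {
  withr::with_seed(65, {
    n <- 60
    pad <- rnorm(n, 0, 2)
    shape <- c(6L, 6L, 6L)
    signal <- numeric(prod(shape))
    block <- which(array(slice.index(array(0, shape), 1) <= 2, shape))
    signal[block] <- 0.02
    Y <- make_stack(n, shape, seed = 66, signal = signal, pad = pad)
    design <- data.frame(intercept = 1, pad = pad)
    stat <- massuni_fit(Y, design, "pad")
    expect_true(which.max(abs(stat$t)) %in% block)
    design$pad2 <- design$pad
    expect_error(massuni_fit(Y, design, "pad"), "collinear")
    expect_error(massuni_fit(Y[1:5, ], design[1:5, 1:2], "pad"), "10")
  })
})

test_that("permutation FWE p-values are monotone in |t| and deterministic", {
  withr::with_seed(67, {
    n <- 30
    pad <- rnorm(n); age <- runif(n, 40, 80)
    Y <- make_stack(n, c(4L, 4L, 4L), seed = 68)
    design <- data.frame(intercept = 1, pad = pad, age = age)
    p1 <- fwe_correct(Y, design, "pad", n_perm = 150, seed = 4)
    p2 <- fwe_correct(Y, design, "pad", n_perm = 150, seed = 4)
    expect_equal(p1, p2)
    tv <- abs(attr(p1, "t"))
    ord <- order(tv)
    expect_true(all(diff(as.numeric(p1)[ord]) <= 1e-12))
    expect_error(fwe_correct(Y, design, "pad", n_perm = 50), "100")
  })
})

test_that("cluster extraction applies extent, size and coordinate rules", {
  shape <- c(10L, 10L, 10L)
  mask <- array(TRUE, shape)
  spacing <- c(8, 8, 8)
  affine <- rbind(cbind(diag(spacing), -spacing * (shape - 1) / 2),
                  c(0, 0, 0, 1))
  tvec <- rep(0.1, prod(shape))
  pvec <- rep(1, prod(shape))
  stat <- structure(list(t = tvec, beta = tvec, df = 30, contrast = "pad",
                         n_undefined = 0, mask = mask, spacing = spacing,
                         affine = affine), class = "stat_map")
  # no suprathreshold voxels: empty table
  expect_equal(nrow(extract_clusters(stat, pvec, 0.05, 1)), 0)

  # a 5-voxel blob is dropped at min extent 100
  blob5 <- which(array(seq_len(prod(shape)), shape) <= 5)
  stat5 <- stat; stat5$t[blob5] <- -6; p5 <- pvec; p5[blob5] <- 0.001
  expect_equal(nrow(extract_clusters(stat5, p5, 0.05, 100)), 0)
  expect_equal(nrow(extract_clusters(stat5, p5, 0.05, 5)), 1)

  # a 200-voxel blob: 200 x 0.512 ml = 102.4 ml, peak at the injected centre
  arr <- array(FALSE, shape)
  arr[2:6, 2:6, 2:9] <- TRUE # 5*5*8 = 200 voxels
  blob <- which(arr)
  stat200 <- stat
  stat200$t[blob] <- -5
  centre <- c(4L, 4L, 5L)
  centre_idx <- centre[1] + (centre[2] - 1) * 10 + (centre[3] - 1) * 100
  stat200$t[centre_idx] <- -8
  p200 <- pvec; p200[blob] <- 0.001
  cl <- extract_clusters(stat200, p200, 0.05, 100)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size_voxels, 200)
  expect_equal(cl$size_ml, 102.4)
  expect_equal(cl$peak_t, -8)
  expect_equal(cl$sign, "neg")
  world <- affine %*% c(centre - 1, 1)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z), world[1:3])
  expect_equal(cl$hemisphere, if (world[1] < 0) "L" else "R")
})

test_that("cluster labels are invariant to component ordering", {
  shape <- c(8L, 8L, 8L)
  mask <- array(TRUE, shape)
  spacing <- c(8, 8, 8)
  affine <- rbind(cbind(diag(spacing), rep(0, 3)), c(0, 0, 0, 1))
  tvec <- rep(0, prod(shape))
  arrA <- array(FALSE, shape); arrA[1:2, 1:2, 1:2] <- TRUE
  arrB <- array(FALSE, shape); arrB[6:8, 6:8, 6:8] <- TRUE
  tvec[which(arrA)] <- -4; tvec[which(arrB)] <- -5
  pv <- rep(1, prod(shape)); pv[tvec < 0] <- 0.01
  stat <- structure(list(t = tvec, beta = tvec, df = 20, contrast = "pad",
                         n_undefined = 0, mask = mask, spacing = spacing,
                         affine = affine), class = "stat_map")
  cl <- extract_clusters(stat, pv, 0.05, 1)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$size_voxels, c(8, 27))
})

test_that("slope contrasts are antisymmetric and localize interactions", {
  withr::with_seed(71, {
    n <- 80
    grp <- rep(c("HC", "PD"), each = n / 2)
    pad <- rnorm(n, ifelse(grp == "PD", 3, 0), 2)
    shape <- c(6L, 6L, 6L)
    signal <- numeric(prod(shape))
    region <- which(array(slice.index(array(0, shape), 3) >= 5, shape))
    # HC-only negative slope in the region; PD slope zero
    Y <- make_stack(n, shape, seed = 72)
    Y[grp == "HC", region] <- Y[grp == "HC", region] -
      0.03 * pad[grp == "HC"]
    stat <- slope_contrast(Y, pad, grp)
    expect_true(which.max(abs(stat$t)) %in% region)
    # swapping which group is coded 1 flips the interaction map's sign
    grp2 <- ifelse(grp == "HC", "ZZ", "AA")
    stat2 <- slope_contrast(Y, pad, grp2)
    expect_equal(stat2$t, -stat$t, tolerance = 1e-10)
    expect_error(slope_contrast(Y[1:12, ], pad[1:12],
                                rep(c("a", "b"), c(3, 9))), "at least 10")
  })
})

test_that("ROI correlations behave at their analytic limits", {
  withr::with_seed(73, {
    n <- 30
    pad <- rnorm(n, 2, 1.5)
    Y <- make_stack(n, c(4L, 4L, 4L), seed = 74)
    grp <- rep("PD", n)
    # make mean cluster value exactly linear in pad
    Y[, 1:8] <- 0.5 - 0.01 * pad
    rc <- roi_correlation(1:8, Y, pad, grp)
    expect_equal(rc$r, -1, tolerance = 1e-10)

    # permuted pad: negligible correlation on independent columns
    rc2 <- roi_correlation(33:64, Y, sample(pad), grp)
    expect_lt(abs(rc2$r), 0.5)

    expect_error(roi_correlation(integer(0), Y, pad, grp), "empty")
    expect_error(roi_correlation(1:8, Y, rep(1, n), grp), "constant")
    expect_error(roi_correlation(1:8, Y[1:2, ], pad[1:2], grp[1:2]), "fewer")
  })
})
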