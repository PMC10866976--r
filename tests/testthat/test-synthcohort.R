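test_that("phenotype generation honours group structure and the gap latent", {
  # no-disease cohort
  s0 <- tiny_spec(n_pd = 0)
  p0 <- generate_phenotypes(s0)
  expect_true(all(startsWith(p0$group, "HC")))
  expect_true(all(p0$true_gap == 0))

  # degenerate gap distribution
  s1 <- tiny_spec(n_pd = 12, pad_gap_sd = 0, pad_gap_mean_m = 3.5,
                  pad_gap_mean_f = 1.8)
  p1 <- generate_phenotypes(s1)
  pd_m <- p1[p1$group == "PD" & p1$sex == "M", ]
  expect_true(all(pd_m$true_gap == 3.5))
  expect_true(all(p1$true_gap[p1$group == "PD" & p1$sex == "F"] == 1.8))
  expect_true(all(p1$true_gap[p1$group != "PD"] == 0))

  # disease duration bookkeeping (months from diagnosis age to scan age)
  pd <- p1[p1$group == "PD", ]
  expect_equal(pd$disease_duration, round(12 * (pd$age - pd$diagnosis_age)))
  expect_true(all(pd$age >= s1$age_range[1] & pd$age <= s1$age_range[2]))

  # sex composition within the binomial 99% interval of the target fraction
  s2 <- cohort_spec(n_hc_train = 10, n_hc_holdout = 2, n_pd = 400, seed = 42)
  p2 <- generate_phenotypes(s2)
  n_f <- sum(p2$sex[p2$group == "PD"] == "F")
  bounds <- qbinom(c(0.005, 0.995), 400, 0.34)
  expect_gte(n_f, bounds[1])
  expect_lte(n_f, bounds[2])
})

test_that("generation is bit-identical under a fixed spec and seed", {
  s <- tiny_spec(seed = 9)
  p1 <- generate_phenotypes(s)
  p2 <- generate_phenotypes(s)
  expect_identical(p1, p2)
  m1 <- generate_tissue_maps(p1, s)
  m2 <- generate_tissue_maps(p2, s)
  expect_identical(m1, m2)
})

test_that("the noiseless generative model is exactly linear in effective age", {
  base <- tiny_spec(n_hc_train = 0, n_hc_holdout = 0, n_pd = 4,
                    noise_sd = 0, tiv_cv = 0, pad_gap_sd = 0,
                    atrophy_rate_map = -0.002,
                    sex_offset_map = 0,
                    scanner_levels = data.frame(vendor = "GE",
                                                field_strength = 1.5,
                                                offset = 0, noise_scale = 1))
  pheno <- generate_phenotypes(base)
  # null generative model: no atrophy either -> identical subjects
  null_spec <- base
  null_spec$atrophy_rate_map <- 0
  pheno_same <- pheno
  pheno_same$sex <- "M"
  m0 <- generate_tissue_maps(pheno_same, null_spec)
  for (i in 2:4) expect_identical(m0[[i]], m0[[1]])

  # uniform atrophy: ages 50 vs 60 differ by exactly -0.02 at in-mask voxels
  ph <- pheno[1:2, ]
  ph$sex <- "M"; ph$age <- c(50, 60); ph$true_gap <- 0; ph$head_scale <- 1
  mm <- generate_tissue_maps(ph, base)
  mask <- mm[[1]]$gm$mask
  d <- mm[[2]]$gm$values[mask] - mm[[1]]$gm$values[mask]
  expect_true(all(abs(d - (-0.02)) < 1e-12))

  # the gap latent is an effective-age shift: (age, gap g) == (age + g, 0)
  ph2 <- pheno[1:2, ]
  ph2$sex <- "F"; ph2$age <- c(55, 60); ph2$true_gap <- c(5, 0)
  ph2$head_scale <- 1
  mg <- generate_tissue_maps(ph2, base)
  expect_equal(mg[[1]]$gm$values, mg[[2]]$gm$values, tolerance = 1e-12)
  expect_equal(mg[[1]]$csf$values, mg[[2]]$csf$values, tolerance = 1e-12)
})

test_that("tissue maps respect probability bounds and the unit-sum ceiling", {
  s <- tiny_spec(n_pd = 10, noise_sd = 0.05, seed = 4)
  maps <- generate_tissue_maps(generate_phenotypes(s), s)
  for (m in maps[1:5]) {
    tot <- m$gm$values + m$wm$values + m$csf$values
    expect_true(all(tot <= 1 + 1e-9))
    for (tis in m) {
      expect_true(all(tis$values >= 0 & tis$values <= 1))
    }
  }
})

test_that("unknown vendors and invalid specs are rejected with named fields", {
  s <- tiny_spec()
  p <- generate_phenotypes(s)
  p$vendor[1] <- "Canon"
  expect_error(generate_tissue_maps(p, s), "Canon")
  expect_error(cohort_spec(n_hc_train = -1), "n_hc_train")
  expect_error(cohort_spec(age_range = c(90, 20)), "age_range")
  expect_error(cohort_spec(pad_gap_sd = -1), "pad_gap_sd")
  expect_error(tiny_spec(atrophy_rate_map = 0.01), "atrophy_rate_map")
})

test_that("paper-scale preset pins the mask to 3747 in-mask voxels", {
  s <- cohort_spec(preset = "paper", n_hc_train = 10, n_hc_holdout = 2,
                   n_pd = 2)
  expect_equal(sum(cohort_mask(s)), 3747)
})

test_that("clinical scores follow their generating equations", {
  s <- tiny_spec(n_pd = 30, pad_gap_sd = 2, seed = 6)
  pheno <- generate_phenotypes(s)

  # all coefficients zero, zero residual sd: outcomes constant at intercept
  eff0 <- null_effect_spec()
  for (nm in names(eff0)) eff0[[nm]]$sd <- 0
  for (nm in names(eff0)) eff0[[nm]]$missing <- 0
  eff0$UPDRS3_total$coefs["intercept"] <- 20
  g0 <- generate_clinical_scores(pheno, eff0, seed = 1)
  pd <- g0$pheno$group == "PD"
  expect_true(all(g0$pheno$UPDRS3_total[pd] == 20))
  expect_true(all(g0$pheno$MoCA[pd] == 0))
  expect_true(all(is.na(g0$pheno$UPDRS3_total[!pd])))

  # noiseless linear: UPDRS = intercept + 0.3 * true_gap exactly
  eff1 <- eff0
  eff1$UPDRS3_total$coefs["pad"] <- 0.3
  g1 <- generate_clinical_scores(pheno, eff1, seed = 1)
  expect_equal(g1$pheno$UPDRS3_total[pd], 20 + 0.3 * pheno$true_gap[pd],
               tolerance = 1e-12)
  # ground truth returned alongside
  expect_equal(g1$coefficients$UPDRS3_total$coefs[["pad"]], 0.3)

  # missingness near its binomial expectation
  s2 <- cohort_spec(n_hc_train = 2, n_hc_holdout = 2, n_pd = 1000, seed = 8)
  p2 <- generate_phenotypes(s2)
  effm <- clinical_effect_spec(list(MoCA = list(missing = 0.1)))
  g2 <- generate_clinical_scores(p2, effm, seed = 8)
  n_missing <- sum(is.na(g2$pheno$MoCA[g2$pheno$group == "PD"]))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])

  expect_error(clinical_effect_spec(list(nonsense = list(sd = 1))), "nonsense")
})

test_that("cohorts round-trip through CSV/NIfTI/JSON on disk", {
  s <- tiny_spec(n_hc_train = 3, n_hc_holdout = 2, n_pd = 3)
  clin <- generate_clinical_scores(generate_phenotypes(s),
                                   clinical_effect_spec(), seed = 1)
  maps <- generate_tissue_maps(clin$pheno, s)
  dir <- withr::local_tempdir()
  write_cohort(clin$pheno, maps, clin$coefficients, dir)
  p2 <- read_cohort_pheno(dir)
  expect_equal(p2$subject_id, clin$pheno$subject_id)
  expect_equal(p2$age, clin$pheno$age, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "mask.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  g <- read_grid_nifti(file.path(dir, sprintf("%s_gm.nii.gz",
                                              clin$pheno$subject_id[1])), "GM")
  expect_equal(g$values, maps[[1]]$gm$values, tolerance = 1e-6)
})
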