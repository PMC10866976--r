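# Shared fixtures: small cohort specs and a compact brain-age pipeline used
# by recovery and acceptance tests (simulate -> features -> CV -> train ->
# CV-fit bias adjustment -> Brain-PAD).

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_hc_train = 30, n_hc_holdout = 5, n_pd = 20,
                   grid_shape = c(8L, 8L, 8L), noise_sd = 0.01, seed = 1L)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

# Deterministic single-subject map triple on a small grid, for morphometry
# and feature tests.
tiny_maps <- function(n_subjects = 2, shape = c(6L, 6L, 6L), seed = 1) {
  withr::with_seed(seed, {
    mask <- array(FALSE, shape)
    mask[2:5, 2:5, 2:5] <- TRUE
    out <- lapply(seq_len(n_subjects), function(i) {
      mk <- function(tissue, base) {
        v <- array(0, shape)
        v[mask] <- base + stats::runif(sum(mask), -0.05, 0.05)
        voxel_grid(v, spacing = 8, mask = mask, tissue = tissue)
      }
      list(gm = mk("GM", 0.5), wm = mk("WM", 0.3), csf = mk("CSF", 0.1))
    })
    names(out) <- sprintf("S%04d", seq_len(n_subjects))
    out
  })
}

tiny_pheno_for <- function(maps) {
  n <- length(maps)
  data.frame(subject_id = names(maps),
             group = "HC_train",
             sex = rep_len(c("F", "M"), n),
             age = seq(40, 70, length.out = n),
             vendor = "GE", field_strength = 1.5,
             true_gap = 0, stringsAsFactors = FALSE)
}

# Phenotype-table column names of each model family's predictors.
battery_predictors_for_test <- function(family) {
  base <- c("pad", "age", "disease_duration", "education", "sex_code")
  switch(family,
         motor = base,
         nonmotor = c(base, "UPDRS3_total"),
         mood = c(base, "UPDRS3_total", "MoCA"))
}

# Compact estimation pipeline over package functions; bias adjustment is fit
# on out-of-fold CV predictions of the training set and frozen.
estimate_pads <- function(spec, folds = 5, eff = clinical_effect_spec()) {
  pheno <- generate_phenotypes(spec)
  clin <- generate_clinical_scores(pheno, eff, seed = spec$seed)
  pheno <- clin$pheno
  maps <- generate_tissue_maps(pheno, spec)
  features <- assemble_features(maps, pheno)
  ages <- stats::setNames(pheno$age, pheno$subject_id)
  train <- pheno$subject_id[pheno$group == "HC_train"]
  cv <- crossval_metrics(features[train, , drop = FALSE], ages[train],
                         k = folds, seed = spec$seed)
  model <- train_age_model(features[train, , drop = FALSE], ages[train],
                           seed = spec$seed)
  cv_pred <- attr(cv, "predictions")
  ab <- fit_bias_adjustment(cv_pred, ages[train])
  pred <- predict(model, features)
  corrected <- apply_bias_adjustment(pred, ages[rownames(features)],
                                     ab[["alpha"]], ab[["beta"]])
  pad <- brainpad(corrected, ages[rownames(features)])
  cv_adj <- apply_bias_adjustment(cv_pred, ages[train], ab[["alpha"]], ab[["beta"]])
  pad[train] <- brainpad(cv_adj, ages[train])
  pheno$pad <- unname(pad[pheno$subject_id])
  list(pheno = pheno, maps = maps, features = features, model = model,
       cv = cv, ab = ab, train_ids = train, raw_pred = pred)
}
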