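# Configuration, orchestration and reporting for the full synthetic study:
# simulate -> morphometry -> features -> train -> bias-adjust -> Brain-PAD ->
# match -> regression battery -> voxelwise stats -> report bundle.

#' Default run configuration
#'
#' Nested list mirroring the pipeline stages. The master `seed` determines
#' every stage's RNG sub-stream; all other values are ordinary parameters.
#' `voxelwise$min_extent` is in analysis-grid voxels (the conventional
#' 100-voxel VBM extent refers to a much finer grid; on the default 8-mm grid
#' a 10-voxel extent covers a comparable volume).
#'
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_hc_train = 200, n_hc_holdout = 22, n_pd = 100,
                  female_fraction = list(hc = 0.53, pd = 0.34),
                  age_range = c(18, 94),
                  grid_shape = c(16L, 16L, 16L),
                  voxel_spacing = 8,
                  mask_voxels = NULL,
                  wm_rate_scale = 0.4,
                  pad_gap_mean_m = 3.5, pad_gap_mean_f = 1.8, pad_gap_sd = 2,
                  tiv_cv = 0.03, noise_fwhm = 12, noise_sd = 0.02),
    morphometry = list(fwhm = 4, target_spacing = 8),
    model = list(cost = 1, epsilon = 0.1),
    folds = 10L,
    matching = list(covariates = c("age", "education", "diagnosis_age",
                                   "UPDRS3_total", "UPDRS3_rigidity",
                                   "UPDRS3_tremor", "MoCA", "REM", "ESS"),
                    ratio = 1L, caliper = NULL),
    battery = list(families = c("motor", "nonmotor", "mood")),
    voxelwise = list(n_perm = 200L, alpha = 0.05, min_extent = 10L,
                     tissues = c("gm", "wm"))),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Strict: unknown keys anywhere in the tree are errors (reported with their
#' path), and basic value constraints are checked (`folds >= 2`, positive
#' permutation counts, a valid cohort spec).
#'
#' @param config A `run_config` list.
#' @return The config, invisibly, or an error listing the problems.
#' @export
validate_config <- function(config) {
  template <- default_run_config()
  problems <- character()
  walk <- function(cfg, tmpl, path) {
    unknown <- setdiff(names(cfg), names(tmpl))
    if (length(unknown))
      problems <<- c(problems, sprintf("unknown key(s) at %s: %s", path,
                                       paste(unknown, collapse = ", ")))
    for (nm in intersect(names(cfg), names(tmpl))) {
      if (is.list(tmpl[[nm]]) && !is.data.frame(tmpl[[nm]]) &&
          !is.null(names(tmpl[[nm]]))) {
        if (is.list(cfg[[nm]]))
          walk(cfg[[nm]], tmpl[[nm]], paste0(path, "$", nm))
      }
    }
  }
  walk(config, template, "config")
  if (!is.null(config$folds) && (!is.numeric(config$folds) || config$folds < 2))
    problems <- c(problems, "config$folds: k must be >= 2")
  vw <- config$voxelwise
  if (!is.null(vw$n_perm) && vw$n_perm < 100)
    problems <- c(problems, "config$voxelwise$n_perm must be >= 100")
  if (!is.null(vw$alpha) && (vw$alpha <= 0 || vw$alpha >= 1))
    problems <- c(problems, "config$voxelwise$alpha must be in (0, 1)")
  if (length(problems) == 0) {
    spec_try <- tryCatch(as_cohort_spec(config), error = function(e) e)
    if (inherits(spec_try, "error"))
      problems <- c(problems, paste0("config$cohort: ", conditionMessage(spec_try)))
  }
  if (length(problems)) stop_invalid(problems, "run_config")
  invisible(config)
}

as_cohort_spec <- function(config) {
  ch <- config$cohort
  ff <- unlist(ch$female_fraction)
  do.call(cohort_spec, c(ch[setdiff(names(ch), "female_fraction")],
                         list(female_fraction = ff, seed = config$seed)))
}

#' Load / save a run configuration as YAML
#'
#' `load_config` merges the file over the defaults, then validates strictly
#' (unknown keys are errors). `save_config` writes the full, explicit config,
#' so `load_config(save_config(cfg))` is the identity.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (nm %in% names(base) && is.list(base[[nm]]) && is.list(new[[nm]]) &&
          !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[nm] <- list(new[[nm]]) # preserves explicit NULLs (yaml `~`)
      }
    }
    base
  }
  # unknown keys must be caught before merging silently drops nothing:
  # merge keeps them, validate_config reports them
  cfg <- merge_into(cfg, raw)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Content hash of a configuration
#'
#' MD5 of the canonical YAML serialization; stamped into every output table
#' of a report bundle.
#'
#' @param config A `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

stage_log <- function(run_env, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    if (!is.null(run_env$out_dir))
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(run_env$out_dir, "FAILED"))
    stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full synthetic study
#'
#' Executes every stage in order — simulate phenotypes, clinical scores and
#' tissue maps; smooth and resample; assemble features; 10-fold
#' cross-validation and final training on the healthy training set; bias
#' adjustment (fit on training, frozen elsewhere); Brain-PAD for every
#' subject; propensity matching of the male disease subgroup; the regression
#' battery with FDR; voxelwise Brain-PAD regressions with permutation FWE and
#' cluster tables; and a ground-truth recovery summary. Identical config and
#' seed give an identical bundle.
#'
#' @param config A `run_config` (validated on entry).
#' @param out_dir Optional output directory for the report bundle artifacts.
#' @return A `report_bundle` list.
#' @export
run_all <- function(config = default_run_config(), out_dir = NULL) {
  validate_config(config)
  run_env <- new.env()
  run_env$out_dir <- out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  sim <- stage_log(run_env, "simulate", {
    spec <- as_cohort_spec(config)
    pheno <- generate_phenotypes(spec)
    clin <- generate_clinical_scores(pheno, clinical_effect_spec(), seed = seed)
    maps <- generate_tissue_maps(clin$pheno, spec)
    message(sprintf("  simulated %d subjects (%s)", nrow(clin$pheno),
                    paste(sprintf("%s=%d", names(table(clin$pheno$group)),
                                  table(clin$pheno$group)), collapse = ", ")))
    list(spec = spec, pheno = clin$pheno, coefficients = clin$coefficients,
         maps = maps)
  })
  pheno <- sim$pheno

  proc <- stage_log(run_env, "morphometry", {
    fw <- config$morphometry$fwhm
    ts <- config$morphometry$target_spacing
    maps <- lapply(sim$maps, function(m)
      lapply(m, function(g) resample_grid(smooth_grid(g, fw), ts)))
    volumes <- lapply(maps, function(m) tissue_volumes(m$gm, m$wm, m$csf))
    list(maps = maps, volumes = volumes)
  })

  features <- stage_log(run_env, "features",
                        assemble_features(proc$maps, pheno, proc$volumes))

  fitres <- stage_log(run_env, "train", {
    train_ids <- pheno$subject_id[pheno$group == "HC_train"]
    holdout_ids <- pheno$subject_id[pheno$group == "HC_holdout"]
    ages <- stats::setNames(pheno$age, pheno$subject_id)
    cv <- crossval_metrics(features[train_ids, , drop = FALSE], ages[train_ids],
                           k = config$folds, seed = seed,
                           hyperparams = config$model)
    model <- train_age_model(features[train_ids, , drop = FALSE], ages[train_ids],
                             hyperparams = config$model, seed = seed)
    # bias adjustment is fit on the *out-of-fold* CV predictions of the
    # training set: in-sample predictions hide the regularization shrinkage
    # the adjustment exists to remove. Coefficients are frozen thereafter.
    cv_pred <- attr(cv, "predictions")
    ab <- fit_bias_adjustment(cv_pred, ages[train_ids])
    model$bias_alpha <- ab[["alpha"]]
    model$bias_beta <- ab[["beta"]]
    pred_all <- predict(model, features)
    corrected <- apply_bias_adjustment(pred_all, ages[rownames(features)],
                                       model$bias_alpha, model$bias_beta)
    pad <- brainpad(corrected, ages[rownames(features)])
    # training-set Brain-PAD is reported from the adjusted CV predictions
    # (honest out-of-fold; mean 0 and zero age-correlation by OLS identity)
    cv_corrected <- apply_bias_adjustment(cv_pred, ages[train_ids],
                                          model$bias_alpha, model$bias_beta)
    corrected[train_ids] <- cv_corrected
    pad[train_ids] <- brainpad(cv_corrected, ages[train_ids])
    list(model = model, cv = cv, train_ids = train_ids,
         holdout_ids = holdout_ids, predicted = pred_all,
         corrected = corrected, pad = pad)
  })
  pheno$pad <- unname(fitres$pad[pheno$subject_id])

  matched <- stage_log(run_env, "match", {
    if (sum(pheno$group == "PD" & pheno$sex == "F") >= 2 &&
        sum(pheno$group == "PD" & pheno$sex == "M") >= 2) {
      spec_m <- do.call(match_spec,
                        c(config$matching, list(seed = seed)))
      res <- match_minority(pheno, spec_m)
      message(sprintf("  matched %d of %d majority subjects (%d dropped listwise)",
                      length(res$matched_majority),
                      sum(res$labels == res$majority), attr(res, "n_dropped")))
      res
    } else NULL
  })

  subgroups <- list(
    "PD" = pheno$subject_id[pheno$group == "PD"],
    "PD-F" = pheno$subject_id[pheno$group == "PD" & pheno$sex == "F"],
    "PD-M" = pheno$subject_id[pheno$group == "PD" & pheno$sex == "M"])
  if (!is.null(matched)) subgroups[["PD-M*"]] <- matched$matched_majority
  subgroups <- Filter(length, subgroups)

  battery <- stage_log(run_env, "battery", {
    pd_data <- pheno[pheno$group == "PD", , drop = FALSE]
    if (nrow(pd_data) > 0)
      run_battery(pd_data, subgroups, families = config$battery$families)
    else NULL
  })

  voxelwise <- stage_log(run_env, "voxelwise", {
    vw <- config$voxelwise
    hc_ids <- if (length(fitres$holdout_ids) >= 10) fitres$holdout_ids else
      c(fitres$train_ids, fitres$holdout_ids)
    groups <- list(HC = hc_ids, PD = pheno$subject_id[pheno$group == "PD"])
    tiv <- vapply(proc$volumes, `[[`, numeric(1), "tiv_ml")
    out <- list()
    for (tis in vw$tissues) {
      for (gname in names(groups)) {
        ids <- groups[[gname]]
        if (length(ids) < 10) next
        Y <- stack_maps(proc$maps, tis, ids)
        rowsel <- match(ids, pheno$subject_id)
        design <- data.frame(intercept = 1,
                             pad = pheno$pad[rowsel],
                             age = pheno$age[rowsel],
                             sex = as.numeric(pheno$sex[rowsel] == "M"),
                             tiv = tiv[ids])
        # constant nuisance columns (e.g. single-sex subsets) are dropped
        keep <- c(TRUE, vapply(design[-1], function(v) stats::sd(v) > 0,
                               logical(1)))
        design <- design[, keep, drop = FALSE]
        stat <- massuni_fit(Y, design, "pad")
        p_fwe <- fwe_correct(Y, design, "pad", n_perm = vw$n_perm, seed = seed)
        clusters <- extract_clusters(stat, p_fwe, vw$alpha, vw$min_extent)
        out[[paste(tis, gname, sep = "_")]] <-
          list(tissue = tis, group = gname, stat = stat, p_fwe = p_fwe,
               clusters = clusters)
      }
      # between-group slope contrast on this tissue
      ids2 <- c(groups$HC, groups$PD)
      if (length(groups$HC) >= 10 && length(groups$PD) >= 10) {
        Y2 <- stack_maps(proc$maps, tis, ids2)
        rowsel <- match(ids2, pheno$subject_id)
        cov2 <- data.frame(age = pheno$age[rowsel],
                           sex = as.numeric(pheno$sex[rowsel] == "M"),
                           tiv = tiv[ids2])
        grp <- rep(c("HC", "PD"), c(length(groups$HC), length(groups$PD)))
        out[[paste0(tis, "_contrast")]] <-
          list(tissue = tis, stat = slope_contrast(Y2, pheno$pad[rowsel], grp, cov2))
      }
    }
    out
  })

  report <- stage_log(run_env, "report", {
    ages <- stats::setNames(pheno$age, pheno$subject_id)
    sets <- list(
      list(set = "Training (CV)", group = "HC", ids = fitres$train_ids,
           metrics = fitres$cv),
      list(set = "Training", group = "HC", ids = fitres$train_ids),
      list(set = "Hold-out", group = "HC", ids = fitres$holdout_ids),
      list(set = "Test", group = "PD", ids = subgroups[["PD"]]),
      list(set = "Test", group = "PD-F", ids = subgroups[["PD-F"]]),
      list(set = "Test", group = "PD-M", ids = subgroups[["PD-M"]]),
      list(set = "Test", group = "PD-M*", ids = subgroups[["PD-M*"]]))
    rows <- lapply(sets, function(s) {
      if (is.null(s$ids) || length(s$ids) < 2) return(NULL)
      m <- if (!is.null(s$metrics)) s$metrics else
        evaluate_predictions(fitres$corrected[s$ids], ages[s$ids])
      data.frame(set = s$set, group = s$group, n = m$n,
                 mae = m$mae, rmse = m$rmse, r2 = m$r2,
                 mean_pad = m$mean_pad,
                 pad_ci_low = m$pad_ci95[1], pad_ci_high = m$pad_ci95[2],
                 stringsAsFactors = FALSE)
    })
    metrics_table <- do.call(rbind, Filter(Negate(is.null), rows))

    true_m <- mean(pheno$true_gap[pheno$group == "PD" & pheno$sex == "M"])
    true_f <- mean(pheno$true_gap[pheno$group == "PD" & pheno$sex == "F"])
    est_m <- mean(pheno$pad[pheno$group == "PD" & pheno$sex == "M"])
    est_f <- mean(pheno$pad[pheno$group == "PD" & pheno$sex == "F"])
    matched_test <- if (!is.null(matched) &&
                        length(matched$matched_majority) >= 2) {
      group_ttest(pheno$pad[pheno$subject_id %in% matched$matched_majority],
                  pheno$pad[pheno$group == "PD" & pheno$sex == "F"])
    } else NULL
    recovery <- list(true_gap_mean_m = true_m, true_gap_mean_f = true_f,
                     est_pad_mean_m = est_m, est_pad_mean_f = est_f,
                     error_m = est_m - true_m, error_f = est_f - true_f,
                     sex_difference_positive = (est_m - est_f) > 0,
                     matched_ttest = matched_test)
    list(metrics_table = metrics_table, recovery = recovery)
  })

  bundle <- structure(list(
    config = config, config_hash = config_hash(config), seed = seed,
    pheno = pheno, coefficients = sim$coefficients,
    model = fitres$model, cv = fitres$cv,
    metrics_table = report$metrics_table,
    matched = matched, battery = battery, voxelwise = voxelwise,
    recovery = report$recovery), class = "report_bundle")

  if (!is.null(out_dir)) stage_log(run_env, "write", write_bundle(bundle, out_dir))
  bundle
}

#' Write the report bundle artifacts
#'
#' Metrics and Brain-PAD CSVs, matching pairs, battery tables, cluster
#' tables, t-map NIfTIs, recovery JSON and the stamped config.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @return `dir` invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$config_hash <- rep(bundle$config_hash, nrow(df))
    df$seed <- rep(bundle$seed, nrow(df))
    df
  }
  utils::write.csv(stamp(bundle$metrics_table), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  pad_df <- data.frame(subject_id = bundle$pheno$subject_id,
                       group = bundle$pheno$group, sex = bundle$pheno$sex,
                       age = bundle$pheno$age, pad = bundle$pheno$pad,
                       stringsAsFactors = FALSE)
  utils::write.csv(stamp(pad_df), file.path(dir, "pad.csv"), row.names = FALSE)
  utils::write.csv(bundle$pheno, file.path(dir, "pheno.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(bundle$matched))
    utils::write.csv(stamp(bundle$matched$pairs), file.path(dir, "pairs.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$battery)) write_battery(bundle$battery, dir)
  for (nm in names(bundle$voxelwise)) {
    v <- bundle$voxelwise[[nm]]
    if (!is.null(v$clusters))
      utils::write.csv(stamp(v$clusters),
                       file.path(dir, sprintf("clusters_%s.csv", nm)),
                       row.names = FALSE)
    write_stat_map(v$stat, file.path(dir, sprintf("tmap_%s.nii.gz", nm)),
                   p_fwe = v$p_fwe)
  }
  jsonlite::write_json(bundle$recovery, file.path(dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  save_config(bundle$config, file.path(dir, "config.yaml"))
  writeLines(bundle$config_hash, file.path(dir, "config_hash.txt"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> seed", x$seed, "config", substr(x$config_hash, 1, 8), "\n")
  print(x$metrics_table, digits = 3)
  r <- x$recovery
  cat(sprintf("gap recovery: M %.2f (true %.2f), F %.2f (true %.2f)\n",
              r$est_pad_mean_m, r$true_gap_mean_m, r$est_pad_mean_f,
              r$true_gap_mean_f))
  invisible(x)
}
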