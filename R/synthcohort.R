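# Synthetic cohort generator: phenotypes, tissue maps, clinical scores.
#
# The generative model is deliberately linear: every tissue map is a smooth
# template plus a per-voxel atrophy rate times the subject's *effective age*
# (chronological age + true accelerated-aging gap), plus sex and scanner
# offsets and smooth Gaussian noise. CSF absorbs whatever GM and WM lose, so
# GM + WM + CSF is constant per voxel and TIV is age-invariant. The injected
# gap is therefore exactly the Brain-PAD a consistent estimator should
# recover.

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the generative model: group sizes, sex
#' composition, age range, the voxel grid, per-voxel atrophy and sex-offset
#' maps, scanner levels, the sex-specific accelerated-aging gap of the disease
#' group, and noise. Defaults give a small three-group cohort on a 16^3 grid
#' at 8 mm with an ellipsoidal brain mask (~1900 in-mask voxels); the
#' `"paper"` preset fixes the mask to exactly 3747 in-mask voxels per tissue
#' on a 24^3 grid.
#'
#' Default study conditions: healthy groups are 53% female, the disease group
#' 34% female; ages are uniform over 18-94 years; the disease group carries a
#' latent gap drawn from Normal(3.5, 2) years for males and Normal(1.8, 2)
#' years for females, zero for healthy subjects.
#'
#' @param n_hc_train,n_hc_holdout,n_pd Group sizes (non-negative integers; at
#'   least one must be positive).
#' @param female_fraction Named vector `c(hc = , pd = )` of female proportions.
#' @param age_range Length-2 numeric, min < max, in years.
#' @param grid_shape Voxel counts per axis (length 3).
#' @param voxel_spacing Isotropic voxel size in mm.
#' @param mask_voxels If non-`NULL`, the ellipsoidal mask is trimmed/grown to
#'   exactly this many in-mask voxels (innermost first).
#' @param atrophy_rate_map Per-voxel GM decline per year of effective age
#'   (probability units / year, all `<= 0`); scalar or array of `grid_shape`.
#'   `NULL` gives a centre-weighted default of about -0.002/y.
#' @param wm_rate_scale WM atrophy as a fraction of the GM rate.
#' @param sex_offset_map Additive GM offset for males (scalar or array);
#'   `NULL` gives a small negative centre-weighted default.
#' @param scanner_levels Data frame with columns `vendor`, `field_strength`,
#'   `offset` (additive intensity offset on GM and WM) and `noise_scale`.
#' @param pad_gap_mean_m,pad_gap_mean_f True mean accelerated-aging gap in
#'   years for male / female disease subjects.
#' @param pad_gap_sd SD of the gap, years, `>= 0`.
#' @param tiv_cv Coefficient of variation of a per-subject head-size factor
#'   that multiplies all three tissue maps (age-invariant, so TIV varies
#'   across subjects but not with age); 0 disables it.
#' @param noise_fwhm Spatial FWHM (mm) of the smooth noise field.
#' @param noise_sd Per-voxel noise SD in probability units (before the
#'   per-scanner `noise_scale`).
#' @param seed Master seed for all generator sub-streams.
#' @param preset `"default"` or `"paper"` (3747-voxel mask, 24^3 grid).
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(n_hc_train = 200, n_hc_holdout = 22, n_pd = 100,
                        female_fraction = c(hc = 0.53, pd = 0.34),
                        age_range = c(18, 94),
                        grid_shape = c(16L, 16L, 16L),
                        voxel_spacing = 8,
                        mask_voxels = NULL,
                        atrophy_rate_map = NULL,
                        wm_rate_scale = 0.4,
                        sex_offset_map = NULL,
                        scanner_levels = default_scanner_levels(),
                        pad_gap_mean_m = 3.5, pad_gap_mean_f = 1.8,
                        pad_gap_sd = 2,
                        tiv_cv = 0.03,
                        noise_fwhm = 12, noise_sd = 0.02,
                        seed = 1L,
                        preset = c("default", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    grid_shape <- c(24L, 24L, 24L)
    mask_voxels <- 3747L
  }
  spec <- list(n_hc_train = n_hc_train, n_hc_holdout = n_hc_holdout,
               n_pd = n_pd, female_fraction = female_fraction,
               age_range = age_range, grid_shape = as.integer(grid_shape),
               voxel_spacing = voxel_spacing, mask_voxels = mask_voxels,
               atrophy_rate_map = atrophy_rate_map,
               wm_rate_scale = wm_rate_scale,
               sex_offset_map = sex_offset_map,
               scanner_levels = scanner_levels,
               pad_gap_mean_m = pad_gap_mean_m,
               pad_gap_mean_f = pad_gap_mean_f,
               pad_gap_sd = pad_gap_sd, tiv_cv = tiv_cv,
               noise_fwhm = noise_fwhm, noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  p <- character()
  for (f in c("n_hc_train", "n_hc_holdout", "n_pd"))
    if (!is_count(spec[[f]])) p <- c(p, sprintf("%s must be a non-negative integer", f))
  if (all(vapply(c("n_hc_train", "n_hc_holdout", "n_pd"),
                 function(f) is_count(spec[[f]]) && spec[[f]] == 0, logical(1))))
    p <- c(p, "at least one group size must be positive")
  ff <- spec$female_fraction
  if (!is_prob(ff) || !all(c("hc", "pd") %in% names(ff)))
    p <- c(p, "female_fraction must be named proportions c(hc=, pd=) in [0,1]")
  if (!is.numeric(spec$age_range) || length(spec$age_range) != 2 ||
      spec$age_range[1] >= spec$age_range[2])
    p <- c(p, "age_range must satisfy min < max")
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 2))
    p <- c(p, "grid_shape must be 3 counts >= 2")
  if (!is.numeric(spec$voxel_spacing) || spec$voxel_spacing <= 0)
    p <- c(p, "voxel_spacing must be > 0")
  if (!is.numeric(spec$pad_gap_sd) || spec$pad_gap_sd < 0)
    p <- c(p, "pad_gap_sd must be >= 0")
  if (!is.numeric(spec$tiv_cv) || spec$tiv_cv < 0)
    p <- c(p, "tiv_cv must be >= 0")
  if (!is.numeric(spec$noise_sd) || spec$noise_sd < 0)
    p <- c(p, "noise_sd must be >= 0")
  if (!is.numeric(spec$noise_fwhm) || spec$noise_fwhm < 0)
    p <- c(p, "noise_fwhm must be >= 0")
  sl <- spec$scanner_levels
  if (!is.data.frame(sl) ||
      !all(c("vendor", "field_strength", "offset", "noise_scale") %in% names(sl)) ||
      nrow(sl) < 1)
    p <- c(p, "scanner_levels must be a data frame with vendor/field_strength/offset/noise_scale")
  if (!is.null(spec$atrophy_rate_map)) {
    arm <- spec$atrophy_rate_map
    if (any(arm > 0)) p <- c(p, "atrophy_rate_map must be <= 0 everywhere")
    if (is.array(arm) && !identical(dim(arm), as.integer(spec$grid_shape)))
      p <- c(p, "atrophy_rate_map array must match grid_shape")
  }
  if (length(p)) stop_invalid(p, "cohort_spec")
  invisible(spec)
}

#' @rdname cohort_spec
#' @export
default_scanner_levels <- function() {
  data.frame(vendor = c("GE", "Siemens"),
             field_strength = c(1.5, 3.0),
             offset = c(0, 0.004),
             noise_scale = c(1.0, 1.2),
             stringsAsFactors = FALSE)
}

# Normalized squared ellipsoidal radius of every voxel (semi-axes 0.45*shape).
ellipsoid_radius2 <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- 0.45 * shape
  r1 <- ((seq_len(shape[1]) - ctr[1]) / ax[1])^2
  r2 <- ((seq_len(shape[2]) - ctr[2]) / ax[2])^2
  r3 <- ((seq_len(shape[3]) - ctr[3]) / ax[3])^2
  outer(outer(r1, r2, `+`), r3, `+`)
}

#' Brain mask for a cohort spec
#'
#' Ellipsoidal mask; with `mask_voxels` set, exactly that many voxels are kept
#' (innermost by ellipsoidal radius, deterministic tie-break by array order).
#'
#' @param spec A [cohort_spec].
#' @return Logical array of `grid_shape`.
#' @export
cohort_mask <- function(spec) {
  r2 <- ellipsoid_radius2(spec$grid_shape)
  if (is.null(spec$mask_voxels)) return(r2 <= 1)
  n <- spec$mask_voxels
  if (n > length(r2)) stop("mask_voxels exceeds grid size", call. = FALSE)
  m <- array(FALSE, dim(r2))
  m[order(as.vector(r2))[seq_len(n)]] <- TRUE
  m
}

# Smooth tissue templates and default parameter maps, all keyed off the
# ellipsoidal radius so they are spatially structured but analytic.
cohort_fields <- function(spec) {
  r2 <- ellipsoid_radius2(spec$grid_shape)
  mask <- cohort_mask(spec)
  profile <- exp(-2 * r2)
  gm_t <- (0.35 + 0.15 * profile) * mask
  wm_t <- (0.12 + 0.20 * exp(-3 * r2)) * mask
  csf_t <- 0.08 * mask
  arm <- spec$atrophy_rate_map
  if (is.null(arm)) arm <- -0.002 * (0.5 + 0.5 * profile)
  if (!is.array(arm)) arm <- array(arm, dim(mask))
  arm <- arm * mask
  sxm <- spec$sex_offset_map
  if (is.null(sxm)) {
    # laterally antisymmetric: sex differences are regionally specific, not a
    # rescaled copy of the (radially symmetric) aging pattern
    lat <- sin(pi * (seq_len(spec$grid_shape[1]) / (spec$grid_shape[1] + 1) - 0.5))
    sxm <- -0.008 * profile * array(lat, dim(mask))
  }
  if (!is.array(sxm)) sxm <- array(sxm, dim(mask))
  sxm <- sxm * mask
  list(mask = mask, gm_t = gm_t, wm_t = wm_t, csf_t = csf_t,
       atrophy_gm = arm, atrophy_wm = arm * spec$wm_rate_scale,
       sex_offset = sxm)
}

#' Generate the phenotype table of a synthetic cohort
#'
#' Draws per-subject demographics and group/sex labels: group sizes and female
#' fractions per `spec`, ages uniform over `age_range`, education approximately
#' normal (years), scanner levels assigned cyclically within group, and the
#' latent accelerated-aging gap `true_gap` (Normal(`pad_gap_mean_<sex>`,
#' `pad_gap_sd`) for disease subjects, 0 for healthy subjects). Disease
#' subjects also get a diagnosis age and a disease duration in months,
#' `disease_duration = round(12 * (age - diagnosis_age))`. Clinical score
#' columns are created as `NA` and filled by [generate_clinical_scores()].
#'
#' @param spec A [cohort_spec].
#' @return A data frame (`phenotype_table`), one row per subject, deterministic
#'   given `spec$seed`.
#' @export
generate_phenotypes <- function(spec) {
  validate_cohort_spec(spec)
  with_substream(spec$seed, "phenotypes", {
    groups <- c(HC_train = spec$n_hc_train, HC_holdout = spec$n_hc_holdout,
                PD = spec$n_pd)
    rows <- lapply(names(groups), function(g) {
      n <- groups[[g]]
      if (n == 0) return(NULL)
      ff <- if (g == "PD") spec$female_fraction[["pd"]] else spec$female_fraction[["hc"]]
      n_f <- round(n * ff)
      sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
      age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
      edu <- pmin(pmax(round(stats::rnorm(n, 15, 3)), 6), 24)
      sl <- spec$scanner_levels
      level <- sample(rep_len(seq_len(nrow(sl)), n))
      if (g == "PD") {
        gap_mean <- ifelse(sex == "M", spec$pad_gap_mean_m, spec$pad_gap_mean_f)
        true_gap <- stats::rnorm(n, gap_mean, spec$pad_gap_sd)
        dx_age <- pmax(age - stats::runif(n, 0.5, 8), spec$age_range[1] / 2)
        duration <- round(12 * (age - dx_age))
      } else {
        true_gap <- 0
        dx_age <- NA_real_
        duration <- NA_real_
      }
      data.frame(group = g, sex = sex, age = age, education = edu,
                 diagnosis_age = dx_age, disease_duration = duration,
                 vendor = sl$vendor[level], field_strength = sl$field_strength[level],
                 true_gap = true_gap, stringsAsFactors = FALSE)
    })
    pheno <- do.call(rbind, rows)
    pheno$head_scale <- if (spec$tiv_cv > 0)
      pmin(pmax(stats::rnorm(nrow(pheno), 1, spec$tiv_cv), 0.9), 1.1)
    else 1
    pheno <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(pheno))), pheno)
    for (col in clinical_outcomes()) pheno[[col]] <- NA_real_
    class(pheno) <- c("phenotype_table", "data.frame")
    pheno
  })
}

# Smooth Gaussian noise field on the grid, rescaled to unit in-mask SD.
smooth_noise_field <- function(shape, spacing, fwhm, mask) {
  z <- array(stats::rnorm(prod(shape)), shape)
  if (fwhm > 0) {
    g <- voxel_grid(array(0.5, shape), spacing, tissue = "GM")
    sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
    for (axis in 1:3) {
      sigma_vox <- sigma_mm / spacing
      r <- max(1L, ceiling(4 * sigma_vox))
      kern <- stats::dnorm(-r:r, sd = sigma_vox)
      z <- conv_axis(z, kern / sum(kern), axis)
    }
  }
  s <- stats::sd(z[mask])
  if (s > 0) z <- z / s
  z
}

#' Generate tissue probability maps for a cohort
#'
#' For each subject, per-voxel GM = template + atrophy_rate * (age + true_gap)
#' + male sex offset + scanner offset + smooth noise, clipped to `[0, 1]`;
#' WM is built analogously at `wm_rate_scale` times the GM atrophy rate; CSF
#' absorbs every deviation of GM and WM from their templates, so
#' GM + WM + CSF <= 1 at every voxel and TIV is invariant to age, gap, sex,
#' scanner and noise. Deterministic given `spec$seed`.
#'
#' @param pheno Phenotype table from [generate_phenotypes()] (same spec).
#' @param spec The [cohort_spec].
#' @return Named list (by `subject_id`) of lists with [voxel_grid]s
#'   `gm`, `wm`, `csf`.
#' @export
generate_tissue_maps <- function(pheno, spec) {
  validate_cohort_spec(spec)
  sl <- spec$scanner_levels
  unknown <- setdiff(unique(pheno$vendor), sl$vendor)
  if (length(unknown))
    stop("unknown scanner vendor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  fld <- cohort_fields(spec)
  shape <- spec$grid_shape
  spacing <- spec$voxel_spacing
  with_substream(spec$seed, "tissue_maps", {
    out <- vector("list", nrow(pheno))
    names(out) <- pheno$subject_id
    for (i in seq_len(nrow(pheno))) {
      eff_age <- pheno$age[i] + pheno$true_gap[i]
      male <- as.numeric(pheno$sex[i] == "M")
      lev <- match(pheno$vendor[i], sl$vendor)
      off <- sl$offset[lev] * fld$mask
      gm <- fld$gm_t + fld$atrophy_gm * eff_age + fld$sex_offset * male + off
      wm <- fld$wm_t + fld$atrophy_wm * eff_age + off
      if (spec$noise_sd > 0) {
        nsd <- spec$noise_sd * sl$noise_scale[lev]
        gm <- gm + nsd * smooth_noise_field(shape, spacing, spec$noise_fwhm, fld$mask) * fld$mask
        wm <- wm + nsd * smooth_noise_field(shape, spacing, spec$noise_fwhm, fld$mask) * fld$mask
      }
      csf <- fld$csf_t - (gm - fld$gm_t) - (wm - fld$wm_t)
      hs <- if ("head_scale" %in% names(pheno)) pheno$head_scale[i] else 1
      gm <- gm * hs; wm <- wm * hs; csf <- csf * hs
      gm <- pmin(pmax(gm, 0), 1)
      wm <- pmin(pmax(wm, 0), 1)
      csf <- pmin(pmax(csf, 0), 1)
      csf <- pmin(csf, pmax(1 - gm - wm, 0))
      out[[i]] <- list(
        gm = voxel_grid(gm, spacing, fld$mask, "GM"),
        wm = voxel_grid(wm, spacing, fld$mask, "WM"),
        csf = voxel_grid(csf, spacing, fld$mask, "CSF"))
    }
    out
  })
}

#' Stack one tissue across subjects as a matrix
#'
#' @param maps Output of [generate_tissue_maps()] (or same structure).
#' @param tissue `"gm"`, `"wm"` or `"csf"`.
#' @param subject_ids Optional subset/order; defaults to all subjects.
#' @return Numeric matrix, subjects x in-mask voxels, with attributes
#'   `mask`, `spacing`, `affine` taken from the first subject's grid.
#' @export
stack_maps <- function(maps, tissue = c("gm", "wm", "csf"), subject_ids = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(subject_ids)) subject_ids <- names(maps)
  missing_ids <- setdiff(subject_ids, names(maps))
  if (length(missing_ids))
    stop("no maps for subject(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  g1 <- maps[[subject_ids[1]]][[tissue]]
  idx <- which(g1$mask)
  Y <- matrix(NA_real_, length(subject_ids), length(idx),
              dimnames = list(subject_ids, NULL))
  for (i in seq_along(subject_ids)) {
    g <- maps[[subject_ids[i]]][[tissue]]
    if (!identical(which(g$mask), idx))
      stop("inconsistent masks across subjects", call. = FALSE)
    Y[i, ] <- g$values[idx]
  }
  structure(Y, mask = g1$mask, spacing = g1$spacing, affine = g1$affine)
}

# Clinical score generation ---------------------------------------------------

#' Clinical outcome names and model families
#'
#' Motor outcomes are modelled on intercept + Brain-PAD + age + disease
#' duration + education + sex; non-motor outcomes add UPDRS-III (total); mood
#' outcomes add UPDRS-III and MoCA.
#'
#' @return `clinical_outcomes()`: character vector of all outcome columns.
#'   `outcome_family()`: the family of one outcome.
#' @export
clinical_outcomes <- function() {
  c(motor_outcomes(), nonmotor_outcomes(), mood_outcomes())
}

motor_outcomes <- function() c("UPDRS3_total", "UPDRS3_rigidity", "UPDRS3_tremor")
nonmotor_outcomes <- function() {
  c("MoCA", "ESS", "LNS", "REM", "BJLO", "HVLT_recall", "HVLT_recognition",
    "olfactory", "SDM")
}
mood_outcomes <- function() c("anxiety", "GDS")

#' @rdname clinical_outcomes
#' @param outcome Outcome column name.
#' @export
outcome_family <- function(outcome) {
  if (outcome %in% motor_outcomes()) return("motor")
  if (outcome %in% nonmotor_outcomes()) return("nonmotor")
  if (outcome %in% mood_outcomes()) return("mood")
  stop("unknown outcome family for: ", outcome, call. = FALSE)
}

family_predictors <- function(family) {
  base <- c("intercept", "pad", "age", "duration", "education", "sex")
  switch(family,
         motor = base,
         nonmotor = c(base, "updrs3"),
         mood = c(base, "updrs3", "moca"),
         stop("unknown family: ", family, call. = FALSE))
}

#' Ground-truth clinical effect specification
#'
#' One entry per outcome with the generating coefficient vector (named per the
#' outcome's model family: `intercept`, `pad` (the Brain-PAD slot, applied to
#' the latent `true_gap`), `age`, `duration` (months), `education`, `sex`
#' (F = 0, M = 1), plus `updrs3` / `moca` where the family includes them), a
#' residual SD, and a missingness probability. Defaults echo the direction and
#' rough magnitude of the motor, non-motor and mood batteries of the cohort
#' the generator emulates.
#'
#' @param overrides Named list of per-outcome partial overrides, e.g.
#'   `list(UPDRS3_total = list(coefs = c(pad = 0), sd = 1))`.
#' @return A `clinical_effect_spec` list keyed by outcome.
#' @export
clinical_effect_spec <- function(overrides = list()) {
  def <- function(family, coefs, sd, missing = 0.02) {
    full <- stats::setNames(numeric(length(family_predictors(family))),
                            family_predictors(family))
    full[names(coefs)] <- coefs
    list(family = family, coefs = full, sd = sd, missing = missing)
  }
  eff <- list(
    UPDRS3_total = def("motor", c(intercept = 18, pad = 0.30, age = 0.10,
                                  duration = 0.03, education = -0.10, sex = 1.5), 6),
    UPDRS3_rigidity = def("motor", c(intercept = 4, pad = 0.08, age = 0.02,
                                     duration = 0.008, education = -0.02, sex = 0.5), 2),
    UPDRS3_tremor = def("motor", c(intercept = 4, pad = 0.05, age = 0.01,
                                   duration = 0.006, education = -0.02, sex = 0.3), 2),
    MoCA = def("nonmotor", c(intercept = 29, pad = -0.04, age = -0.046,
                             education = 0.08, sex = 0.4, updrs3 = -0.02), 2),
    ESS = def("nonmotor", c(intercept = 6, pad = 0.01, age = -0.005,
                            duration = 0.005, sex = 0.2, updrs3 = 0.056), 3),
    LNS = def("nonmotor", c(intercept = 14, pad = -0.037, age = -0.10,
                            education = 0.15, updrs3 = -0.009), 2.5),
    REM = def("nonmotor", c(intercept = 4, pad = 0.057, age = -0.018,
                            sex = -0.24, updrs3 = 0.060), 2.5),
    BJLO = def("nonmotor", c(intercept = 25, pad = -0.034, age = -0.032,
                             education = 0.17, sex = -1.0, updrs3 = -0.017), 3,
               missing = 0.05),
    HVLT_recall = def("nonmotor", c(intercept = 12, pad = -0.002, age = -0.08,
                                    education = 0.20, sex = -1.0, updrs3 = -0.009), 2.5),
    HVLT_recognition = def("nonmotor", c(intercept = 11, pad = 0.001, age = -0.029,
                                         education = 0.062, sex = -0.26,
                                         updrs3 = -0.010), 1.5),
    olfactory = def("nonmotor", c(intercept = 40, pad = -0.047, age = -0.266,
                                  education = 0.077, sex = -2.4, updrs3 = -0.055),
                    6, missing = 0.05),
    SDM = def("nonmotor", c(intercept = 60, pad = -0.092, age = -0.398,
                            education = 0.713, sex = -3.2, updrs3 = -0.145), 8),
    anxiety = def("mood", c(intercept = 35, pad = 0.05, age = -0.05,
                            education = -0.1, sex = 1.0, updrs3 = 0.10,
                            moca = -0.30), 8, missing = 0.05),
    GDS = def("mood", c(intercept = 4, pad = 0.02, age = -0.01,
                        education = -0.03, sex = 0.2, updrs3 = 0.05,
                        moca = -0.08), 2, missing = 0.05))
  for (nm in names(overrides)) {
    if (!nm %in% names(eff)) stop("unknown outcome in overrides: ", nm, call. = FALSE)
    ov <- overrides[[nm]]
    if (!is.null(ov$coefs)) eff[[nm]]$coefs[names(ov$coefs)] <- ov$coefs
    if (!is.null(ov$sd)) eff[[nm]]$sd <- ov$sd
    if (!is.null(ov$missing)) eff[[nm]]$missing <- ov$missing
  }
  validate_effect_spec(eff)
  structure(eff, class = "clinical_effect_spec")
}

#' @rdname clinical_effect_spec
#' @param eff A `clinical_effect_spec`.
#' @export
null_effect_spec <- function(eff = clinical_effect_spec()) {
  # All generating coefficients zero: outcomes are pure noise around 0.
  for (nm in names(eff)) eff[[nm]]$coefs[] <- 0
  eff
}

validate_effect_spec <- function(eff) {
  p <- character()
  for (nm in names(eff)) {
    e <- eff[[nm]]
    want <- family_predictors(e$family)
    if (!identical(names(e$coefs), want))
      p <- c(p, sprintf("%s: coefficient vector must be named %s", nm,
                        paste(want, collapse = ",")))
    if (!is.numeric(e$sd) || e$sd < 0) p <- c(p, sprintf("%s: sd must be >= 0", nm))
    if (!is_prob(e$missing)) p <- c(p, sprintf("%s: missingness must be in [0,1]", nm))
  }
  if (length(p)) stop_invalid(p, "clinical_effect_spec")
  invisible(eff)
}

#' Generate clinical scores from ground-truth regression equations
#'
#' Fills the clinical score columns of disease-group rows with a linear
#' combination of the outcome's family predictors — with the latent `true_gap`
#' standing in the Brain-PAD slot — plus Gaussian noise, and injects missing
#' values per outcome. Non-motor scores use the realized `UPDRS3_total`; mood
#' scores additionally use the realized `MoCA`. Healthy rows keep `NA`.
#'
#' @param pheno Phenotype table with `true_gap`, `age`, `disease_duration`,
#'   `education`, `sex`.
#' @param eff A [clinical_effect_spec()].
#' @param seed Integer seed (sub-stream `"clinical"`).
#' @return List with `pheno` (scores filled) and `coefficients` (the
#'   ground-truth `eff`, returned alongside for recovery tests).
#' @export
generate_clinical_scores <- function(pheno, eff = clinical_effect_spec(),
                                     seed = 1L) {
  validate_effect_spec(eff)
  for (nm in names(eff)) outcome_family(nm) # errors on unknown outcomes
  pd <- which(pheno$group == "PD")
  with_substream(seed, "clinical", {
    if (length(pd)) {
      base <- list(intercept = rep(1, length(pd)),
                   pad = pheno$true_gap[pd],
                   age = pheno$age[pd],
                   duration = ifelse(is.na(pheno$disease_duration[pd]), 0,
                                     pheno$disease_duration[pd]),
                   education = pheno$education[pd],
                   sex = as.numeric(pheno$sex[pd] == "M"))
      # family order matters: non-motor uses realized UPDRS-III, mood uses MoCA
      for (nm in names(eff)) {
        e <- eff[[nm]]
        preds <- base
        if ("updrs3" %in% names(e$coefs)) preds$updrs3 <- pheno$UPDRS3_total[pd]
        if ("moca" %in% names(e$coefs)) preds$moca <- pheno$MoCA[pd]
        X <- do.call(cbind, preds[names(e$coefs)])
        y <- drop(X %*% e$coefs)
        if (e$sd > 0) y <- y + stats::rnorm(length(pd), 0, e$sd)
        pheno[[nm]][pd] <- y
      }
      for (nm in names(eff)) {
        e <- eff[[nm]]
        if (e$missing > 0) {
          drop_i <- stats::runif(length(pd)) < e$missing
          pheno[[nm]][pd][drop_i] <- NA_real_
        }
      }
    }
    list(pheno = pheno, coefficients = eff)
  })
}

# Cohort I/O -------------------------------------------------------------------

#' Write / read a synthetic cohort to disk
#'
#' Phenotypes go to `pheno.csv` (UTF-8, missing as empty cells), maps to one
#' NIfTI per subject and tissue plus a 0/1 `mask.nii.gz`, and ground truth
#' (`true_gap`, generating coefficients) to `truth.json`.
#'
#' @param pheno Phenotype table.
#' @param maps Output of [generate_tissue_maps()], or `NULL` to skip.
#' @param coefficients Ground-truth effect spec, or `NULL`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(pheno, maps = NULL, coefficients = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pheno, file.path(dir, "pheno.csv"), row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  if (!is.null(maps)) {
    mask_grid <- maps[[1]]$gm
    mask_grid$values <- array(as.numeric(mask_grid$mask), dim(mask_grid$mask))
    write_grid_nifti(mask_grid, file.path(dir, "mask.nii.gz"))
    for (id in names(maps)) {
      for (tis in c("gm", "wm", "csf")) {
        write_grid_nifti(maps[[id]][[tis]],
                         file.path(dir, sprintf("%s_%s.nii.gz", id, tis)))
      }
    }
  }
  truth <- list(true_gap = stats::setNames(as.list(pheno$true_gap), pheno$subject_id))
  if (!is.null(coefficients)) {
    truth$coefficients <- lapply(coefficients, function(e)
      list(family = e$family, coefs = as.list(e$coefs), sd = e$sd,
           missing = e$missing))
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_pheno <- function(dir) {
  pheno <- utils::read.csv(file.path(dir, "pheno.csv"),
                           stringsAsFactors = FALSE,
                           na.strings = "", fileEncoding = "UTF-8")
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno
}
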