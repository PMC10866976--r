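# Clinical statistics: OLS model fits, the sex-stratified regression battery
# with FDR control, and pooled-variance group t-tests.

#' Fit one multiple linear regression model
#'
#' OLS with classical (homoskedastic) standard errors, listwise deletion on
#' the columns used, two-sided coefficient t-tests, the overall F-test against
#' the intercept-only model, and the adjusted R-squared. Rank-deficient
#' designs raise an error naming the collinear columns.
#'
#' @param outcome Outcome column name.
#' @param predictors Predictor column names (intercept added automatically).
#' @param data Data frame.
#' @return A `fit_table`: data frame of per-term `b`, `t`, `p` with attributes
#'   `n`, `df_residual`, `adj_r2`, `f`, `f_p`, `outcome`.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' fit_ols("y", "x", d)
#' @export
fit_ols <- function(outcome, predictors, data) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  k <- length(predictors) + 1L
  if (nrow(d) <= k + 1)
    stop(sprintf("insufficient n after listwise deletion (n = %d, %d coefficients)",
                 nrow(d), k), call. = FALSE)
  X <- as.matrix(cbind(`(Intercept)` = 1, d[, predictors, drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ",
                                  paste0("`", predictors, "`", collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  s <- summary(fit)
  co <- s$coefficients
  tab <- data.frame(term = c("(Intercept)", predictors),
                    b = co[, 1], t = co[, 3], p = co[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- s$fstatistic
  f_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(tab, class = c("fit_table", "data.frame"),
            outcome = outcome, n = nrow(d), df_residual = fit$df.residual,
            adj_r2 = s$adj.r.squared, r2 = s$r.squared,
            f = unname(fstat[1]), f_p = unname(f_p))
}

# Predictor sets per family, in phenotype-table column names; the Brain-PAD
# column is supplied by the caller (default "pad").
battery_predictors <- function(family, pad_col = "pad") {
  base <- c(pad_col, "age", "disease_duration", "education", "sex_code")
  switch(family,
         motor = base,
         nonmotor = c(base, "UPDRS3_total"),
         mood = c(base, "UPDRS3_total", "MoCA"),
         stop("unknown family: ", family, call. = FALSE))
}

family_outcomes <- function(family) {
  switch(family,
         motor = motor_outcomes(),
         nonmotor = nonmotor_outcomes(),
         mood = mood_outcomes(),
         stop("unknown family: ", family, call. = FALSE))
}

#' Run the sex-stratified regression battery
#'
#' Fits one model per outcome and subgroup. Motor outcomes are regressed on
#' Brain-PAD, age, disease duration, education and sex; non-motor outcomes add
#' UPDRS-III (total); mood outcomes add UPDRS-III and MoCA. The sex predictor
#' is dropped automatically in single-sex subgroups (constant column).
#' Listwise deletion is applied per model. Within each family, the F-test
#' p-values of all models are adjusted with Benjamini-Hochberg FDR (only the
#' F-test p-values are adjusted; coefficient p-values are reported raw), and
#' significance is flagged at 0.05. Outcomes whose column is entirely missing
#' in a subgroup are skipped with the reason recorded.
#'
#' @param data Phenotype table for the disease group with a Brain-PAD column.
#' @param subgroups Named list of subject-id vectors, e.g.
#'   `list("PD" = ..., "PD-F" = ..., "PD-M" = ..., "PD-M*" = ...)`.
#' @param families Families to run (subset of motor/nonmotor/mood).
#' @param pad_col Name of the Brain-PAD column in `data`.
#' @return A `battery_result`: list per family with `summary` (one row per
#'   outcome x subgroup: n, df, adj_r2, F, p, FDR p, significance),
#'   `coefficients` (long per-term table), and `skipped`.
#' @export
run_battery <- function(data, subgroups,
                        families = c("motor", "nonmotor", "mood"),
                        pad_col = "pad") {
  if (!pad_col %in% names(data))
    stop("Brain-PAD column `", pad_col, "` not found", call. = FALSE)
  if (!length(subgroups) || is.null(names(subgroups)))
    stop("`subgroups` must be a named list of subject ids", call. = FALSE)
  for (sg in names(subgroups)) {
    if (!length(subgroups[[sg]]))
      stop("empty subgroup: ", sg, call. = FALSE)
  }
  data$sex_code <- as.numeric(data$sex == "M")
  out <- list()
  for (fam in families) {
    fits <- list(); skipped <- list()
    for (outc in family_outcomes(fam)) {
      for (sg in names(subgroups)) {
        d <- data[data$subject_id %in% subgroups[[sg]], , drop = FALSE]
        key <- paste(outc, sg, sep = "|")
        if (!outc %in% names(d) || all(is.na(d[[outc]]))) {
          skipped[[key]] <- "outcome entirely missing"
          message("skipping ", key, ": outcome entirely missing")
          next
        }
        preds <- battery_predictors(fam, pad_col)
        # drop constant predictors (e.g. sex in single-sex subgroups)
        cc <- stats::complete.cases(d[, c(outc, preds), drop = FALSE])
        const <- vapply(preds, function(pv) {
          v <- d[[pv]][cc]
          length(unique(v)) < 2
        }, logical(1))
        preds <- preds[!const]
        res <- tryCatch(fit_ols(outc, preds, d), error = function(e) e)
        if (inherits(res, "error")) {
          skipped[[key]] <- conditionMessage(res)
          message("skipping ", key, ": ", conditionMessage(res))
        } else {
          fits[[key]] <- list(outcome = outc, subgroup = sg, fit = res)
        }
      }
    }
    if (!length(fits)) {
      out[[fam]] <- list(summary = NULL, coefficients = NULL,
                         skipped = unlist(skipped))
      next
    }
    summ <- do.call(rbind, lapply(fits, function(f) data.frame(
      outcome = f$outcome, subgroup = f$subgroup,
      n = attr(f$fit, "n"), df_residual = attr(f$fit, "df_residual"),
      adj_r2 = attr(f$fit, "adj_r2"), f = attr(f$fit, "f"),
      f_p = attr(f$fit, "f_p"), stringsAsFactors = FALSE)))
    summ$f_p_fdr <- bh_fdr(summ$f_p)
    summ$significant <- summ$f_p_fdr < 0.05
    rownames(summ) <- NULL
    coefs <- do.call(rbind, lapply(fits, function(f) {
      tab <- as.data.frame(f$fit)
      cbind(outcome = f$outcome, subgroup = f$subgroup, tab,
            stringsAsFactors = FALSE)
    }))
    rownames(coefs) <- NULL
    out[[fam]] <- list(summary = summ, coefficients = coefs,
                       skipped = unlist(skipped))
  }
  structure(out, class = "battery_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03)) # 0.03 0.03 0.03
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Pooled-variance two-sample Student t-test
#'
#' Two-sided, independent samples, pooled variance,
#' `df = n_a + n_b - 2`.
#'
#' @param values_a,values_b Numeric vectors, each of length `>= 2`.
#' @return List with `t`, `df`, `p`.
#' @export
group_ttest <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  n1 <- length(values_a); n2 <- length(values_b)
  sp2 <- ((n1 - 1) * stats::var(values_a) + (n2 - 1) * stats::var(values_b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Write battery tables to CSV
#'
#' One summary CSV and one coefficient CSV per family, plus a JSON of raw and
#' FDR-adjusted F-test p-values.
#'
#' @param battery A `battery_result`.
#' @param dir Output directory.
#' @return `dir` invisibly.
#' @export
write_battery <- function(battery, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pvals <- list()
  for (fam in names(battery)) {
    b <- battery[[fam]]
    if (is.null(b$summary)) next
    utils::write.csv(b$summary, file.path(dir, sprintf("battery_%s_summary.csv", fam)),
                     row.names = FALSE)
    utils::write.csv(b$coefficients,
                     file.path(dir, sprintf("battery_%s_coefficients.csv", fam)),
                     row.names = FALSE)
    pvals[[fam]] <- list(model = paste(b$summary$outcome, b$summary$subgroup,
                                       sep = "|"),
                         f_p = b$summary$f_p, f_p_fdr = b$summary$f_p_fdr)
  }
  jsonlite::write_json(pvals, file.path(dir, "battery_pvalues.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
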