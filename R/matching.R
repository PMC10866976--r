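# Propensity-score matching: logistic scores, greedy nearest-neighbour
# matching without replacement, and balance diagnostics.

#' Matching specification
#'
#' @param covariates Ordered covariate column names; the default is the
#'   clinical matching list (age, education, diagnosis age, UPDRS-III total /
#'   rigidity / tremor, MoCA, REM, ESS).
#' @param ratio Matches per minority subject, `>= 1`.
#' @param caliper Optional maximum |logit score difference| for a match.
#' @param seed Seed for the minority processing order.
#' @return A `match_spec` list.
#' @export
match_spec <- function(covariates = c("age", "education", "diagnosis_age",
                                      "UPDRS3_total", "UPDRS3_rigidity",
                                      "UPDRS3_tremor", "MoCA", "REM", "ESS"),
                       ratio = 1, caliper = NULL, seed = 1L) {
  p <- character()
  if (!length(covariates)) p <- c(p, "covariates must be non-empty")
  if (!is_count(ratio) || ratio < 1) p <- c(p, "ratio must be an integer >= 1")
  if (!is.null(caliper) && (!is.numeric(caliper) || caliper < 0))
    p <- c(p, "caliper must be >= 0")
  if (length(p)) stop_invalid(p, "match_spec")
  structure(list(covariates = covariates, ratio = ratio, caliper = caliper,
                 seed = as.integer(seed)), class = "match_spec")
}

#' Propensity scores from a logistic model
#'
#' Fits a logistic regression (with intercept) of majority-group membership on
#' the covariates and returns the fitted probabilities. Constant covariates
#' are dropped with a warning; (near-)perfect separation raises an error
#' advising a caliper or covariate review. Rows must be complete — apply
#' listwise deletion first (see [match_minority()]).
#'
#' @param covariates Data frame of numeric covariates.
#' @param labels Two-level vector; the majority (larger) group is the modelled
#'   outcome class.
#' @return Numeric vector of fitted majority-membership probabilities, with
#'   attribute `majority` (the label modelled as 1).
#' @export
propensity_scores <- function(covariates, labels) {
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates))
    stop("covariates contain missing values; apply listwise deletion first",
         call. = FALSE)
  lev <- unique(as.character(labels))
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  counts <- table(factor(labels, levels = lev))
  majority <- names(counts)[which.max(counts)]
  y <- as.numeric(labels == majority)
  keep <- vapply(covariates, function(x) stats::sd(x) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[!keep], collapse = ", "), call. = FALSE)
    covariates <- covariates[, keep, drop = FALSE]
  }
  if (ncol(covariates) == 0) {
    fit <- stats::glm(y ~ 1, family = stats::binomial())
  } else {
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = cbind(y = y, covariates),
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          stop(paste("(near-)perfect separation in the propensity model;",
                     "review the covariate list or use a caliper"),
               call. = FALSE)
        invokeRestart("muffleWarning")
      })
  }
  structure(unname(stats::fitted(fit)), majority = majority)
}

#' Greedy nearest-neighbour matching without replacement
#'
#' Minority subjects are processed in a seeded random order; each is matched
#' to the nearest unused majority subject on the logit of the propensity
#' score (within the caliper, if any), `ratio` times. Majority subjects are
#' never reused.
#'
#' @param scores Propensity scores in (0, 1), one per subject.
#' @param labels Group labels aligned with `scores`.
#' @param spec A [match_spec()].
#' @param ids Optional subject ids aligned with `scores` (defaults to
#'   indices).
#' @return A `match_result`: `scores`, `pairs` (data frame minority_id,
#'   majority_id, score_minority, score_majority, distance), and
#'   `matched_majority`. A warning reports minority subjects left unmatched
#'   by the caliper.
#' @export
match_groups <- function(scores, labels, spec = match_spec(), ids = NULL) {
  stopifnot(inherits(spec, "match_spec"))
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  lev <- unique(as.character(labels))
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  counts <- table(factor(labels, levels = lev))
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(lev, minority)
  if (counts[[minority]] > counts[[majority]])
    stop("minority group larger than majority group", call. = FALSE)
  eps <- 1e-12
  lgt <- stats::qlogis(pmin(pmax(scores, eps), 1 - eps))
  min_i <- which(labels == minority)
  maj_i <- which(labels == majority)
  # invariance to majority row order: process candidates sorted by logit,
  # deterministic tie-break by id
  maj_i <- maj_i[order(lgt[maj_i], ids[maj_i])]
  order_min <- with_substream(spec$seed, "match", sample(min_i))
  used <- logical(length(scores))
  pairs <- vector("list", length(min_i) * spec$ratio)
  k <- 0L
  unmatched <- 0L
  for (r in seq_len(spec$ratio)) {
    for (i in order_min) {
      cand <- maj_i[!used[maj_i]]
      if (!length(cand)) { unmatched <- unmatched + 1L; next }
      d <- abs(lgt[cand] - lgt[i])
      j <- cand[which.min(d)]
      dj <- abs(lgt[j] - lgt[i])
      if (!is.null(spec$caliper) && dj > spec$caliper) {
        unmatched <- unmatched + 1L
        next
      }
      used[j] <- TRUE
      k <- k + 1L
      pairs[[k]] <- data.frame(minority_id = ids[i], majority_id = ids[j],
                               score_minority = scores[i],
                               score_majority = scores[j],
                               distance = dj, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (k) do.call(rbind, pairs[seq_len(k)]) else
    data.frame(minority_id = character(), majority_id = character(),
               score_minority = numeric(), score_majority = numeric(),
               distance = numeric())
  if (unmatched > 0)
    warning(sprintf("%d minority subject-slot(s) left unmatched", unmatched),
            call. = FALSE)
  structure(list(scores = stats::setNames(scores, ids),
                 labels = stats::setNames(as.character(labels), ids),
                 pairs = pairs,
                 matched_majority = unique(pairs$majority_id),
                 minority = minority, majority = majority,
                 n_unmatched = unmatched),
            class = "match_result")
}

#' Match the male disease subgroup to the female subgroup
#'
#' Convenience wrapper: listwise deletion on the matching covariates, logistic
#' propensity scores, then greedy matching of majority (male) subjects to the
#' minority (female) group.
#'
#' @param pheno Phenotype table restricted to the disease group (or with a
#'   `group == "PD"` subset taken internally).
#' @param spec A [match_spec()].
#' @return A `match_result` (ids are `subject_id`s); attribute `n_dropped`
#'   counts subjects removed by listwise deletion.
#' @export
match_minority <- function(pheno, spec = match_spec()) {
  pd <- pheno[pheno$group == "PD", , drop = FALSE]
  if (nrow(pd) == 0) stop("no disease-group rows to match", call. = FALSE)
  missing_cols <- setdiff(spec$covariates, names(pd))
  if (length(missing_cols))
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  complete <- stats::complete.cases(pd[, spec$covariates, drop = FALSE])
  dropped <- sum(!complete)
  pd <- pd[complete, , drop = FALSE]
  scores <- propensity_scores(pd[, spec$covariates, drop = FALSE], pd$sex)
  res <- match_groups(scores, pd$sex, spec, ids = pd$subject_id)
  attr(res, "n_dropped") <- dropped
  res
}

#' Covariate balance before and after matching
#'
#' For each variable: group means and SDs, the pooled-variance two-sided
#' Student t-test, and the standardized mean difference
#' (mean1 - mean2) / pooled SD, both pre-match (all minority vs all majority)
#' and post-match (minority vs matched majority). Zero pooled variance makes
#' the SMD (and t) undefined; they are reported as `NA`.
#'
#' @param pheno Phenotype table containing the matched subjects.
#' @param matched A `match_result` from [match_groups()]/[match_minority()].
#' @param variables Variable names to diagnose.
#' @return Data frame, one row per variable and phase (`pre` / `post`).
#' @export
balance_table <- function(pheno, matched, variables) {
  stopifnot(inherits(matched, "match_result"))
  ids <- names(matched$scores)
  lab <- matched$labels[ids]
  one <- function(var, ids_a, ids_b, phase) {
    a <- pheno[[var]][match(ids_a, pheno$subject_id)]
    b <- pheno[[var]][match(ids_b, pheno$subject_id)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    sp2 <- if (n1 + n2 > 2)
      ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
    else NA_real_
    if (is.na(sp2) || sp2 <= 0) {
      tt <- list(t = NA_real_, df = n1 + n2 - 2, p = NA_real_)
      smd <- NA_real_
    } else {
      tt <- group_ttest(a, b)
      smd <- (mean(a) - mean(b)) / sqrt(sp2)
    }
    data.frame(variable = var, phase = phase,
               mean_minority = mean(a), sd_minority = stats::sd(a),
               mean_majority = mean(b), sd_majority = stats::sd(b),
               t = tt$t, df = tt$df, p = tt$p, smd = smd,
               stringsAsFactors = FALSE)
  }
  min_ids <- ids[lab == matched$minority]
  maj_ids <- ids[lab == matched$majority]
  out <- lapply(variables, function(v) rbind(
    one(v, min_ids, maj_ids, "pre"),
    one(v, min_ids, matched$matched_majority, "post")))
  do.call(rbind, out)
}
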