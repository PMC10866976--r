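# Mass-univariate voxelwise regression with permutation family-wise-error
# control, cluster extraction, between-group slope contrasts, and ROI
# correlations.
#
# The map stack is a subjects x in-mask-voxels matrix (see stack_maps()),
# carrying the mask, spacing and affine as attributes so cluster tables can
# report sizes in ml and peak coordinates in world mm.

as_design <- function(design) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(X)
}

# Vectorized OLS t-statistics for one design column across all voxels.
ols_tmap <- function(Y, X, j, XtX_inv = NULL) {
  if (is.null(XtX_inv)) XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtX_inv[j, j])
  tval <- B[j, ] / se
  tval[sigma2 <= 0 | !is.finite(tval)] <- NA_real_
  list(t = tval, beta = B[j, ], df = df)
}

#' Mass-univariate voxelwise regression
#'
#' Per-voxel OLS of the map stack on the design matrix; returns the
#' t-statistic of the contrast column at every in-mask voxel. A negative t
#' means tissue volume decreases as the contrast covariate (typically
#' Brain-PAD) increases. Voxels with zero residual variance get `NA` with the
#' count recorded in the result.
#'
#' @param Y Map stack (subjects x voxels), e.g. from [stack_maps()].
#' @param design Design matrix or data frame (include an intercept column).
#' @param contrast Name (or index) of the design column to test.
#' @return A `stat_map`: list with `t`, `beta`, `df`, `contrast`,
#'   `n_undefined`, plus `mask`/`spacing`/`affine` carried from `Y`.
#' @export
massuni_fit <- function(Y, design, contrast) {
  X <- check_full_rank(as_design(design))
  if (nrow(X) != nrow(Y)) stop("design rows must match map stack rows", call. = FALSE)
  if (nrow(X) < 10) stop("need at least 10 subjects", call. = FALSE)
  j <- if (is.character(contrast)) match(contrast, colnames(X)) else as.integer(contrast)
  if (is.na(j) || j < 1 || j > ncol(X))
    stop("contrast column not found in design", call. = FALSE)
  r <- ols_tmap(Y, X, j)
  n_undef <- sum(is.na(r$t))
  if (n_undef > 0)
    message(n_undef, " voxel(s) with undefined t (zero residual variance)")
  structure(list(t = r$t, beta = r$beta, df = r$df,
                 contrast = colnames(X)[j], n_undefined = n_undef,
                 mask = attr(Y, "mask"), spacing = attr(Y, "spacing"),
                 affine = attr(Y, "affine")),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> contrast %s, df = %d, %d voxels (peak |t| = %.2f)\n",
              x$contrast, x$df, length(x$t), max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

#' Peak-level permutation family-wise-error correction
#'
#' Max-statistic permutation test with Freedman-Lane residual permutation
#' under the nuisance-only model: the contrast column is removed, the map
#' stack is reduced to nuisance fits plus permuted nuisance residuals, and
#' the full-model |t| map is recomputed for each permutation. The corrected
#' p-value of a voxel is the rank of its observed |t| within the permutation
#' distribution of the maximum |t| (with the identity permutation included),
#' so it is monotone non-increasing in |t|. Deterministic given `seed`.
#'
#' @param Y Map stack (subjects x voxels).
#' @param design Design matrix/data frame including the contrast column.
#' @param contrast Contrast column name or index.
#' @param n_perm Number of permutations, `>= 100`.
#' @param seed Integer seed (sub-stream `"fwe"`).
#' @return Numeric vector of peak-level FWE-corrected p-values per voxel,
#'   with attributes `max_t` (the null distribution) and `t` (observed).
#' @export
fwe_correct <- function(Y, design, contrast, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  X <- check_full_rank(as_design(design))
  j <- if (is.character(contrast)) match(contrast, colnames(X)) else as.integer(contrast)
  if (is.na(j) || j < 1 || j > ncol(X))
    stop("contrast column not found in design", call. = FALSE)
  n <- nrow(X)
  XtX_inv <- solve(crossprod(X))
  obs <- ols_tmap(Y, X, j, XtX_inv)$t
  Z <- X[, -j, drop = FALSE]
  Gz <- solve(crossprod(Z), crossprod(Z, Y))
  fitted_z <- Z %*% Gz
  resid_z <- Y - fitted_z
  max_t <- with_substream(seed, "fwe", {
    vapply(seq_len(n_perm - 1L), function(p) {
      Yp <- fitted_z + resid_z[sample.int(n), , drop = FALSE]
      max(abs(ols_tmap(Yp, X, j, XtX_inv)$t), na.rm = TRUE)
    }, numeric(1))
  })
  max_t <- c(max(abs(obs), na.rm = TRUE), max_t) # identity permutation
  pvals <- vapply(abs(obs), function(tv)
    if (is.na(tv)) NA_real_ else mean(max_t >= tv), numeric(1))
  structure(pvals, max_t = max_t, t = obs)
}

# 26-connectivity connected components over a logical 3-D array.
label_components <- function(flag) {
  d <- dim(flag)
  labels <- array(0L, d)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  idx <- which(flag, arr.ind = TRUE)
  if (!nrow(idx)) return(labels)
  current <- 0L
  for (s in seq_len(nrow(idx))) {
    v <- idx[s, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    current <- current + 1L
    queue <- matrix(v, ncol = 3)
    labels[v[1], v[2], v[3]] <- current
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      cand <- sweep(nbr, 2, p, `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      for (q in seq_len(nrow(cand))) {
        w <- cand[q, ]
        if (flag[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- current
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

#' Extract suprathreshold clusters
#'
#' Voxels with corrected p below `alpha` are grouped into 26-connectivity
#' components, separately for positive and negative t; components smaller
#' than `min_extent_voxels` are dropped. Sizes are reported in voxels and ml
#' (voxels x voxel volume); the peak (max |t|) voxel coordinate is mapped to
#' world mm through the affine, and the hemisphere is the sign of world x
#' (`L` for negative).
#'
#' @param stat A `stat_map` from [massuni_fit()].
#' @param p_fwe Corrected p-values aligned with `stat$t` (from
#'   [fwe_correct()]).
#' @param alpha Significance threshold on corrected p.
#' @param min_extent_voxels Minimum cluster extent in analysis-grid voxels.
#' @return Data frame of cluster records (possibly empty): cluster id, sign,
#'   size_voxels, size_ml, peak world coordinates, peak t, peak FWE p,
#'   hemisphere.
#' @export
extract_clusters <- function(stat, p_fwe, alpha = 0.05, min_extent_voxels = 1) {
  stopifnot(inherits(stat, "stat_map"))
  if (alpha <= 0 || min_extent_voxels < 1)
    stop("thresholds must be positive", call. = FALSE)
  mask_idx <- which(stat$mask)
  voxel_ml <- prod(stat$spacing) / 1000
  empty <- data.frame(cluster = integer(), sign = character(),
                      size_voxels = integer(), size_ml = numeric(),
                      peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
                      peak_t = numeric(), peak_p_fwe = numeric(),
                      hemisphere = character(), stringsAsFactors = FALSE)
  out <- list()
  cl_id <- 0L
  for (sgn in c("neg", "pos")) {
    keep <- !is.na(stat$t) & !is.na(p_fwe) & p_fwe < alpha &
      (if (sgn == "neg") stat$t < 0 else stat$t > 0)
    if (!any(keep)) next
    flag <- array(FALSE, dim(stat$mask))
    flag[mask_idx[keep]] <- TRUE
    labels <- label_components(flag)
    tmap <- array(NA_real_, dim(stat$mask)); tmap[mask_idx] <- stat$t
    pmap <- array(NA_real_, dim(stat$mask)); pmap[mask_idx] <- p_fwe
    for (comp in seq_len(max(labels))) {
      vox <- which(labels == comp)
      if (length(vox) < min_extent_voxels) next
      peak <- vox[which.max(abs(tmap[vox]))]
      pc <- arrayInd(peak, dim(stat$mask))
      world <- stat$affine %*% c(pc - 1, 1)
      cl_id <- cl_id + 1L
      out[[cl_id]] <- data.frame(
        cluster = cl_id, sign = sgn,
        size_voxels = length(vox), size_ml = length(vox) * voxel_ml,
        peak_x = world[1], peak_y = world[2], peak_z = world[3],
        peak_t = tmap[peak], peak_p_fwe = pmap[peak],
        hemisphere = if (world[1] < 0) "L" else "R",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Between-group contrast of Brain-PAD slopes
#'
#' Fits, per voxel, a model with the covariates, a group indicator and a
#' group x Brain-PAD interaction, and returns the t-map of the interaction
#' coefficient — the difference between the groups' Brain-PAD slopes.
#' Swapping the two group labels flips the map's sign.
#'
#' @param Y Map stack (subjects x voxels).
#' @param pad Brain-PAD per subject.
#' @param group Two-level group labels; the second level (sorted) is coded 1.
#' @param covariates Optional data frame of nuisance covariates (e.g. age,
#'   sex, TIV).
#' @return A `stat_map` for the interaction term.
#' @export
slope_contrast <- function(Y, pad, group, covariates = NULL) {
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  n_by <- table(factor(group, levels = lev))
  if (any(n_by < 10))
    stop("each group needs at least 10 subjects", call. = FALSE)
  g <- as.numeric(group == lev[2])
  X <- data.frame(intercept = 1, pad = pad, group = g, group_pad = g * pad)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  massuni_fit(Y, X, "group_pad")
}

#' Correlation between mean cluster volume and Brain-PAD per group
#'
#' For each group, the Pearson correlation (two-sided test) between each
#' subject's mean tissue value inside the cluster and their Brain-PAD.
#'
#' @param cluster_voxels Integer indices of cluster voxels (columns of `Y`).
#' @param Y Map stack (subjects x voxels).
#' @param pad Brain-PAD per subject.
#' @param group Group label per subject.
#' @return Data frame with group, n, r, p.
#' @export
roi_correlation <- function(cluster_voxels, Y, pad, group) {
  if (!length(cluster_voxels)) stop("empty cluster", call. = FALSE)
  roi_mean <- rowMeans(Y[, cluster_voxels, drop = FALSE])
  out <- lapply(sort(unique(as.character(group))), function(g) {
    sel <- group == g
    if (sum(sel) < 3) stop("fewer than 3 subjects in group ", g, call. = FALSE)
    if (stats::sd(pad[sel]) == 0)
      stop("constant Brain-PAD in group ", g, ": correlation undefined",
           call. = FALSE)
    ct <- stats::cor.test(roi_mean[sel], pad[sel])
    data.frame(group = g, n = sum(sel), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a stat map (and optional corrected p map) as NIfTI
#'
#' @param stat A `stat_map`.
#' @param path Output path for the t map.
#' @param p_fwe Optional corrected p vector; written next to `path` with a
#'   `_pfwe` suffix.
#' @return `path` invisibly.
#' @export
write_stat_map <- function(stat, path, p_fwe = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  to_grid <- function(v) {
    arr <- array(0, dim(stat$mask))
    arr[which(stat$mask)] <- ifelse(is.na(v), 0, v)
    arr
  }
  ni <- RNifti::asNifti(to_grid(stat$t))
  RNifti::pixdim(ni) <- stat$spacing
  RNifti::qform(ni) <- structure(stat$affine, code = 2L)
  RNifti::writeNifti(ni, path)
  if (!is.null(p_fwe)) {
    ni_p <- RNifti::asNifti(to_grid(p_fwe))
    RNifti::pixdim(ni_p) <- stat$spacing
    RNifti::qform(ni_p) <- structure(stat$affine, code = 2L)
    RNifti::writeNifti(ni_p, sub("(\\.nii(\\.gz)?)$", "_pfwe\\1", path))
  }
  invisible(path)
}
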