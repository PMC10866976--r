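#' Voxel grid container for tissue probability maps
#'
#' A minimal container for one subject's tissue probability (density) map:
#' a 3-D array of values in `[0, 1]`, the voxel spacing in mm, a logical brain
#' mask of the same shape, the tissue class, and a 4x4 voxel-to-world affine
#' (RAS+, mm). The affine defaults to a diagonal scaling by the spacing with
#' the origin at the first voxel's centre.
#'
#' @param values Numeric 3-D array of tissue probabilities in `[0, 1]`.
#' @param spacing Voxel spacing in mm; scalar or length-3 vector, all `> 0`.
#' @param mask Logical array of the same shape; defaults to all `TRUE`.
#' @param tissue One of `"GM"`, `"WM"`, `"CSF"`.
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel indices).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0.5, c(4, 4, 4)), spacing = 8, tissue = "GM")
#' @export
voxel_grid <- function(values, spacing, mask = NULL, tissue = c("GM", "WM", "CSF"),
                       affine = NULL) {
  tissue <- match.arg(tissue)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (any(!is.finite(values)) || any(values < -1e-9) || any(values > 1 + 1e-9))
    stop("`values` must lie within [0, 1]", call. = FALSE)
  values[] <- pmin(pmax(values, 0), 1)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive (scalar or length 3)", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  if (!identical(dim(mask), dim(values)))
    stop("`mask` shape must equal `values` shape", call. = FALSE)
  mask <- array(as.logical(mask), dim(values))
  if (is.null(affine)) {
    affine <- rbind(cbind(diag(spacing), -spacing * (dim(values) - 1) / 2),
                    c(0, 0, 0, 1))
  }
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  structure(list(values = values, spacing = spacing, mask = mask,
                 tissue = tissue, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s> %s voxels @ %s mm, %d in mask\n",
              x$tissue, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"), sum(x$mask)))
  invisible(x)
}

# 1-D convolution along `axis` with a normalized kernel, via a small banded
# matrix. The kernel rows are renormalized at the array boundary so constants
# are preserved (see smooth_grid).
conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kern) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    keep <- i + o >= 1L & i + o <= n
    K[cbind(i[keep], i[keep] + o)] <- kern[o + r + 1L]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  out <- K %*% matrix(a, nrow = n)
  aperm(array(out, dim(a)), match(1:3, perm))
}

#' Gaussian smoothing of a tissue map
#'
#' Separable Gaussian convolution with a kernel of full-width-at-half-maximum
#' `fwhm_mm` (so sigma = fwhm / (2 * sqrt(2 * log(2))) per axis, in mm). The
#' discrete kernel is normalized, and renormalized where it overhangs the array
#' boundary, so constant maps are preserved exactly and an interior unit
#' impulse conserves its mass. The mask is unchanged; `fwhm_mm = 0` is the
#' identity.
#'
#' @param grid A [voxel_grid].
#' @param fwhm_mm Kernel FWHM in mm, `>= 0`.
#' @return A smoothed [voxel_grid].
#' @export
smooth_grid <- function(grid, fwhm_mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  if (any(grid$spacing <= 0)) stop("non-positive voxel spacing", call. = FALSE)
  if (fwhm_mm == 0) return(grid)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  v <- grid$values
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / grid$spacing[axis]
    r <- max(1L, ceiling(4 * sigma_vox))
    kern <- stats::dnorm(-r:r, sd = sigma_vox)
    kern <- kern / sum(kern)
    v <- conv_axis(v, kern, axis)
  }
  out <- grid
  out$values <- pmin(pmax(v, 0), 1)
  out
}

#' Block-average downsampling of a tissue map
#'
#' Downsamples to a coarser isotropic-or-anisotropic spacing by averaging each
#' block of child voxels (volume-weighted, i.e. the plain mean since voxels are
#' equal-sized), the discrete analogue of the volume-preserving intent of
#' modulated VBM. The target spacing must be an integer multiple of the source
#' spacing on each axis; the mask is resampled by majority vote (ties count as
#' in-mask) and the affine is updated so world coordinates refer to block
#' centres.
#'
#' @param grid A [voxel_grid].
#' @param target_spacing_mm Target spacing in mm (scalar or length 3), each an
#'   integer multiple of the corresponding source spacing.
#' @return A [voxel_grid] at the coarser spacing.
#' @export
resample_grid <- function(grid, target_spacing_mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(target_spacing_mm) == 1L) target_spacing_mm <- rep(target_spacing_mm, 3L)
  if (any(target_spacing_mm < grid$spacing - 1e-9))
    stop("upsampling unsupported: target spacing must be >= source spacing",
         call. = FALSE)
  f <- target_spacing_mm / grid$spacing
  if (any(abs(f - round(f)) > 1e-8))
    stop("target spacing must be an integer multiple of the source spacing",
         call. = FALSE)
  f <- as.integer(round(f))
  if (all(f == 1L)) return(grid)
  d <- dim(grid$values)
  dc <- as.integer(ceiling(d / f))
  idx1 <- (seq_len(d[1]) - 1L) %/% f[1]
  idx2 <- (seq_len(d[2]) - 1L) %/% f[2]
  idx3 <- (seq_len(d[3]) - 1L) %/% f[3]
  group <- 1L + outer(outer(idx1, idx2 * dc[1], `+`), idx3 * dc[1] * dc[2], `+`)
  block_mean <- function(x) {
    s <- rowsum(as.vector(x), as.vector(group))
    n <- rowsum(rep(1, length(group)), as.vector(group))
    array(as.vector(s / n), dc)
  }
  vals <- block_mean(grid$values)
  mask <- block_mean(grid$mask * 1) >= 0.5
  aff <- grid$affine
  # block centre of coarse voxel k lies at fine index k*f + (f-1)/2
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% ((f - 1) / 2)
  aff[1:3, 1:3] <- aff[1:3, 1:3] %*% diag(f)
  voxel_grid(vals, spacing = grid$spacing * f, mask = array(mask, dc),
             tissue = grid$tissue, affine = aff)
}

#' Total tissue volumes and TIV
#'
#' Sums each tissue probability map over the brain mask and multiplies by the
#' voxel volume; total intracranial volume (TIV) is the sum of the three.
#'
#' @param gm,wm,csf [voxel_grid]s sharing shape and spacing.
#' @return A list with `gm_ml`, `wm_ml`, `csf_ml`, `tiv_ml` (millilitres).
#' @examples
#' m <- array(TRUE, c(4, 4, 4))
#' g <- voxel_grid(array(1, c(4, 4, 4)), 8, m, "GM")
#' w <- voxel_grid(array(0, c(4, 4, 4)), 8, m, "WM")
#' c_ <- voxel_grid(array(0, c(4, 4, 4)), 8, m, "CSF")
#' tissue_volumes(g, w, c_)$gm_ml # 64 voxels * 0.512 ml
#' @export
tissue_volumes <- function(gm, wm, csf) {
  grids <- list(gm, wm, csf)
  stopifnot(all(vapply(grids, inherits, logical(1), "voxel_grid")))
  dims <- lapply(grids, function(g) dim(g$values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("tissue maps must share the same shape", call. = FALSE)
  sp <- lapply(grids, `[[`, "spacing")
  if (!all(vapply(sp, function(s) all(abs(s - sp[[1]]) < 1e-9), logical(1))))
    stop("tissue maps must share the same spacing", call. = FALSE)
  voxel_ml <- prod(gm$spacing) / 1000
  vol <- function(g) sum(g$values[g$mask]) * voxel_ml
  out <- list(gm_ml = vol(gm), wm_ml = vol(wm), csf_ml = vol(csf))
  out$tiv_ml <- out$gm_ml + out$wm_ml + out$csf_ml
  out
}

#' Striatal binding ratio
#'
#' The SBR of a target region against a reference region is the ratio of mean
#' uptakes minus one, so equal uptake gives 0.
#'
#' @param target_mean Mean uptake in the target region (vectorized).
#' @param reference_mean Mean uptake in the reference region, `> 0`.
#' @return `target_mean / reference_mean - 1`.
#' @examples
#' sbr(3, 1.5) # 1
#' @export
sbr <- function(target_mean, reference_mean) {
  if (any(!is.finite(reference_mean)) || any(reference_mean <= 0))
    stop("`reference_mean` must be positive", call. = FALSE)
  target_mean / reference_mean - 1
}

# NIfTI I/O -------------------------------------------------------------------

#' Write / read a voxel grid as NIfTI-1
#'
#' Values are stored as float32 with the grid's affine as qform (code 2) and
#' pixdim equal to the spacing; masks round-trip as 0/1 volumes.
#'
#' @param grid A [voxel_grid].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_grid_nifti` returns `path` invisibly; `read_grid_nifti`
#'   returns a [voxel_grid].
#' @export
write_grid_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  ni <- RNifti::asNifti(grid$values)
  RNifti::pixdim(ni) <- grid$spacing
  RNifti::qform(ni) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' @rdname write_grid_nifti
#' @param tissue Tissue label to attach on read.
#' @param mask Optional logical array (e.g. read from a mask volume).
#' @export
read_grid_nifti <- function(path, tissue = c("GM", "WM", "CSF"), mask = NULL) {
  ni <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(ni))
  attributes(aff) <- list(dim = c(4L, 4L))
  voxel_grid(array(as.numeric(ni), dim(ni)[1:3]),
             spacing = RNifti::pixdim(ni)[1:3],
             mask = mask, tissue = match.arg(tissue), affine = aff)
}
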