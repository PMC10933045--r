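#' Volume grids
#'
#' `volume_grid` is the package's common currency for 3D scalar volumes:
#' binary organ masks (values in \{0, 1\}) and dose grids (Gy). The axis
#' convention is fixed: the first array axis is x (patient left-right), the
#' second y (anterior-posterior), the third z (inferior-superior). Voxel
#' `(i, j, k)` (0-based) is centered at `origin + c(i, j, k) * spacing` in mm.
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param origin numeric length-3, physical coordinate of the first voxel, mm.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(spacing) == 3L, length(origin) == 3L)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing entries must be finite and > 0")
  if (!all(is.finite(values)))
    stop("volume values must all be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, spacing %s mm, origin %s mm, range [%g, %g]>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              min(x$values), max(x$values)))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

vg_dim <- function(v) dim(v$values)

#' Check that a volume is a binary mask
#'
#' @param v a `volume_grid`.
#' @param require_nonempty error if the mask has no 1-voxels.
#' @return invisibly, `v`.
#' @export
assert_mask <- function(v, require_nonempty = TRUE) {
  stopifnot(is_volume_grid(v))
  u <- unique(as.vector(v$values))
  if (!all(u %in% c(0, 1)))
    stop("mask volume must contain only 0/1 values")
  if (require_nonempty && !any(v$values == 1))
    stop("mask is empty (no 1-voxels)")
  invisible(v)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(vg_dim(a), vg_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

# world coordinates (mm) of all voxel centers, n x 3
vg_coords <- function(v, subset = NULL) {
  d <- vg_dim(v)
  a <- grid_arrayind(d)
  if (!is.null(subset)) a <- a[subset, , drop = FALSE]
  cbind(v$origin[1] + a[, 1] * v$spacing[1],
        v$origin[2] + a[, 2] * v$spacing[2],
        v$origin[3] + a[, 3] * v$spacing[3])
}

#' Resample a volume to a new voxel spacing
#'
#' Resamples onto a grid with the same origin and (approximately) the same
#' physical extent. Linear interpolation for dose-like volumes; nearest
#' neighbour for masks (mask outputs stay binary).
#'
#' @param v a `volume_grid`.
#' @param target_spacing numeric length-3, new spacing in mm (> 0).
#' @param mode `"linear"` or `"nearest"`.
#' @return a `volume_grid` with the requested spacing.
#' @export
vg_resample <- function(v, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is_volume_grid(v), length(target_spacing) == 3L)
  target_spacing <- as.numeric(target_spacing)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be > 0")
  d <- vg_dim(v)
  extent <- (d - 1) * v$spacing            # node-to-node physical extent
  nd <- pmax(2L, as.integer(round(extent / target_spacing)) + 1L)
  a <- arrayInd(seq_len(prod(nd)), nd) - 1L
  # continuous voxel coordinates in the source grid
  pts <- cbind(a[, 1] * target_spacing[1] / v$spacing[1],
               a[, 2] * target_spacing[2] / v$spacing[2],
               a[, 3] * target_spacing[3] / v$spacing[3])
  vals <- cpp_sample(as.numeric(v$values), d, pts,
                     if (mode == "linear") 0L else 1L, 1L, 0)
  volume_grid(array(vals, nd), target_spacing, v$origin)
}

#' Crop a volume to an organ bounding box plus margin
#'
#' The crop box is the mask's tight bounding box dilated by
#' `ceiling(margin / spacing)` voxels per axis and clipped to the volume
#' extent; the origin metadata is updated so physical coordinates are
#' preserved.
#'
#' @param v `volume_grid` to crop.
#' @param mask non-empty binary `volume_grid` on the same grid.
#' @param margin margin in mm (default 4).
#' @return cropped `volume_grid`.
#' @export
vg_crop <- function(v, mask, margin = 4) {
  stopifnot(is_volume_grid(v))
  assert_mask(mask)
  if (!same_grid(v, mask)) stop("volume and mask must share a grid")
  d <- vg_dim(v)
  idx <- which(mask$values == 1)
  a <- arrayInd(idx, d)
  pad <- ceiling(margin / mask$spacing)
  lo <- pmax(1L, apply(a, 2, min) - pad)
  hi <- pmin(d, apply(a, 2, max) + pad)
  out <- v$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  volume_grid(out, v$spacing, v$origin + (lo - 1L) * v$spacing)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Undefined (error) when both masks are
#' empty.
#'
#' @param a,b binary `volume_grid`s on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_mask(a, require_nonempty = FALSE)
  assert_mask(b, require_nonempty = FALSE)
  if (!same_grid(a, b)) stop("masks must share a grid")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) stop("Dice is undefined for two empty masks")
  2 * sum(a$values * b$values) / (na + nb)
}

#' Mirror a volume left-right
#'
#' Reverses the array along the x (left-right) axis. The grid metadata is
#' unchanged: the mirrored volume lives on the same grid, so applying the
#' flip twice is an exact identity and midline-symmetric masks map close to
#' themselves.
#'
#' @param v a `volume_grid`.
#' @return mirrored `volume_grid`.
#' @export
vg_flip_lr <- function(v) {
  stopifnot(is_volume_grid(v))
  d <- vg_dim(v)
  volume_grid(v$values[d[1]:1, , , drop = FALSE], v$spacing, v$origin)
}

#' Mirror all volumes of a patient case left-right
#'
#' @param case a `patient_case`.
#' @return the case with masks and dose mirrored and id suffixed `"_flip"`.
#' @export
flip_case <- function(case) {
  stopifnot(inherits(case, "patient_case"))
  case$pc_mask <- vg_flip_lr(case$pc_mask)
  case$larynx_mask <- vg_flip_lr(case$larynx_mask)
  case$dose <- vg_flip_lr(case$dose)
  case$id <- paste0(case$id, "_flip")
  case$flipped <- TRUE
  case
}
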