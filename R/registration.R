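#' Deformation fields
#'
#' Dense displacement fields on a grid, in the pull-back convention used
#' throughout the package: for each voxel of the grid the field is defined on
#' (the reference frame), the displacement in mm points to the location in
#' the moving volume to sample from. Warping a patient volume into the
#' reference frame therefore reads
#' `warped(x) = moving(x + u(x))`.
#'
#' @param displacement 4D array `c(dim, 3)` of mm displacements.
#' @param spacing,origin grid metadata, mm.
#' @param components character vector naming the composed stages.
#' @return an object of class `deformation_field`.
#' @export
deformation_field <- function(displacement, spacing, origin = c(0, 0, 0),
                              components = character()) {
  stopifnot(is.array(displacement), length(dim(displacement)) == 4L,
            dim(displacement)[4] == 3L)
  if (!all(is.finite(displacement))) stop("displacements must be finite")
  structure(list(displacement = displacement, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), components = components),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  nrm <- sqrt(rowSums(matrix(x$displacement, ncol = 3)^2))
  cat(sprintf("<deformation_field %s, |u| mean %.2f max %.2f mm, stages: %s>\n",
              paste(dim(x$displacement)[1:3], collapse = "x"),
              mean(nrm), max(nrm),
              paste(x$components, collapse = "+")))
  invisible(x)
}

zero_field <- function(d, spacing, origin = c(0, 0, 0)) {
  deformation_field(array(0, c(d, 3L)), spacing, origin, "identity")
}

field_norms <- function(field) {
  sqrt(rowSums(matrix(field$displacement, ncol = 3)^2))
}

#' Warp a volume through a deformation field
#'
#' Pull-back resampling: the output lives on the field's grid and samples the
#' input volume at `x + u(x)`. Linear interpolation for dose, nearest for
#' masks. Sample points falling outside the moving volume take the value 0;
#' their count is attached as attribute `"n_outside"`.
#'
#' @param v `volume_grid` to warp (must share the field's grid metadata).
#' @param field a `deformation_field`.
#' @param mode `"linear"` or `"nearest"`.
#' @return warped `volume_grid`.
#' @export
warp <- function(v, field, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is_volume_grid(v), inherits(field, "deformation_field"))
  d <- dim(field$displacement)[1:3]
  if (!identical(vg_dim(v), d)) stop("volume and field grids differ")
  vals <- cpp_pullback(as.numeric(v$values), d, field$spacing,
                       as.numeric(field$displacement),
                       if (mode == "linear") 0L else 1L, 0L, 0)
  out <- volume_grid(array(vals, d), field$spacing, field$origin)
  attr(out, "n_outside") <- attr(vals, "n_outside")
  out
}

# ---- internal geometry helpers --------------------------------------------

mask_centroid <- function(mask) {
  idx <- which(mask$values == 1)
  colMeans(vg_coords(mask, idx))
}

mask_cov <- function(mask) {
  idx <- which(mask$values == 1)
  stats::cov(vg_coords(mask, idx))
}

sqrtm3 <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
}

# displacement field of the affine map y -> c_m + A (y - c_f), pull-back form
affine_disp <- function(d, spacing, origin, A, c_f, c_m) {
  a <- grid_arrayind(d)
  y <- cbind(origin[1] + a[, 1] * spacing[1],
             origin[2] + a[, 2] * spacing[2],
             origin[3] + a[, 3] * spacing[3])
  u <- sweep(y, 2, c_f) %*% t(A)
  u <- sweep(u, 2, c_m, "+") - y
  array(u, c(d, 3L))
}

signed_distance <- function(mask, cap = 20) {
  d <- vg_dim(mask)
  inside <- mask$values == 1
  sd <- cpp_edt3(as.vector(inside), d, mask$spacing) -
        cpp_edt3(as.vector(!inside), d, mask$spacing)
  pmin(pmax(sd, -cap), cap)
}

# resample a plain array (linear) onto a new grid sharing the origin
resample_arr <- function(arr, d, spacing, nd, nspacing) {
  a <- arrayInd(seq_len(prod(nd)), nd) - 1L
  pts <- cbind(a[, 1] * nspacing[1] / spacing[1],
               a[, 2] * nspacing[2] / spacing[2],
               a[, 3] * nspacing[3] / spacing[3])
  array(cpp_sample(as.numeric(arr), d, pts, 0L, 1L, 0), nd)
}

dice_through <- function(moving, fixed, disp) {
  d <- vg_dim(fixed)
  w <- cpp_pullback(as.numeric(moving$values), d, fixed$spacing,
                    as.numeric(disp), 1L, 0L, 0)
  2 * sum(w * as.numeric(fixed$values)) /
    (sum(w) + sum(fixed$values))
}

# demons-style refinement of a pull-back field on signed distance maps.
# u_base (the rigid/affine initialization) is held fixed; only the demons
# increment v is regularized, so elastic smoothing cannot corrupt the
# spatially linear base transform. The iteration loop runs in C++.
demons_refine <- function(f_sdt, m_sdt, u_base, v, d, spacing, iters,
                          sigma_elastic = 2.5, max_step = 2) {
  cpp_demons(f_sdt, m_sdt, u_base, v, d, spacing, as.integer(iters),
             sigma_elastic, max_step)
}

#' Registration parameter defaults
#'
#' @param qc_threshold Dice QC gate (default 0.7).
#' @param sdt_cap clamp of the signed distance surrogate, mm.
#' @param iters iterations per resolution level (coarse to fine).
#' @param sigma_elastic field smoothing per iteration, mm.
#' @param max_step per-iteration displacement update cap, mm.
#' @return a named list of parameters.
#' @export
registration_params <- function(qc_threshold = 0.7, sdt_cap = 20,
                                iters = c(40, 10), sigma_elastic = 2,
                                max_step = 3) {
  list(qc_threshold = qc_threshold, sdt_cap = sdt_cap, iters = iters,
       sigma_elastic = sigma_elastic, max_step = max_step)
}

#' Register a moving organ mask to a fixed (reference) mask
#'
#' Contour-driven registration on signed distance surrogates of the masks
#' (binary images give vanishing gradients): a moments-based rigid stage
#' (centroid alignment), a principal-axes affine stage (covariance matching),
#' then a multi-resolution demons-style deformable stage. After every stage
#' the Dice coefficient of the warped moving mask against the fixed mask is
#' evaluated and the stage is kept only if it improves Dice, so the final
#' field never degrades the initial overlap.
#'
#' @param moving,fixed non-empty binary `volume_grid`s on a common grid.
#' @param params see [registration_params()].
#' @return a list with elements `field` (a [deformation_field()]) and `qc`
#'   (list: `dice_before`, `dice_after`, `pass_flag`).
#' @export
register <- function(moving, fixed, params = registration_params()) {
  assert_mask(moving); assert_mask(fixed)
  if (!same_grid(moving, fixed)) stop("masks must be resampled to a common grid")
  if (sum(moving$values) < 2 || sum(fixed$values) < 2)
    stop("degenerate (single-voxel) mask cannot be registered")
  d <- vg_dim(fixed)
  spacing <- fixed$spacing

  best_u <- array(0, c(d, 3L))
  best_dice <- dice(moving, fixed)
  dice_before <- best_dice
  stages <- "identity"

  # rigid: centroid translation (pull-back: sample moving at +(c_m - c_f))
  c_f <- mask_centroid(fixed); c_m <- mask_centroid(moving)
  u_rigid <- array(rep(c_m - c_f, each = prod(d)), c(d, 3L))
  d_rigid <- dice_through(moving, fixed, u_rigid)
  if (d_rigid > best_dice) {
    best_u <- u_rigid; best_dice <- d_rigid; stages <- c(stages, "rigid")
  }

  # affine: principal-axes covariance matching about the centroids
  A <- tryCatch(sqrtm3(mask_cov(moving)) %*% solve(sqrtm3(mask_cov(fixed))),
                error = function(e) NULL)
  if (!is.null(A)) {
    u_aff <- affine_disp(d, spacing, fixed$origin, A, c_f, c_m)
    d_aff <- dice_through(moving, fixed, u_aff)
    if (d_aff > best_dice) {
      best_u <- u_aff; best_dice <- d_aff; stages <- c(stages, "affine")
    }
  }

  # deformable: multi-resolution demons on clamped signed distance maps,
  # refining an increment v on top of the best rigid/affine base
  f_sdt <- signed_distance(fixed, params$sdt_cap)
  m_sdt <- signed_distance(moving, params$sdt_cap)
  n_levels <- length(params$iters)
  u_base <- as.numeric(best_u)
  v <- numeric(length(u_base))
  downsample_field <- function(w, nd, nsp) {
    out <- numeric(prod(nd) * 3)
    for (cmp in 1:3) {
      comp <- resample_arr(array(w[(cmp - 1) * prod(d) + seq_len(prod(d))], d),
                           d, spacing, nd, nsp)
      out[(cmp - 1) * prod(nd) + seq_len(prod(nd))] <- as.numeric(comp)
    }
    out
  }
  upsample_field <- function(w, nd, nsp) {
    out <- numeric(prod(d) * 3)
    for (cmp in 1:3) {
      comp <- resample_arr(array(w[(cmp - 1) * prod(nd) + seq_len(prod(nd))], nd),
                           nd, nsp, d, spacing)
      out[(cmp - 1) * prod(d) + seq_len(prod(d))] <- as.numeric(comp)
    }
    out
  }
  for (lev in seq_len(n_levels)) {
    fac <- 2^(n_levels - lev)
    if (fac > 1) {
      nd <- pmax(4L, as.integer(ceiling(d / fac)))
      nsp <- spacing * (d - 1) / pmax(nd - 1, 1)
      f_l <- as.numeric(resample_arr(array(f_sdt, d), d, spacing, nd, nsp))
      m_l <- as.numeric(resample_arr(array(m_sdt, d), d, spacing, nd, nsp))
      v_l <- demons_refine(f_l, m_l, downsample_field(u_base, nd, nsp),
                           downsample_field(v, nd, nsp), nd, nsp,
                           params$iters[lev], params$sigma_elastic,
                           params$max_step)
      v <- upsample_field(v_l, nd, nsp)
    } else {
      v <- demons_refine(f_sdt, m_sdt, u_base, v, d, spacing,
                         params$iters[lev], params$sigma_elastic,
                         params$max_step)
    }
  }
  u <- array(u_base + v, c(d, 3L))
  d_def <- dice_through(moving, fixed, u)
  if (d_def > best_dice) {
    best_u <- u; best_dice <- d_def; stages <- c(stages, "deformable")
  }

  field <- deformation_field(best_u, spacing, fixed$origin, stages)
  qc <- list(dice_before = dice_before, dice_after = best_dice,
             pass_flag = best_dice > params$qc_threshold)
  list(field = field, qc = qc)
}
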