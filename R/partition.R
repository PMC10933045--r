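#' Partition the reference organs into dosimetric subregions
#'
#' The pharyngeal constrictor mask is split into equal-extent cranio-caudal
#' thirds (superior / middle / inferior, by the z-slices the mask spans) and,
#' crossed with that, into midline vs lateral voxels
#' (`|x - x_mid| <= midline_halfwidth`); the larynx is split into a superior
#' (supraglottic-like) region — the top `larynx_sup_frac` of its z-extent —
#' and the rest. This yields the 8 dosimetric regions of the regional dose
#' model (6 PC + 2 larynx).
#'
#' @param ref a [make_reference()] anatomy (or any list with `pc_mask`,
#'   `larynx_mask`).
#' @param midline_halfwidth half-width of the midline band, mm (default 10).
#' @param larynx_sup_frac fraction of the larynx z-extent counted as
#'   superior (default 1/3).
#' @return an object of class `subregion_partition`: integer label array on
#'   the reference grid (0 outside both organs) plus the level names.
#' @export
partition_subregions <- function(ref, midline_halfwidth = 10,
                                 larynx_sup_frac = 1 / 3) {
  pc <- ref$pc_mask; lar <- ref$larynx_mask
  assert_mask(pc); assert_mask(lar)
  d <- vg_dim(pc)
  levels <- c("pc_superior_midline", "pc_superior_lateral",
              "pc_middle_midline", "pc_middle_lateral",
              "pc_inferior_midline", "pc_inferior_lateral",
              "larynx_superior", "larynx_inferior")
  lab <- array(0L, d)

  idx_pc <- which(pc$values == 1)
  a <- arrayInd(idx_pc, d)
  x_mm <- pc$origin[1] + (a[, 1] - 1L) * pc$spacing[1]
  x_mid <- mean(x_mm)
  zsl <- a[, 3]
  zmin <- min(zsl); zmax <- max(zsl)
  span <- zmax - zmin + 1L
  n_sup <- ceiling(span / 3)
  n_inf <- floor(span / 3)
  third <- ifelse(zsl > zmax - n_sup, 1L,          # superior
                  ifelse(zsl < zmin + n_inf, 3L, 2L))  # inferior / middle
  midline <- abs(x_mm - x_mid) <= midline_halfwidth
  lab[idx_pc] <- (third - 1L) * 2L + ifelse(midline, 1L, 2L)

  idx_l <- which(lar$values == 1)
  al <- arrayInd(idx_l, d)
  zl <- al[, 3]
  zl_min <- min(zl); zl_max <- max(zl)
  n_lsup <- ceiling((zl_max - zl_min + 1L) * larynx_sup_frac)
  lab[idx_l] <- ifelse(zl > zl_max - n_lsup, 7L, 8L)

  counts <- tabulate(lab[lab > 0], nbins = 8L)
  if (any(counts == 0))
    stop("empty subregion(s): ", paste(levels[counts == 0], collapse = ", "))
  structure(list(labels = lab, levels = levels, spacing = pc$spacing,
                 origin = pc$origin, counts = stats::setNames(counts, levels)),
            class = "subregion_partition")
}

#' Voxel indices of a subregion (or cranio-caudal group)
#'
#' @param partition a [partition_subregions()] result.
#' @param label one of the 8 partition labels, a group label
#'   (`"pc_superior"`, `"pc_middle"`, `"pc_inferior"`, `"pc"`, `"larynx"`),
#'   covering all matching regions.
#' @return integer voxel indices into the reference grid.
#' @export
partition_indices <- function(partition, label) {
  stopifnot(inherits(partition, "subregion_partition"))
  hit <- if (label %in% partition$levels) {
    which(partition$levels == label)
  } else {
    grep(paste0("^", label, "(_|$)"), partition$levels)
  }
  if (length(hit) == 0) stop("unknown partition label: ", label)
  which(partition$labels %in% hit)
}

#' Mean dose per subregion
#'
#' @param dose_values dose values aligned with the reference grid: either a
#'   `volume_grid` or a bare numeric vector of full-grid values.
#' @param partition a [partition_subregions()] result.
#' @return named numeric vector of 8 regional mean doses, Gy.
#' @export
region_mean_doses <- function(dose_values, partition) {
  v <- if (is_volume_grid(dose_values)) as.numeric(dose_values$values) else dose_values
  out <- vapply(seq_along(partition$levels), function(l) {
    mean(v[partition$labels == l])
  }, numeric(1))
  stats::setNames(out, partition$levels)
}
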