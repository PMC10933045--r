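#' RBE scaling of dose grids
#'
#' Proton physical doses are multiplied by 1.1 to account for relative
#' biological effectiveness relative to photon plans; photon doses are
#' unchanged. The result carries a `"rbe_scaled"` attribute and scaling an
#' already-scaled proton dose is an error, so the factor can only ever be
#' applied once in a pipeline.
#'
#' @param dose a `volume_grid` with non-negative values.
#' @param modality `"photon"` or `"proton"`.
#' @return the (possibly scaled) `volume_grid`, flagged as scaled.
#' @export
rbe_scale <- function(dose, modality) {
  stopifnot(is_volume_grid(dose))
  if (any(dose$values < 0)) stop("dose must be non-negative")
  if (!modality %in% c("photon", "proton"))
    stop("unknown modality: ", modality)
  if (isTRUE(attr(dose, "rbe_scaled")) && modality == "proton")
    stop("dose is already RBE-scaled; the 1.1 factor must be applied exactly once")
  if (modality == "proton") dose$values <- dose$values * 1.1
  attr(dose, "rbe_scaled") <- TRUE
  dose
}

#' Mean dose inside a mask
#'
#' @param dose dose `volume_grid`.
#' @param mask non-empty binary `volume_grid` on the same grid.
#' @return mean dose over mask voxels, Gy.
#' @export
mean_dose <- function(dose, mask) {
  stopifnot(is_volume_grid(dose))
  assert_mask(mask)
  if (!same_grid(dose, mask)) stop("dose and mask must share a grid")
  mean(dose$values[mask$values == 1])
}

#' VxGy: percent organ volume receiving at least x Gy
#'
#' The threshold is inclusive (dose >= x).
#'
#' @param dose dose `volume_grid`.
#' @param mask non-empty binary `volume_grid` on the same grid.
#' @param x dose threshold, Gy (>= 0).
#' @return percent of mask voxels with dose >= x.
#' @export
v_at_dose <- function(dose, mask, x) {
  stopifnot(is_volume_grid(dose))
  assert_mask(mask)
  if (!same_grid(dose, mask)) stop("dose and mask must share a grid")
  if (x < 0) stop("dose threshold must be >= 0")
  d <- dose$values[mask$values == 1]
  100 * sum(d >= x) / length(d)
}

#' Cumulative dose-volume histogram
#'
#' @param dose dose `volume_grid`.
#' @param mask non-empty binary `volume_grid` on the same grid.
#' @param bin_width DVH bin width, Gy (default 0.1).
#' @return a list of class `dvh_curve`: `dose_edges` (Gy, ascending) and
#'   `volume_percent` (non-increasing; 100 at 0 Gy, 0 above the max dose).
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  stopifnot(is_volume_grid(dose))
  assert_mask(mask)
  if (!same_grid(dose, mask)) stop("dose and mask must share a grid")
  d <- dose$values[mask$values == 1]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  vp <- vapply(edges, function(x) 100 * sum(d >= x) / length(d), numeric(1))
  structure(list(dose_edges = edges, volume_percent = vp), class = "dvh_curve")
}

#' The seven clinical DVH metrics of the DVH-metrics model
#'
#' Mean pharyngeal constrictor dose, mean larynx dose, PC V50/V55/V60 Gy and
#' larynx V50/V60 Gy, computed on RBE-scaled dose in the patient frame. If
#' the dose has not yet been RBE-scaled, `modality` must be supplied and the
#' scaling is applied here (exactly once).
#'
#' @param dose dose `volume_grid` (patient frame).
#' @param pc_mask,larynx_mask organ masks on the dose grid.
#' @param modality `"photon"` or `"proton"`; ignored when `dose` is already
#'   flagged as scaled.
#' @param include_v65 also report PC V65Gy (off by default; the canonical
#'   metric set uses V50/V55/V60).
#' @return named numeric vector of metrics.
#' @export
dvh_feature_set <- function(dose, pc_mask, larynx_mask, modality = "photon",
                            include_v65 = FALSE) {
  if (is.null(pc_mask) || is.null(larynx_mask))
    stop("both organ masks are required for the DVH feature set")
  if (!isTRUE(attr(dose, "rbe_scaled"))) dose <- rbe_scale(dose, modality)
  out <- c(pc_mean_dose = mean_dose(dose, pc_mask),
           larynx_mean_dose = mean_dose(dose, larynx_mask),
           pc_v50 = v_at_dose(dose, pc_mask, 50),
           pc_v55 = v_at_dose(dose, pc_mask, 55),
           pc_v60 = v_at_dose(dose, pc_mask, 60),
           larynx_v50 = v_at_dose(dose, larynx_mask, 50),
           larynx_v60 = v_at_dose(dose, larynx_mask, 60))
  if (include_v65) out <- c(out, pc_v65 = v_at_dose(dose, pc_mask, 65))
  out
}
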