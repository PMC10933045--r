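#' Synthetic reference anatomy
#'
#' Builds a reference patient's organ masks on a regular grid: a curved,
#' posterior, sheet-like tubular structure standing in for the pharyngeal
#' constrictor muscles (a half-annular shell whose radius widens superiorly
#' and whose center bows posteriorly), and an ellipsoidal midline structure
#' standing in for the larynx, sitting anterior-inferior and overlapping the
#' lower part of the constrictor z-range. Both organs are exactly symmetric
#' about the grid midline before voxelization. The seed drives small smooth
#' axial perturbations of the organ outline (radius and posterior bow), so
#' distinct seeds give slightly different but deterministic references.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm (default `c(1.27, 1.27, 1)`).
#' @param seed integer seed.
#' @return a list of class `reference_anatomy`: `pc_mask`, `larynx_mask`
#'   (binary `volume_grid`s), `spacing`, `origin`, `shape`.
#' @export
make_reference <- function(shape = c(96, 96, 120), spacing = c(1.27, 1.27, 1),
                           seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(spacing) == 3L)
  ext <- (shape - 1L) * spacing
  # fixed anatomical sizes (mm); the grid must fit them with a 4 mm margin
  pc_span <- 48; pc_r0 <- 13; pc_r1 <- 15.5; pc_t <- 3.6
  lar_a <- 13; lar_b <- 10; lar_c <- 17
  need <- c(2 * (pc_r1 + pc_t / 2 + 2) + 8,           # x extent
            (lar_b + 14) + (3 + pc_r1 + pc_t / 2) + 8, # y extent
            pc_span + 14 + 9 + 8)                      # z extent
  if (any(ext < need))
    stop(sprintf(
      "grid too small for reference organs + 4 mm margin: extent %s mm, need at least %s mm",
      paste(round(ext, 1), collapse = "x"), paste(ceiling(need), collapse = "x")))

  x_c <- ext[1] / 2
  y_c <- ext[2] * 0.55
  z1 <- ext[3] - 14; z0 <- z1 - pc_span

  # smooth seeded axial perturbations (functions of z only: keeps L-R symmetry)
  zs <- seq(0, ext[3], length.out = 9)
  pert <- with_seed(seed, list(r = rnorm(9, 0, 1), y = rnorm(9, 0, 1)))
  fr <- stats::splinefun(zs, pert$r)
  fy <- stats::splinefun(zs, pert$y)

  n <- prod(shape)
  a <- arrayInd(seq_len(n), shape) - 1L
  x <- a[, 1] * spacing[1]; y <- a[, 2] * spacing[2]; z <- a[, 3] * spacing[3]

  tz <- pmin(pmax((z - z0) / pc_span, 0), 1)
  y_pc <- y_c + 3 * sin(pi * tz) + 1.2 * fy(z)
  r_pc <- (pc_r0 + (pc_r1 - pc_r0) * tz) * (1 + 0.04 * tanh(fr(z)))
  R <- sqrt((x - x_c)^2 + (y - y_pc)^2)
  pc <- (z >= z0) & (z <= z1) & (abs(R - r_pc) <= pc_t / 2) &
        ((y - y_pc) >= -0.35 * r_pc)

  y_l <- y_c - 14; z_l <- z0 + 8
  lar <- ((x - x_c) / lar_a)^2 + ((y - y_l) / lar_b)^2 + ((z - z_l) / lar_c)^2 <= 1

  ref <- structure(list(
    pc_mask = volume_grid(array(as.numeric(pc), shape), spacing),
    larynx_mask = volume_grid(array(as.numeric(lar), shape), spacing),
    spacing = as.numeric(spacing), origin = c(0, 0, 0), shape = shape,
    geometry = list(x_c = x_c, y_c = y_c, z0 = z0, z1 = z1, pc_span = pc_span)),
    class = "reference_anatomy")
  assert_mask(ref$pc_mask); assert_mask(ref$larynx_mask)
  ref
}

#' Covariate sampling model
#'
#' Marginal distributions of the clinical covariates. Binary frequencies and
#' the means of continuous covariates follow the study-population summaries
#' the generator emulates (e.g. 85/231 primary-treatment, 156/231
#' chemotherapy, mean age ~61 y, ADI mean ~45); joint dependence is not
#' modeled except for the deliberate coupling of the `bilateral` covariate to
#' dose laterality in [sample_patient()].
#'
#' @param p named probabilities for binary covariates.
#' @param weight_mean,weight_sd baseline weight distribution, kg.
#' @param adi_mean,adi_sd area deprivation index distribution (clipped 1-100).
#' @param age_mean,age_sd age distribution, years (clipped 23-89).
#' @return a named list (class `covariate_model`) with a `means` element
#'   giving the expected value of every covariate (used for centering in the
#'   outcome truth model).
#' @export
covariate_model <- function(p = c(treatment_setting = 85 / 231, bilateral = 0.5,
                                  chemotherapy = 156 / 231, dysphagia_grade0 = 0.65,
                                  gender = 189 / 231, modality_proton = 100 / 231,
                                  smoker = 120 / 231),
                            weight_mean = 82, weight_sd = 16,
                            adi_mean = 45, adi_sd = 25,
                            age_mean = 61, age_sd = 12) {
  m <- list(p = p, weight_mean = weight_mean, weight_sd = weight_sd,
            adi_mean = adi_mean, adi_sd = adi_sd,
            age_mean = age_mean, age_sd = age_sd)
  m$means <- c(p, baseline_weight = weight_mean, adi = adi_mean, age = age_mean)
  class(m) <- "covariate_model"
  m
}

sample_covariates <- function(cov_model) {
  p <- cov_model$p
  cv <- as.list(stats::setNames(as.numeric(runif(length(p)) < p), names(p)))
  cv$baseline_weight <- min(max(rnorm(1, cov_model$weight_mean, cov_model$weight_sd), 45), 140)
  cv$adi <- round(min(max(rnorm(1, cov_model$adi_mean, cov_model$adi_sd), 1), 100))
  cv$age <- round(min(max(rnorm(1, cov_model$age_mean, cov_model$age_sd), 23), 89))
  cv
}

#' Outcome truth model
#'
#' The planted logistic ground truth used to generate outcomes:
#' `p = logistic(intercept + dose_effect * (mean planted-subregion dose -
#' dose_center) + sum_j beta_j (x_j - center_j))`. Covariate log-odds default
#' to the log odds ratios of the emulated study population (risk increases
#' with primary treatment setting, bilateral treatment, chemotherapy, weight
#' and ADI; decreases with baseline dysphagia grade 0). Continuous and binary
#' covariates are centered at their sampling means so the intercept controls
#' the outcome prevalence directly.
#'
#' @param intercept log-odds intercept (default 0.1, prevalence ~0.53).
#' @param dose_effect log-odds per Gy of mean (RBE-scaled) dose to the
#'   planted subregion; default 0.15.
#' @param planted_subregion a partition label (e.g. `"pc_superior_midline"`,
#'   `"larynx_superior"`) or a cranio-caudal group (`"pc_superior"`,
#'   `"pc_middle"`, `"pc_inferior"`) covering both midline and lateral parts.
#' @param covariate_effects named log-odds per covariate (per unit for
#'   continuous covariates).
#' @param dose_center Gy value at which the dose term is centered.
#' @param centers named centering constants for covariates (defaults to the
#'   [covariate_model()] means).
#' @param noise_seed integer seed of the Bernoulli outcome noise.
#' @return an object of class `outcome_truth_model`.
#' @export
outcome_truth_model <- function(intercept = 0.1, dose_effect = 0.15,
                                planted_subregion = "pc_superior",
                                covariate_effects = log(c(
                                  treatment_setting = 4.62, bilateral = 6.72,
                                  chemotherapy = 2.54, baseline_weight = 1.014,
                                  adi = 1.014, dysphagia_grade0 = 0.51,
                                  gender = 1.63, modality_proton = 0.69,
                                  smoker = 1.28, age = 0.99)),
                                dose_center = 18,
                                centers = covariate_model()$means,
                                noise_seed = 1) {
  valid <- c(paste0("pc_", rep(c("superior", "middle", "inferior"), each = 2),
                    "_", c("midline", "lateral")),
             "larynx_superior", "larynx_inferior",
             "pc_superior", "pc_middle", "pc_inferior")
  if (!planted_subregion %in% valid)
    stop("planted_subregion must be one of: ", paste(valid, collapse = ", "))
  structure(list(intercept = intercept, dose_effect = dose_effect,
                 planted_subregion = planted_subregion,
                 covariate_effects = covariate_effects,
                 dose_center = dose_center, centers = centers,
                 noise_seed = as.integer(noise_seed)),
            class = "outcome_truth_model")
}

# ---- deformation + dose sampling ------------------------------------------

# smooth band-limited random vector field, max norm = amplitude (mm).
# The white noise is generated and smoothed on a 4x coarser grid and
# trilinearly upsampled: for a field band-limited at sigma >> voxel size this
# is equivalent to full-resolution smoothing and far cheaper.
random_smooth_field <- function(d, spacing, sigma_mm, amplitude, factor = 4L) {
  dc <- pmax(4L, as.integer(ceiling(d / factor)))
  spc <- spacing * (d - 1) / pmax(dc - 1, 1)
  nc <- prod(dc)
  u <- array(0, c(d, 3L))
  a <- grid_arrayind(d)
  pts <- cbind(a[, 1] * spacing[1] / spc[1], a[, 2] * spacing[2] / spc[2],
               a[, 3] * spacing[3] / spc[3])
  for (cmp in 1:3) {
    coarse <- cpp_smooth3(rnorm(nc), dc, sigma_mm / spc)
    u[, , , cmp] <- array(cpp_sample(coarse, dc, pts, 0L, 1L, 0), d)
  }
  nrm <- sqrt(rowSums(matrix(u, ncol = 3)^2))
  mx <- max(nrm)
  if (mx > 0) u <- u * (amplitude / mx)
  u
}

affine_jitter_disp <- function(d, spacing, rot_deg, scale, trans) {
  th <- rot_deg * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  A <- Rz %*% diag(scale)
  ctr <- (d - 1) * spacing / 2
  a <- grid_arrayind(d)
  y <- cbind(a[, 1] * spacing[1], a[, 2] * spacing[2], a[, 3] * spacing[3])
  u <- sweep(y, 2, ctr) %*% t(A)
  u <- sweep(u, 2, ctr + trans, "+") - y
  array(u, c(d, 3L))
}

# evaluate the analytic dose model at physical points (patient frame)
dose_eval <- function(dose_params, pts) {
  out <- 0
  for (b in seq_len(nrow(dose_params$centers))) {
    ctr <- dose_params$centers[b, ]
    sg <- dose_params$sigmas[b, ]
    q <- ((pts[, 1] - ctr[1]) / sg[1])^2 + ((pts[, 2] - ctr[2]) / sg[2])^2 +
         ((pts[, 3] - ctr[3]) / sg[3])^2
    out <- pmax(out, exp(-0.5 * q))
  }
  dose_params$prescription * out
}

# compact representation of the generating forward warp
#   w(y) = A (y - ctr) + ctr + t - y  +  damp * noise(y)
# with the band-limited noise stored on its coarse generation grid. Cases
# carry this object instead of a dense field (which would cost ~8 MB/case).
truth_warp_eval <- function(tw, pts) {
  u <- sweep(pts, 2, tw$ctr) %*% t(tw$A)
  u <- sweep(u, 2, tw$ctr + tw$trans, "+") - pts
  if (!is.null(tw$coarse)) {
    q <- cbind(pts[, 1] / tw$spc[1], pts[, 2] / tw$spc[2], pts[, 3] / tw$spc[3])
    for (cmp in 1:3)
      u[, cmp] <- u[, cmp] +
        tw$damp * cpp_sample(as.numeric(tw$coarse[, , , cmp]), tw$dc, q, 0L, 1L, 0)
  }
  u
}

# materialize the case's generating warp as a dense field on the ref grid
truth_field_of <- function(case, ref) {
  d <- ref$shape
  u <- truth_warp_eval(case$truth_warp, vg_coords(ref$pc_mask))
  deformation_field(array(u, c(d, 3L)), ref$spacing, ref$origin, "synthetic")
}

# numerically invert the forward field w (reference -> patient sampling) so
# patient volumes can be materialized: solve q + w(q) = x by fixed point
invert_field_points <- function(w, d, spacing, iters = 8) {
  a <- grid_arrayind(d)
  x <- cbind(a[, 1], a[, 2], a[, 3])          # voxel coords
  q <- x
  wv <- matrix(as.numeric(w), ncol = 3)
  for (it in seq_len(iters)) {
    wx <- cbind(cpp_sample(wv[, 1], d, q, 0L, 1L, 0),
                cpp_sample(wv[, 2], d, q, 0L, 1L, 0),
                cpp_sample(wv[, 3], d, q, 0L, 1L, 0))
    q <- x - sweep(wx, 2, spacing, "/")
  }
  q
}

#' Sample one synthetic patient
#'
#' Draws clinical covariates, a smooth random anatomical deformation (affine
#' jitter plus a band-limited displacement field), and an analytic dose
#' distribution (one lateralized high-dose target, or two mirrored targets
#' when the `bilateral` covariate is 1, peak dose equal to the sampled
#' prescription in 30-81.6 Gy). Patient masks are the reference masks carried
#' through the deformation; the generating field is retained on the case so
#' the exact normalization is recoverable.
#'
#' @param ref a [make_reference()] anatomy.
#' @param cov_model a [covariate_model()].
#' @param seed integer seed (one patient = one substream).
#' @param max_displacement cap of the random deformation, mm (default 8).
#' @param field_sigma Gaussian smoothing of the displacement noise, mm
#'   (default 12).
#' @param volumes materialize mask/dose volumes (`TRUE`) or keep the case
#'   analytic-only (covariates, truth warp and dose parameters; volumes can
#'   be added later with [materialize_case()]).
#' @param affine_jitter include the global affine jitter component (disable
#'   together with `max_displacement = 0` for an identity deformation).
#' @return an object of class `patient_case`.
#' @export
sample_patient <- function(ref, cov_model = covariate_model(), seed = 1,
                           max_displacement = 8, field_sigma = 12,
                           volumes = TRUE, affine_jitter = TRUE) {
  stopifnot(inherits(ref, "reference_anatomy"))
  d <- ref$shape; spacing <- ref$spacing
  geo <- ref$geometry
  case <- with_seed(seed, {
    cv <- sample_covariates(cov_model)
    prescription <- runif(1, 30, 81.6)
    amp <- runif(1, 0.3, 1) * max_displacement
    rot <- runif(1, -4, 4)
    scl <- runif(3, 0.95, 1.05)
    trs <- runif(3, -3, 3)
    if (!affine_jitter) { rot <- 0; scl <- c(1, 1, 1); trs <- c(0, 0, 0) }
    th <- rot * pi / 180
    A <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
      diag(scl)
    coarse <- NULL
    dc <- pmax(4L, as.integer(ceiling(d / 4L)))
    spc <- spacing * (d - 1) / pmax(dc - 1, 1)
    if (max_displacement > 0) {
      coarse <- array(0, c(dc, 3L))
      for (cmp in 1:3)
        coarse[, , , cmp] <- array(cpp_smooth3(rnorm(prod(dc)), dc, field_sigma / spc), dc)
      mx <- max(sqrt(rowSums(matrix(coarse, ncol = 3)^2)))
      if (mx > 0) coarse <- coarse * (amp / mx)
    }
    tw <- list(A = A, trans = trs, ctr = (d - 1) * spacing / 2,
               coarse = coarse, dc = dc, spc = spc, damp = 1)
    # dose target(s): anywhere along the pharyngeal/laryngeal column, as in a
    # cohort spanning many treatment sites (oropharynx to larynx)
    z_t <- geo$z0 + geo$pc_span * runif(1, 0.1, 0.9)
    y_t <- geo$y_c + 3 * sin(pi * (z_t - geo$z0) / geo$pc_span) - runif(1, 0, 8)
    lat <- runif(1, 8, 20)
    side <- sample(c(-1, 1), 1)
    sg <- c(runif(1, 14, 24), runif(1, 14, 24), runif(1, 8, 16))
    if (cv$bilateral == 1) {
      centers <- rbind(c(geo$x_c - lat, y_t, z_t), c(geo$x_c + lat, y_t, z_t))
      sigmas <- rbind(sg, sg)
    } else {
      centers <- rbind(c(geo$x_c + side * lat, y_t, z_t))
      sigmas <- rbind(sg)
    }
    list(covariates = cv, modality = if (cv$modality_proton == 1) "proton" else "photon",
         prescription = prescription,
         dose_params = list(centers = centers, sigmas = sigmas,
                            prescription = prescription),
         truth_warp = tw, seed = seed)
  })
  case$id <- sprintf("case_%010d", as.integer(seed))
  case$rt_start_day <- -45
  case$rt_end_day <- 0
  case$outcome <- NA
  class(case) <- "patient_case"
  if (volumes) case <- materialize_case(case, ref) else case$ref_shape <- d
  case
}

#' Materialize a patient's mask and dose volumes
#'
#' Deterministically reconstructs the mask volumes (reference masks carried
#' through the inverted generating field) and the dose grid (analytic dose
#' model evaluated at the patient grid) for a case created with
#' `volumes = FALSE`. Should the deformation fold the organ away entirely,
#' the deformable part is damped by half and the warp retried (logged).
#'
#' @param case a `patient_case`.
#' @param ref the generating [make_reference()] anatomy.
#' @return the case with `pc_mask`, `larynx_mask` and `dose` set.
#' @export
materialize_case <- function(case, ref) {
  stopifnot(inherits(case, "patient_case"), inherits(ref, "reference_anatomy"))
  d <- ref$shape; spacing <- ref$spacing
  for (attempt in 1:4) {
    w <- array(truth_warp_eval(case$truth_warp, vg_coords(ref$pc_mask)),
               c(d, 3L))
    q <- invert_field_points(w, d, spacing)
    pc <- cpp_sample(as.numeric(ref$pc_mask$values), d, q, 1L, 0L, 0)
    lar <- cpp_sample(as.numeric(ref$larynx_mask$values), d, q, 1L, 0L, 0)
    if (sum(pc) > 0 && sum(lar) > 0) break
    vd_log("case %s: deformation emptied a mask; damping amplitude (attempt %d)",
           case$id, attempt, verbose = TRUE)
    case$truth_warp$damp <- case$truth_warp$damp * 0.5
  }
  if (sum(pc) == 0 || sum(lar) == 0)
    stop("deformation fold could not be repaired for case ", case$id)
  case$pc_mask <- volume_grid(array(pc, d), spacing, ref$origin)
  case$larynx_mask <- volume_grid(array(lar, d), spacing, ref$origin)
  pts <- vg_coords(ref$pc_mask)  # full-grid physical coordinates
  case$dose <- volume_grid(array(dose_eval(case$dose_params, pts), d),
                           spacing, ref$origin)
  case
}

# mean analytic dose over reference voxel indices, carried through the
# generating field (exact normalization), physical Gy
truth_warped_dose <- function(case, ref, idx) {
  pts <- vg_coords(ref$pc_mask, idx)
  dose_eval(case$dose_params, pts + truth_warp_eval(case$truth_warp, pts))
}

#' Assign the FT/WL outcome to a case from the truth model
#'
#' Computes the mean RBE-scaled dose to the planted subregion (evaluated in
#' the reference frame through the case's generating deformation), forms the
#' logistic linear predictor, draws the outcome, and constructs feeding-tube
#' events and longitudinal weight records consistent with the outcome under
#' the endpoint rule (feeding tube inserted within 90 days of RT completion,
#' or weight nadir more than 10% below baseline in that window).
#'
#' @param case a `patient_case`.
#' @param truth an [outcome_truth_model()].
#' @param partition a [partition_subregions()] result on the generating
#'   reference.
#' @param ref the generating reference anatomy.
#' @return the case with `outcome`, `ft_days`, `weight_records` and
#'   `planted_mean_dose` set.
#' @export
assign_outcome <- function(case, truth, partition, ref) {
  idx <- partition_indices(partition, truth$planted_subregion)
  if (length(idx) == 0) stop("planted subregion is empty")
  dbar <- mean(truth_warped_dose(case, ref, idx))
  if (case$modality == "proton") dbar <- dbar * 1.1
  lp <- truth$intercept + truth$dose_effect * (dbar - truth$dose_center)
  for (nm in names(truth$covariate_effects)) {
    xv <- case$covariates[[nm]]
    if (is.null(xv)) stop("covariate missing from case: ", nm)
    lp <- lp + truth$covariate_effects[[nm]] * (xv - truth$centers[[nm]])
  }
  p <- plogis(lp)
  case <- with_seed(derive_seed(truth$noise_seed, case$id), {
    y <- rbinom(1, 1, p)
    base_w <- case$covariates$baseline_weight
    ft_days <- numeric(0)
    if (y == 1) {
      use_ft <- runif(1) < 0.5
      if (use_ft) ft_days <- round(runif(1, 5, 85))
      wl <- !use_ft || runif(1) < 0.45   # some FT patients also lose weight
      frac <- if (wl) runif(1, 0.105, 0.20) else runif(1, 0, 0.08)
    } else {
      frac <- runif(1, 0, 0.08)
    }
    nadir_day <- round(runif(1, 20, 85))
    wr <- data.frame(
      day = c(case$rt_start_day + 2, nadir_day, 89),  # baseline near RT start
      kg = base_w * c(1, 1 - frac, 1 - 0.6 * frac))
    case$outcome <- y
    case$outcome_prob <- p
    case$planted_mean_dose <- dbar
    case$ft_days <- ft_days
    case$weight_records <- wr
    case
  })
  chk <- extract_endpoint(case$ft_days, case$weight_records,
                          case$rt_start_day, case$rt_end_day)
  stopifnot(identical(as.integer(chk$outcome), as.integer(case$outcome)))
  case
}

#' Cohort generator settings
#'
#' @param shape,spacing reference grid (see [make_reference()]).
#' @param max_displacement,field_sigma deformation scale parameters, mm.
#' @param cov_model a [covariate_model()].
#' @param truth an [outcome_truth_model()] (its `noise_seed` is overridden by
#'   the cohort seed's `outcome` substream).
#' @param midline_halfwidth,larynx_sup_frac subregion partition parameters
#'   (see [partition_subregions()]).
#' @param volumes materialize volumes per case (see [sample_patient()]).
#' @param prevalence_band expected outcome-prevalence band, logged when the
#'   realized prevalence leaves it.
#' @return a named list of settings.
#' @export
cohort_config <- function(shape = c(96, 96, 120), spacing = c(1.27, 1.27, 1),
                          max_displacement = 8, field_sigma = 12,
                          cov_model = covariate_model(),
                          truth = outcome_truth_model(),
                          midline_halfwidth = 10, larynx_sup_frac = 1 / 3,
                          volumes = TRUE, prevalence_band = c(0.35, 0.70)) {
  list(shape = shape, spacing = spacing, max_displacement = max_displacement,
       field_sigma = field_sigma, cov_model = cov_model, truth = truth,
       midline_halfwidth = midline_halfwidth, larynx_sup_frac = larynx_sup_frac,
       volumes = volumes, prevalence_band = prevalence_band)
}

#' Generate a reproducible synthetic cohort
#'
#' @param n cohort size (at least 10).
#' @param config a [cohort_config()].
#' @param seed master seed; all case- and stage-level seeds derive from it.
#' @return a list of class `synthetic_cohort`: `cases` (list of
#'   `patient_case`), `truth`, `reference`, `partition`, `config`, `seed`.
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = 1) {
  if (n < 10) stop("cohort size must be at least 10 (too small for any split)")
  ref <- make_reference(config$shape, config$spacing,
                        derive_seed(seed, "reference"))
  truth <- config$truth
  truth$noise_seed <- derive_seed(seed, "outcome")
  partition <- partition_subregions(ref,
                                    midline_halfwidth = config$midline_halfwidth,
                                    larynx_sup_frac = config$larynx_sup_frac)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- sample_patient(ref, config$cov_model,
                         seed = derive_seed(seed, sprintf("case_%04d", i)),
                         max_displacement = config$max_displacement,
                         field_sigma = config$field_sigma,
                         volumes = config$volumes)
    cs$id <- sprintf("case_%04d", i)
    cases[[i]] <- assign_outcome(cs, truth, partition, ref)
  }
  prev <- mean(vapply(cases, function(c) c$outcome, numeric(1)))
  doses <- vapply(cases, function(c) c$planted_mean_dose, numeric(1))
  vd_log("cohort n=%d prevalence=%.3f planted-dose mean=%.1f sd=%.1f Gy",
         n, prev, mean(doses), sd(doses))
  if (prev < config$prevalence_band[1] || prev > config$prevalence_band[2])
    vd_log("prevalence %.3f outside configured band [%g, %g]", prev,
           config$prevalence_band[1], config$prevalence_band[2], verbose = TRUE)
  structure(list(cases = cases, truth = truth, reference = ref,
                 partition = partition, config = config, seed = seed,
                 prevalence = prev),
            class = "synthetic_cohort")
}

#' Extract the per-patient clinical table of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return a data.frame, one row per patient.
#' @export
clinical_table <- function(cohort) {
  rows <- lapply(cohort$cases, function(cs) {
    data.frame(id = cs$id, modality = cs$modality,
               prescription = cs$prescription,
               as.data.frame(cs$covariates),
               outcome = cs$outcome,
               planted_mean_dose = cs$planted_mean_dose,
               ft_days = paste(cs$ft_days, collapse = ";"),
               weight_days = paste(cs$weight_records$day, collapse = ";"),
               weight_kg = paste(format(cs$weight_records$kg, digits = 10),
                                 collapse = ";"),
               rt_start_day = cs$rt_start_day, rt_end_day = cs$rt_end_day)
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk (NIfTI volumes + CSV clinical table + JSON truth)
#'
#' @param cohort a [generate_cohort()] result (volumes materialized).
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(cohort$reference$pc_mask, file.path(dir, "reference_pc.nii.gz"))
  write_nifti(cohort$reference$larynx_mask, file.path(dir, "reference_larynx.nii.gz"))
  for (cs in cohort$cases) {
    stopifnot(!is.null(cs$dose))
    write_nifti(cs$pc_mask, file.path(dir, paste0(cs$id, "_pc.nii.gz")))
    write_nifti(cs$larynx_mask, file.path(dir, paste0(cs$id, "_larynx.nii.gz")))
    write_nifti(cs$dose, file.path(dir, paste0(cs$id, "_dose.nii.gz")))
  }
  write.csv(clinical_table(cohort), file.path(dir, "clinical.csv"),
            row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(intercept = truth$intercept, dose_effect = truth$dose_effect,
         planted_subregion = truth$planted_subregion,
         covariate_effects = as.list(truth$covariate_effects),
         dose_center = truth$dose_center, noise_seed = truth$noise_seed,
         seed = cohort$seed, shape = cohort$config$shape,
         spacing = cohort$config$spacing),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 12)
  invisible(dir)
}
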