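# Shared fixtures, memoized per test run. The smoke grid (64x64x80 at
# 1.27x1.27x1 mm) is the smallest grid the reference organs fit with margin;
# most tests use it or tiny hand-built volumes.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

smoke_shape <- c(64L, 64L, 80L)
smoke_spacing <- c(1.27, 1.27, 1)

smoke_ref <- function(seed = 7) {
  memo(paste0("ref_", seed), make_reference(smoke_shape, smoke_spacing, seed))
}

smoke_cohort <- function(n = 40, seed = 1, volumes = FALSE, ...) {
  extra <- paste(deparse(list(...)), collapse = "")
  memo(sprintf("cohort_%d_%d_%d_%s", n, seed, volumes, extra),
       generate_cohort(n, cohort_config(shape = smoke_shape, volumes = volumes,
                                        ...), seed))
}

# tiny hand-built volumes -----------------------------------------------------

box_mask <- function(d, lo, hi, spacing = c(1, 1, 1)) {
  a <- array(0, d)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  volume_grid(a, spacing)
}

random_mask <- function(d, p = 0.3, spacing = c(1, 1, 1)) {
  a <- array(as.numeric(runif(prod(d)) < p), d)
  volume_grid(a, spacing)
}

random_dose <- function(d, max_gy = 70, spacing = c(1, 1, 1)) {
  volume_grid(array(runif(prod(d), 0, max_gy), d), spacing)
}

# a smooth blobby mask (for registration-flavoured tests)
blob_mask <- function(d, center, radius, spacing = c(1, 1, 1)) {
  a <- arrayInd(seq_len(prod(d)), d) - 1L
  r <- sqrt(((a[, 1] - center[1]) * spacing[1])^2 +
            ((a[, 2] - center[2]) * spacing[2])^2 +
            ((a[, 3] - center[3]) * spacing[3])^2)
  volume_grid(array(as.numeric(r <= radius), d), spacing)
}

# independent brute-force dosimetry oracles (plain voxel loops)
oracle_mean_dose <- function(dose, mask) {
  tot <- 0; n <- 0
  for (i in seq_along(mask$values)) {
    if (mask$values[i] == 1) { tot <- tot + dose$values[i]; n <- n + 1 }
  }
  tot / n
}

oracle_v_at_dose <- function(dose, mask, x) {
  hit <- 0; n <- 0
  for (i in seq_along(mask$values)) {
    if (mask$values[i] == 1) {
      n <- n + 1
      if (dose$values[i] >= x) hit <- hit + 1
    }
  }
  100 * hit / n
}
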