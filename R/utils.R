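#' Derive a reproducible substream seed
#'
#' All stage- and case-level randomness in the package flows from one master
#' seed through named substreams, so that any stage can be re-run in
#' isolation and the end-to-end pipeline is reproducible.
#'
#' @param seed master seed (integer).
#' @param label character label of the substream (e.g. `"synth"`,
#'   `"case_0007"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; arithmetic stays exact in doubles
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
    # extra mixing keeps nearby labels/seeds well separated
    h <- (h * 16807) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

vd_log <- function(..., verbose = getOption("voxdose.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[voxdose] ", sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cached 0-based voxel index matrix for a grid shape (arrayInd is a hot path)
.vd_cache <- new.env(parent = emptyenv())
grid_arrayind <- function(d) {
  key <- paste(d, collapse = "x")
  val <- .vd_cache[[key]]
  if (is.null(val)) {
    val <- arrayInd(seq_len(prod(d)), d) - 1L
    .vd_cache[[key]] <- val
  }
  val
}
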