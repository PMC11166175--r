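#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily fixed RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so generators are bit-reproducible without clobbering
#' the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_phbold <- function(fmt, ..., class = "phbold_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assert_that <- function(ok, fmt, ..., class = "phbold_error") {
  if (!isTRUE(ok)) stop_phbold(fmt, ..., class = class)
  invisible(TRUE)
}

#' Flatten a 4D (x,y,z,scan) array to a voxel-by-scan matrix
#' @noRd
vox_by_scan <- function(arr4d) {
  d <- dim(arr4d)
  matrix(arr4d, nrow = prod(d[1:3]), ncol = d[4])
}

#' Reshape a voxel-by-scan matrix back to 4D with spatial dims `sdim`
#' @noRd
scan_to_4d <- function(mat, sdim) {
  array(mat, dim = c(sdim, ncol(mat)))
}
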