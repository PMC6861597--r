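# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Binary brain mask: any channel strictly non-zero.
brainmask_from <- function(volumes) {
  d <- dim(volumes)
  if (length(d) == 3L) return(array(as.numeric(volumes != 0), d))
  m <- matrix(volumes, prod(d[1:3]), d[4])
  array(as.numeric(rowSums(m != 0) > 0), d[1:3])
}

as_mat <- function(x) {
  d <- dim(x)
  matrix(x, prod(d[1:3]), if (length(d) >= 4L) d[4] else 1L)
}

as_arr <- function(m, d3, C = ncol(m)) array(m, c(d3, C))

# Separable Gaussian smoothing of a 3D array (zero boundary).
gauss_smooth <- function(volume, sigma) {
  stopifnot(length(dim(volume)) == 3L)
  array(cpp_gauss_smooth3d(as.numeric(volume), as.integer(dim(volume)), sigma),
        dim(volume))
}

check_volume3d <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  invisible(x)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must be on the same voxel grid (got %s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(NULL)
}

# Voxel coordinate index arrays for a 3D grid (1-based), as N x 3 matrix.
grid_coords <- function(shape) {
  cbind(
    rep_len(seq_len(shape[1]), prod(shape)),
    rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
    rep(seq_len(shape[3]), each = shape[1] * shape[2])
  )
}
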