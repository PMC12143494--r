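#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib retinaseg, .registration = TRUE
NULL

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards.  Keeps record replay independent of the
## global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Mirror-reflection indices (edge pixel not duplicated, period 2(n-1)) for
## positions (1-before)..(n+after) into 1..n.
reflect_idx <- function(n, before, after) {
  if (n == 1L) return(rep(1L, before + 1L + after))
  p <- (1L - before):(n + after)
  q <- abs(p - 1L) %% (2L * n - 2L)
  as.integer(ifelse(q < n, q + 1L, 2L * n - 1L - q))
}

## Reflection padding of a matrix by (top, bottom, left, right); used by the
## Gaussian blur and the inference tiler.
pad_reflect <- function(x, top, bottom, left, right) {
  x[reflect_idx(nrow(x), top, bottom), reflect_idx(ncol(x), left, right),
    drop = FALSE]
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian blur of a matrix with reflective boundaries.
gauss_blur2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  xp <- pad_reflect(x, r, r, r, r)
  ## filter columns (stats::filter works column-wise on matrices)
  xp <- stats::filter(xp, k, sides = 2)
  xp <- t(stats::filter(t(xp), k, sides = 2))
  matrix(xp[(r + 1):(r + nrow(x)), (r + 1):(r + ncol(x))],
         nrow(x), ncol(x))
}

## Blur a (z, y, x) volume: 2D blur per slice, then 1D blur along z with
## sigma_z (0 disables the axial pass; anisotropic volumes use sigma/af).
gauss_blur3d <- function(v, sigma_xy, sigma_z) {
  d <- dim(v)
  out <- v
  if (sigma_xy > 0)
    for (z in seq_len(d[1]))
      out[z, , ] <- gauss_blur2d(matrix(out[z, , ], d[2], d[3]), sigma_xy)
  if (sigma_z > 0 && d[1] > 1) {
    k <- gauss_kernel(sigma_z)
    r <- (length(k) - 1L) %/% 2L
    flat <- matrix(out, d[1], d[2] * d[3])  # z fastest axis
    fp <- flat[reflect_idx(d[1], r, r), , drop = FALSE]
    fp <- stats::filter(fp, k, sides = 2)
    out <- array(fp[(r + 1):(r + d[1]), ], d)
  }
  out
}

rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(array((lo + hi) / 2, dim(x)))
  (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}
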