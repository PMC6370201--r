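# Preprocessing grid: variance-stabilizing transforms, ROI size
# standardization, natural cubic smoothing splines, and noise injection.
# Pipeline order is fixed: transform -> smooth -> add_noise.

#' Anscombe variance-stabilizing transform
#'
#' Maps counts `x` to `2 * sqrt(x + 3/8)`. For Poisson-like counts this
#' approximately stabilizes the variance at 1 and brings the distribution
#' closer to normal.
#'
#' @param values non-negative numeric vector.
#' @return transformed vector, same length; strictly increasing in `values`.
#' @export
anscombe <- function(values) {
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) {
    stop("anscombe() requires non-negative input", call. = FALSE)
  }
  2 * sqrt(values + 3 / 8)
}

#' Log transform with unit offset
#'
#' `log(x + 1)`, the Box-Cox transform with lambda = 0 after incrementing each
#' value by one to avoid `log(0)` on zero-inflated motion energy series.
#'
#' @param values numeric vector, each element > -1.
#' @return `log(values + 1)`.
#' @export
log1p_transform <- function(values) {
  values <- as.numeric(values)
  if (any(values < -1, na.rm = TRUE)) {
    stop("log1p_transform() requires values > -1", call. = FALSE)
  }
  log1p(values)
}

#' ROI size standardization of a dyad's series pair
#'
#' Multiplies every element of the series recorded with the *smaller* region
#' of interest by the ratio of the larger to the smaller ROI area, making the
#' two persons' ranges comparable. Ties leave both series unchanged.
#'
#' @param a,b [mets()] objects carrying `roi_area`.
#' @return a list with elements `a` and `b` (scaled copies).
#' @export
size_standardize <- function(a, b) {
  stopifnot(inherits(a, "mets"), inherits(b, "mets"))
  if (is.na(a$roi_area) || is.na(b$roi_area) ||
      a$roi_area <= 0 || b$roi_area <= 0) {
    stop("size standardization needs positive roi_area on both series",
         call. = FALSE)
  }
  rr <- roi_ratio(a$roi_area, b$roi_area)
  if (rr$smaller == "a") {
    a$values <- a$values * rr$ratio
  } else if (rr$smaller == "b") {
    b$values <- b$values * rr$ratio
  }
  list(a = a, b = b)
}

#' Smoothing specification
#'
#' The three grid levels: `"none"` (bypass), `"slight"` (p = .900) and
#' `"high"` (p = .005). `p` follows the p * misfit + (1 - p) * roughness
#' convention, so p near 1 is near-interpolation and p near 0 approaches the
#' straight-line limit — hence p = .005 is heavy smoothing.
#'
#' @param kind one of `"none"`, `"slight"`, `"high"`.
#' @param spline_p optional override of the roughness trade-off in (0, 1].
#' @return an object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(kind = c("none", "slight", "high"),
                           spline_p = NULL) {
  kind <- match.arg(kind)
  if (is.null(spline_p)) {
    spline_p <- switch(kind, none = NA_real_, slight = 0.900, high = 0.005)
  }
  if (kind != "none" && (spline_p <= 0 || spline_p > 1)) {
    stop("spline_p must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, spline_p = spline_p), class = "smoothing_spec")
}

# Fitted values of a natural cubic smoothing spline at unit-spaced frames.
# Minimizes p * sum((y - f)^2) + (1 - p) * integral(f'')^2 via the
# Green-Silverman banded system: f = y - lambda * Q %*% gamma with
# (R + lambda * t(Q) %*% Q) gamma = t(Q) y, lambda = (1 - p) / p,
# Q the n x (n-2) second-difference matrix and R tridiagonal.
smoothing_spline_fit <- function(y, p) {
  n <- length(y)
  lambda <- (1 - p) / p
  if (lambda == 0) return(y)
  i <- seq_len(n - 2L)
  # Q: column j has entries 1, -2, 1 at rows j, j+1, j+2 (unit knot spacing)
  Q <- Matrix::sparseMatrix(
    i = c(i, i + 1L, i + 2L), j = rep(i, 3L),
    x = rep(c(1, -2, 1), each = n - 2L), dims = c(n, n - 2L))
  # R: tridiagonal with 2/3 on the diagonal, 1/6 off (h = 1)
  R <- Matrix::bandSparse(
    n - 2L, n - 2L, k = c(-1L, 0L, 1L),
    diagonals = list(rep(1 / 6, n - 3L), rep(2 / 3, n - 2L),
                     rep(1 / 6, n - 3L)), symmetric = FALSE)
  gamma <- Matrix::solve(R + lambda * Matrix::crossprod(Q),
                         Matrix::crossprod(Q, y))
  as.numeric(y - lambda * (Q %*% gamma))
}

#' Smooth a series with a natural cubic smoothing spline
#'
#' Fits a cubic smoothing spline over the frame index (unit spacing) and
#' returns the fitted values at every frame. The penalty only acts on
#' curvature, so constant and exactly linear series are reproduced unchanged
#' at any `p`. Smoothed values may become slightly negative near sharp pulse
#' edges; they are passed through unaltered because the (monotone) transforms
#' run before smoothing in the pipeline.
#'
#' @param values numeric vector, length >= 4 for the spline kinds.
#' @param spec a [smoothing_spec()].
#' @return the smoothed vector, same length.
#' @export
smooth_series <- function(values, spec) {
  stopifnot(inherits(spec, "smoothing_spec"))
  values <- as.numeric(values)
  if (spec$kind == "none") return(values)
  if (length(values) < 4L) {
    stop("smoothing splines need a series of length >= 4", call. = FALSE)
  }
  smoothing_spline_fit(values, spec$spline_p)
}

#' Noise specification
#'
#' Gaussian noise added after transformation and smoothing so that local
#' correlations and regressions are defined even on stretches where the
#' motion energy is identically zero (zero-variance windows).
#'
#' @param mean noise mean (0 in the validation design).
#' @param sd noise standard deviation (0.1 in the validation design), in
#'   motion-energy units after the transform.
#' @param seed integer RNG seed; equal seeds give identical draws.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(mean = 0, sd = 0.1, seed = 1L) {
  assert_scalar_number(sd, "sd", min = 0)
  assert_scalar_number(mean, "mean")
  structure(list(mean = mean, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add reproducible Gaussian noise to a series
#'
#' @param values numeric vector.
#' @param spec a [noise_spec()]; the draw is seeded with `spec$seed` and does
#'   not disturb the caller's RNG state.
#' @return `values` plus i.i.d. Gaussian(mean, sd) noise.
#' @export
add_noise <- function(values, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$sd == 0 && spec$mean == 0) return(as.numeric(values))
  values + with_seed(spec$seed,
                     stats::rnorm(length(values), spec$mean, spec$sd))
}

#' Transform specification
#'
#' @param kind one of `"raw"`, `"size"` (ROI size standardization), `"log1p"`
#'   (Box-Cox with lambda = 0 after a unit offset), `"anscombe"`.
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(kind = c("raw", "size", "log1p", "anscombe")) {
  structure(list(kind = match.arg(kind)), class = "transform_spec")
}

# Apply a transform to a dyad's pair of mets; returns list(a, b) of mets.
apply_transform <- function(a, b, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
    raw = list(a = a, b = b),
    size = size_standardize(a, b),
    log1p = {
      a$values <- log1p_transform(a$values)
      b$values <- log1p_transform(b$values)
      list(a = a, b = b)
    },
    anscombe = {
      a$values <- anscombe(a$values)
      b$values <- anscombe(b$values)
      list(a = a, b = b)
    })
}
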