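# internal helpers shared across modules

# run expr with a local RNG state seeded by `seed`; if seed is NULL the
# global RNG stream is used (and advanced) as-is
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# normalize an extent specification to c(xmin, xmax, ymin, ymax);
# length-2 input is a (width, height) window centred on the origin
as_extent <- function(extent) {
  if (length(extent) == 2L) {
    extent <- c(-extent[1] / 2, extent[1] / 2, -extent[2] / 2, extent[2] / 2)
  }
  if (length(extent) == 1L) {
    extent <- c(-extent / 2, extent / 2, -extent / 2, extent / 2)
  }
  stopifnot(length(extent) == 4L)
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("degenerate extent: generation window has zero area", call. = FALSE)
  }
  extent
}

extent_area <- function(extent) {
  e <- as_extent(extent)
  (e[2] - e[1]) * (e[4] - e[3])
}

# wrap angle differences into (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# fold an orientation into [0, pi)
fold_orientation <- function(theta) theta %% pi

# FFT wavenumber axis (rad per unit) for n samples with spacing dx,
# in unshifted FFT order
fft_freq <- function(n, dx) {
  idx <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  2 * pi * idx / (n * dx)
}

# bilinear interpolation of a (possibly complex) matrix z[i, j] sampled at
# x = (i-1)*dx + x0 (rows), y = (j-1)*dy + y0 (cols); points outside the
# grid are clamped to the border
bilinear <- function(z, xi, yi) {
  # xi, yi in fractional index units (1-based)
  n <- nrow(z); m <- ncol(z)
  xi <- pmin(pmax(xi, 1), n)
  yi <- pmin(pmax(yi, 1), m)
  i0 <- pmin(floor(xi), n - 1); j0 <- pmin(floor(yi), m - 1)
  fx <- xi - i0; fy <- yi - j0
  z[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    z[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    z[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    z[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# 2D rotation matrix
rot2 <- function(alpha) {
  matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
}

# Gaussian low-pass of a (complex) matrix by FFT, periodic boundaries;
# sd in the same length units as dx
gaussian_smooth_fft <- function(z, sd, dx) {
  if (sd <= 0) stop("smoothing kernel width must be positive", call. = FALSE)
  n <- nrow(z); m <- ncol(z)
  kx <- fft_freq(n, dx); ky <- fft_freq(m, dx)
  g <- exp(-outer(kx^2, ky^2, "+") * sd^2 / 2)
  fft(fft(z) * g, inverse = TRUE) / (n * m)
}
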