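# shared fixtures: standard Moire parameters and a small wiring-model map
# (built once per test run)

std_params <- function() moire_params()  # r = r' = 170 um, dalpha = 7 deg

std_lambda_mm <- function() moire_geometry(std_params())$Lambda_c / 1000

# small standard map: 3 Lambda window at 48 px/Lambda
.fixture_env <- new.env(parent = emptyenv())

std_map_bundle <- function() {
  if (!is.null(.fixture_env$bundle)) return(.fixture_env$bundle)
  p <- std_params()
  lam <- std_lambda_mm()
  grid <- cortical_grid(3 * lam, 3 * 48)
  ext <- (3 * lam / 2 * 1000 + 500) * c(-1, 1, -1, 1)
  mos <- hex_pair_mosaic(extent = ext)
  unf <- compute_unfiltered_map(mos, grid, wiring_params(), lambda_mm = lam)
  .fixture_env$bundle <- list(params = p, lam = lam, grid = grid,
                              mosaic = mos, unf = unf)
  .fixture_env$bundle
}

# complex field with planted simple zeros (and optionally one double zero),
# on an n x n grid; zeros given as rows (x_index, y_index, charge)
planted_field <- function(zeros, n = 200, scale = 40) {
  w0 <- matrix(complex(real = outer(seq_len(n), rep(1, n)),
                       imaginary = outer(rep(1, n), seq_len(n))), n, n)
  z <- matrix(1 + 0i, n, n)
  for (r in seq_len(nrow(zeros))) {
    f <- (w0 - complex(real = zeros[r, 1], imaginary = zeros[r, 2])) / scale
    q <- zeros[r, 3]
    if (q < 0) f <- Conj(f)
    for (k in seq_len(round(2 * abs(q)))) z <- z * f
  }
  tuning_map(z, px_mm = 1, stage = "grf")
}

# uniform random pinwheel pattern (Poisson control)
poisson_pinwheels <- function(n, side, seed) {
  set.seed(seed)
  pinwheel_set(runif(n, 0, side), runif(n, 0, side),
               charge = sample(c(-0.5, 0.5), n, replace = TRUE),
               region = c(0, side, 0, side), lambda = 1)
}
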