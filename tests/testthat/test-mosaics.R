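test_that("hexagonal lattice has six nearest neighbours and the closed-form density", {
  r <- 170
  m <- hexagonal_mosaic(r, rotation = 0.3, extent = c(4000, 4000),
                        polarity = "ON")
  # interior cell: all six nearest neighbours at exactly r
  i <- which.min(m$x^2 + m$y^2)
  d <- sqrt((m$x - m$x[i])^2 + (m$y - m$y[i])^2)
  expect_equal(sum(abs(d - r) < 1e-6), 6)
  expect_gt(min(d[d > 1e-9]), r - 1e-6)
  # areal density vs 2 / (sqrt(3) r^2)
  dens <- length(m$x) / (4 * 4)  # cells per mm^2
  expect_equal(dens, 2 / (sqrt(3) * (r / 1000)^2), tolerance = 0.02)
})

test_that("rotation by 60 degrees maps the lattice onto itself", {
  m0 <- hexagonal_mosaic(200, 0, c(3000, 3000), "ON")
  m6 <- hexagonal_mosaic(200, pi / 3, c(3000, 3000), "ON")
  # compare inside an inset window (membership can differ at the boundary)
  inset <- function(m) {
    k <- abs(m$x) < 1190 & abs(m$y) < 1190
    mat <- round(cbind(m$x[k], m$y[k]), 6)
    mat[order(mat[, 1], mat[, 2]), ]
  }
  expect_equal(inset(m0), inset(m6), tolerance = 1e-6)
})

test_that("degenerate or undersized extents are rejected", {
  expect_error(hexagonal_mosaic(170, 0, c(1000, 0, 0, 1000), "ON"),
               "degenerate")
  expect_error(hexagonal_mosaic(170, 0, c(200, 200), "ON"), "two lattice")
})

test_that("uncorrelated jitter preserves counts and has SD eta * r", {
  r <- 30
  m <- hexagonal_mosaic(r, 0, c(4000, 4000), "ON")
  expect_identical(apply_uncorrelated_jitter(m, 0), m)
  eta <- 0.12
  j <- apply_uncorrelated_jitter(m, eta, seed = 42)
  expect_equal(length(j$x), length(m$x))
  dx <- j$x - m$x; dy <- j$y - m$y
  n <- length(dx)
  se <- eta * r / sqrt(2 * n)  # SE of the SD estimate
  expect_lt(abs(sd(dx) - eta * r), 3 * se)
  expect_lt(abs(sd(dy) - eta * r), 3 * se)
  # seeding contract
  expect_identical(j, apply_uncorrelated_jitter(m, eta, seed = 42))
  j2 <- apply_uncorrelated_jitter(m, eta, seed = 43)
  expect_gt(max(abs(j$x - j2$x)), 0)
})

test_that("displacement fields have the prescribed Gaussian correlation", {
  sig <- 150
  f <- sample_displacement_field(c(8000, 8000), sig, seed = 5)
  v1 <- var(as.vector(f$y1)); v2 <- var(as.vector(f$y2))
  expect_lt(abs(v1 - 1), 0.15)
  expect_lt(abs(v2 - 1), 0.15)
  expect_lt(abs(mean(f$y1)), 0.1)
  # summed two-component correlation at lags {0, sigma, 2 sigma, 3 sigma}
  lag_corr <- function(lag_px) {
    n <- nrow(f$y1)
    s1 <- mean(f$y1[1:(n - lag_px), ] * f$y1[(1 + lag_px):n, ])
    s2 <- mean(f$y2[1:(n - lag_px), ] * f$y2[(1 + lag_px):n, ])
    s1 + s2
  }
  for (mult in 0:3) {
    lag_px <- round(mult * sig / f$step)
    expect_lt(abs(lag_corr(lag_px) - 2 * exp(-mult^2 / 2)), 0.25)
  }
})

test_that("correlated jitter displaces nearby cells coherently", {
  r <- 170
  m <- hexagonal_mosaic(r, 0, c(6000, 6000), "ON")
  f <- sample_displacement_field(c(6400, 6400), 5 * r, seed = 9)
  expect_identical(apply_correlated_jitter(m, 0, f), m)
  eta <- 0.2
  j <- apply_correlated_jitter(m, eta, f)
  expect_equal(length(j$x), length(m$x))
  dx <- j$x - m$x; dy <- j$y - m$y
  # per-component SD ~ eta r (single realization: generous Monte Carlo band)
  expect_lt(abs(sd(dx) / (eta * r) - 1), 0.35)
  # nearest-neighbour cells move in nearly the same direction
  i <- which.min(m$x^2 + m$y^2)
  nb <- which(abs(sqrt((m$x - m$x[i])^2 + (m$y - m$y[i])^2) - r) < 1)
  cosim <- (dx[i] * dx[nb] + dy[i] * dy[nb]) /
    sqrt((dx[i]^2 + dy[i]^2) * (dx[nb]^2 + dy[nb]^2))
  expect_gt(min(cosim), 0.9)
  # field must cover the mosaic
  fsmall <- sample_displacement_field(c(1000, 1000), 5 * r, seed = 1)
  expect_error(apply_correlated_jitter(m, eta, fsmall), "cover")
})

test_that("jacobian determinant handles canonical fields", {
  f <- sample_displacement_field(c(3000, 3000), 300, seed = 2)
  # uniform translation: zero derivatives
  fc <- f; fc$y1[] <- 0.7; fc$y2[] <- -0.3
  expect_equal(max(abs(jacobian_determinant(fc))), 0)
  # pure unit dilation y(x) = x
  fd <- f
  fd$y1 <- outer(fd$xg, rep(1, length(fd$yg)))
  fd$y2 <- outer(rep(1, length(fd$xg)), fd$yg)
  expect_equal(max(abs(jacobian_determinant(fd) - 1)), 0, tolerance = 1e-9)
  # zero-mean GRF: spatial mean of det J near zero
  expect_lt(abs(mean(jacobian_determinant(f))), 0.05)
})

test_that("PIPP mosaics respect the hard core and are regularly spaced", {
  pp <- pipp_params()
  for (seed in c(3, 11, 27)) {
    m <- pipp_mosaic(pp, extent = c(1800, 1800), seed = seed)
    expect_gte(min(mosaic_nn(m, "ON")), pp$delta)
    expect_gte(min(mosaic_nn(m, "OFF")), pp$delta)
  }
  m <- pipp_mosaic(pp, extent = c(2000, 2000), seed = 3)
  expect_equal(sum(m$polarity == "ON"), round(pp$density * 4))
  expect_gt(regularity_index(m, "ON"), 3)
  expect_gt(regularity_index(m, "OFF"), 3)
  # reproducibility
  m2 <- pipp_mosaic(pp, extent = c(2000, 2000), seed = 3)
  expect_identical(m$x, m2$x)
  # infeasible packing is rejected before iteration
  expect_error(pipp_mosaic(pipp_params(delta = 200, density = 40),
                           extent = c(1500, 1500)), "nfeasible")
})

test_that("PIPP cross-polarity spacing matches independent superposition", {
  pp <- pipp_params(n_sweeps = 25)
  ma <- pipp_mosaic(pp, extent = c(1800, 1800), seed = 5)
  mb <- pipp_mosaic(pp, extent = c(1800, 1800), seed = 6)
  cross_real <- mosaic_nn(ma, "ON", "OFF")
  # superpose the ON process of one realization with the OFF of another
  mix <- rgc_mosaic(c(ma$x[ma$polarity == "ON"], mb$x[mb$polarity == "OFF"]),
                    c(ma$y[ma$polarity == "ON"], mb$y[mb$polarity == "OFF"]),
                    rep(c("ON", "OFF"), c(sum(ma$polarity == "ON"),
                                          sum(mb$polarity == "OFF"))),
                    ma$extent)
  cross_mix <- mosaic_nn(mix, "ON", "OFF")
  expect_gt(suppressWarnings(ks.test(cross_real, cross_mix))$p.value, 0.05)
})

test_that("mosaic serialization round-trips", {
  m <- apply_uncorrelated_jitter(
    hex_pair_mosaic(extent = c(2000, 2000)), 0.1, lattice_constant = 170,
    seed = 8)
  path <- file.path(tempdir(), "mosaic_test.tsv")
  write_mosaic(m, path)
  m2 <- read_mosaic(path)
  expect_lt(max(abs(m$x - m2$x)), 1e-6)
  expect_lt(max(abs(m$y - m2$y)), 1e-6)
  expect_identical(m$polarity, m2$polarity)
  expect_equal(m$extent, m2$extent)
})
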