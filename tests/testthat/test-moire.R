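test_that("scaling factor matches its closed form and symmetries", {
  expect_equal(round(moire_scaling_factor(0, 7 * pi / 180), 1), 8.2)
  expect_equal(moire_scaling_factor(0.1, 0), 11)
  for (b in c(0, 0.05, 0.2)) {
    for (da in c(0.05, 0.2, 0.5)) {
      expect_equal(moire_scaling_factor(b, da), moire_scaling_factor(b, -da))
    }
  }
  expect_warning(s <- moire_scaling_factor(0, 0), "diverges")
  expect_identical(s, Inf)
})

test_that("both column-spacing routes agree for arbitrary parameters", {
  set.seed(1)
  for (i in 1:10) {
    r <- runif(1, 100, 250)
    p <- moire_params(r = r, r_prime = r * (1 + runif(1, 0, 0.2)),
                      alpha = runif(1, 0, 0.3),
                      alpha_prime = runif(1, 0.05, 0.4))
    geo <- moire_geometry(p)
    expect_equal(geo$Lambda_c, sqrt(3) / 2 * geo$S * p$r,
                 tolerance = 1e-10)
    expect_equal(geo$Lambda_c / (geo$S * p$r), sqrt(3) / 2,
                 tolerance = 1e-12)
  }
  # k_c doubles when both lattice constants are halved
  g1 <- moire_geometry(moire_params(r = 170, r_prime = 170))
  g2 <- moire_geometry(moire_params(r = 85, r_prime = 85))
  expect_equal(g2$k_c, 2 * g1$k_c, tolerance = 1e-12)
  expect_equal(moire_geometry(std_params())$Lambda_c, 1205.8,
               tolerance = 1e-4)
})

test_that("closed-form receptive fields equal the brute-force lattice sum", {
  ext <- c(-3200, 3200, -3200, 3200)
  cfgs <- list(std_params(),
               moire_params(r = 140, r_prime = 150, sigma_r = 60,
                            sigma_s = 25),
               moire_params(r = 200, alpha = 0.2, alpha_prime = 0.35,
                            sigma_r = 80, sigma_s = 30))
  set.seed(4)
  for (p in cfgs) {
    mos <- merge_mosaics(
      hexagonal_mosaic(p$r, p$alpha, ext, "ON"),
      hexagonal_mosaic(p$r_prime, p$alpha_prime, ext, "OFF"))
    for (i in 1:7) {
      y <- runif(2, -500, 500)
      w <- 220
      win <- c(y[1] - w, y[1] + w, y[2] - w, y[2] + w)
      a <- analytic_rf(y, seq(win[1], win[2], by = 22),
                       seq(win[3], win[4], by = 22), p)
      b <- cortical_rf(mos, y, wiring_params(p$sigma_r, p$sigma_s),
                       window = win, step = 22, w_cut = 0)
      expect_lt(max(abs(a$values - b$values)) / max(abs(a$values)), 1e-8)
    }
  }
})

test_that("aligned equal lattices cancel and shifted evaluations are periodic", {
  p0 <- moire_params(r = 170, r_prime = 170, alpha = 0.1, alpha_prime = 0.1)
  xg <- seq(-200, 200, by = 25)
  rf <- analytic_rf(c(30, -40), xg, xg, p0)
  expect_lt(max(abs(rf$values)), 1e-12)
  # translating unit and grid by a lattice vector reproduces the field
  p <- std_params()
  a1 <- c(p$r, 0)  # ON lattice vector (alpha = 0)
  y <- c(55, 23)
  f1 <- moiremap:::analytic_rf_sublattice(
    bx = outer(xg, rep(1, length(xg))), by = outer(rep(1, length(xg)), xg),
    d2 = 0, alpha = 0, r = p$r, sigma_r = p$sigma_r, sigma_s = p$sigma_s)
  f2 <- moiremap:::analytic_rf_sublattice(
    bx = outer(xg + a1[1], rep(1, length(xg))),
    by = outer(rep(1, length(xg)), xg + a1[2]),
    d2 = 0, alpha = 0, r = p$r, sigma_r = p$sigma_r, sigma_s = p$sigma_s)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("closed-form spectra match a direct afferent-sum oracle", {
  p <- std_params()
  ext <- c(-3200, 3200, -3200, 3200)
  mos <- hex_pair_mosaic(extent = ext)
  y <- c(123.4, -57.8)
  kx <- c(0.002, 0.01, -0.007, 0.018, 0)
  ky <- c(0.001, -0.004, 0.012, 0.005, 0.02)
  w <- exp(-((mos$x - y[1])^2 + (mos$y - y[2])^2) / (2 * p$sigma_s^2))
  s <- ifelse(mos$polarity == "ON", 1, -1)
  oracle <- sapply(seq_along(kx), function(i) {
    p$sigma_r^2 * exp(-(kx[i]^2 + ky[i]^2) * p$sigma_r^2 / 2) *
      sum(s * w * exp(-1i * (kx[i] * mos$x + ky[i] * mos$y)))
  })
  ana <- analytic_spectrum(y, kx, ky, p)
  expect_lt(max(Mod(ana - oracle)) / max(Mod(oracle)), 1e-8)
  # Hermitian symmetry of the real field's transform
  expect_equal(Mod(analytic_spectrum(y, -kx, -ky, p)), Mod(ana),
               tolerance = 1e-12)
})

test_that("spectrum decays under the Gaussian envelope", {
  p <- std_params()
  y <- c(80, 15)
  kk <- seq(0.001, 0.09, length.out = 60)
  vals <- Mod(analytic_spectrum(y, kk, 0 * kk, p))
  env <- exp(-kk^2 * (p$sigma_r^2 + p$sigma_s^2) / 2)
  # the envelope-compensated factor grows far slower than the envelope decays
  expect_lt(max(vals / env) / min(vals / env), 1e-3 / (env[60] / env[1]))
  expect_lt(vals[length(vals)] / max(vals), 1e-6)
})

test_that("Hessian orientation maximizes the directional second derivative", {
  p <- std_params()
  xg <- seq(-400, 400, length.out = 7)
  hm <- hessian_orientation_map(xg, xg, p)
  th_grid <- seq(0, pi, length.out = 361)[-361]
  for (i in c(2, 11, 23, 37)) {
    a <- hm$a[i]; b <- hm$b[i]; cc <- hm$c[i]
    h <- function(th) a * cos(th)^2 + 2 * b * cos(th) * sin(th) +
      cc * sin(th)^2
    th_k <- fold_orientation(hm$theta[i] - pi / 2)  # back to k-space angle
    expect_gte(h(th_k) + 1e-9 * abs(a), max(h(th_grid)))
    # explicit branch formula agrees with the eigen form
    expect_equal(fold_orientation(hessian_theta_formula(a, b, cc)),
                 th_k, tolerance = 1e-9)
  }
})

test_that("the six-mode layout is periodic under the Moire superlattice", {
  # the unfiltered layout is only quasi-periodic (its fine-scale parcels
  # live on the incommensurate RGC lattice scales); exact superlattice
  # periodicity holds for the low-frequency six-mode field
  p <- std_params()
  A <- six_mode_field(p)$A
  xg <- seq(-600, 600, length.out = 24)
  for (j in 1:2) {
    s0 <- six_mode_map(xg, xg, p)
    s1 <- six_mode_map(xg + A[1, j], xg + A[2, j], p)
    expect_lt(max(Mod(s0$z - s1$z)), 1e-10 * max(Mod(s0$z)))
  }
})

test_that("six-mode field geometry: unit phase factor, central zero, k_c ring", {
  set.seed(2)
  for (i in 1:8) {
    p <- moire_params(r = runif(1, 120, 220),
                      r_prime = runif(1, 120, 220),
                      alpha = runif(1, 0, 0.5), alpha_prime = runif(1, 0, 0.5))
    sm <- six_mode_field(p)
    expect_equal(Mod(sm$u0), 1, tolerance = 1e-12)
    expect_equal(Mod(sum(2 * sm$u)), 0, tolerance = 1e-10)  # z(0) = 0
    geo <- moire_geometry(p)
    expect_equal(sm$k_c, rep(geo$k_c, 3), tolerance = 1e-10)
    expect_equal(sqrt(colSums(sm$A^2)), rep(2 * geo$Lambda_c / sqrt(3), 2),
                 tolerance = 1e-8)
  }
})

test_that("six-mode layout has the crystalline pinwheel density and spacing", {
  res <- sixmode_layout_density(cells_x = 4, cells_y = 3,
                                px_per_lambda = 64)
  expect_equal(res$rho, 2 * sqrt(3), tolerance = 1e-3)
  expect_equal(sum(res$set$charge), 0)  # charge neutrality per full cells
  expect_true(all(res$set$degenerate == (abs(res$set$charge) == 1)))
  nn <- nn_distances(res$set, "any")$d
  expect_lt(max(abs(nn - 2 / 3)), 0.01)
})

test_that("crystalline pinwheel pattern has the predicted variability exponent", {
  pw <- crystalline_pinwheels(n_cells = 30, lambda = 1)
  expect_equal(pinwheel_density(pw), 2 * sqrt(3), tolerance = 0.03)
  dv <- density_variability(pw, n_samples = 100, seed = 11)
  expect_equal(dv$gamma, 0.75, tolerance = 0.07)
})
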