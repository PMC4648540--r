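plane_wave_map <- function(lambda_mm, angle, n_px = 192, size_mm = 8,
                           osi = 1) {
  px <- size_mm / n_px
  xg <- (seq_len(n_px) - 1) * px
  phase <- 2 * pi / lambda_mm *
    (outer(xg, rep(1, n_px)) * cos(angle) +
       outer(rep(1, n_px), xg) * sin(angle))
  tuning_map(osi * exp(1i * phase), px_mm = px, stage = "grf")
}

test_that("amplitude spectra locate plane-wave peaks; marginals are max-normalized", {
  lam <- 1.1; ang <- 0.5
  pm <- plane_wave_map(lam, ang)
  sp <- amplitude_spectrum(pm)
  pk <- which(sp$A == max(sp$A), arr.ind = TRUE)
  k0 <- 2 * pi / lam
  dk <- diff(sp$kx[1:2])  # peak localization limited by the k-grid
  expect_lt(abs(sp$kx[pk[1]] - k0 * cos(ang)), dk)
  expect_lt(abs(sp$ky[pk[2]] - k0 * sin(ang)), dk)
  mg <- marginal_spectrum(sp)
  expect_equal(max(mg$f), 1)
  expect_equal(mg$k[which.max(mg$f)], k0, tolerance = 0.1)
})

test_that("six-mode spectra concentrate on the k_c ring; harmonics appear unfiltered", {
  p <- std_params()
  geo <- moire_geometry(p)
  b <- std_map_bundle()
  k_c <- geo$k_c * 1000  # rad/mm
  ring_stat <- function(map, mult, unit_modulus = TRUE, f = max) {
    sp <- amplitude_spectrum(map, unit_modulus = unit_modulus)
    KK <- sqrt(outer(sp$kx^2, sp$ky^2, "+")) / k_c
    f(sp$A[KK > 0.85 * mult & KK < 1.15 * mult])
  }
  ring_pow <- function(map, mult, um = TRUE) {
    ring_stat(map, mult, um, f = function(a) sum(a^2))
  }
  sixm <- six_mode_map(b$grid$xg_mm * 1000, b$grid$yg_mm * 1000, p)
  # raw six-mode field: k_c ring dominates (residue is window leakage)
  expect_gt(ring_pow(sixm, 1, FALSE), 5 * ring_pow(sixm, sqrt(3), FALSE))
  # the unfiltered wiring-model map carries a sqrt(3) k_c harmonic
  expect_gt(ring_stat(b$unf, sqrt(3)), 0.25 * ring_stat(b$unf, 1))
})

test_that("Fermi band-pass gains and DC removal", {
  lam_in <- c(0.7, 0.1, 2.5)
  gains <- sapply(lam_in, function(l) {
    pm <- plane_wave_map(l, 0.3, n_px = 256, size_mm = 12)
    out <- fermi_bandpass(pm$z, pm$px_mm)
    mean(Mod(out)) / mean(Mod(pm$z))
  })
  expect_gt(gains[1], 0.95)   # inside the band
  expect_lt(gains[2], 0.05)   # below the high-frequency cutoff
  expect_lt(gains[3], 0.2)    # beyond the low-frequency cutoff
  const <- matrix(3.2, 64, 64)
  expect_lt(max(abs(fermi_bandpass(const, 0.05))), 1e-9)
  expect_error(fermi_bandpass(const, 0.2, lambda_low_mm = 0.3), "Nyquist")
  expect_error(fermi_bandpass(const, 0.05, lambda_high_mm = 100), "size")
})

test_that("wavelet analysis recovers plane-wave wavelengths rotation-invariantly", {
  lam0 <- 0.8
  cfg <- wavelet_config(n_scales = 64)  # fine scale grid: quantization 3%
  est <- sapply(c(0, 0.4, 1.1), function(ang) {
    pm <- plane_wave_map(lam0, ang, n_px = 256, size_mm = 10)
    suppressWarnings(
      local_column_spacing(pm, lambda_expected_mm = lam0, cfg = cfg,
                           coarse = TRUE)$mean_lambda_mm)
  })
  # accuracy limit: scale-grid quantization (~3.5%) plus the ~2% bias of
  # the 1/sigma-normalized wavelet amplitude
  expect_lt(max(abs(est - lam0)) / lam0, 0.06)
  expect_lt(diff(range(est)) / lam0, 0.03)
  # full-resolution path agrees with the cropped-spectrum path
  pm <- plane_wave_map(lam0, 0.4, n_px = 128, size_mm = 8)
  f1 <- suppressWarnings(
    local_column_spacing(pm, lambda_expected_mm = lam0))
  f2 <- suppressWarnings(
    local_column_spacing(pm, lambda_expected_mm = lam0, coarse = TRUE))
  expect_equal(f1$mean_lambda_mm, f2$mean_lambda_mm, tolerance = 0.02)
})

test_that("wavelet spacing of the crystalline layout matches Lambda_c", {
  p <- std_params()
  geo <- moire_geometry(p)
  xg <- seq(0, 10 * geo$Lambda_c, length.out = 320)
  sm <- six_mode_map(xg, xg, p)
  w <- suppressWarnings(
    local_column_spacing(sm, lambda_expected_mm = geo$Lambda_c / 1000,
                         coarse = TRUE))
  expect_lt(abs(w$mean_lambda_mm - geo$Lambda_c / 1000) * 1000 /
              geo$Lambda_c, 0.05)
})

test_that("planted singularities are recovered with exact charges", {
  zeros <- rbind(c(40.3, 60.7, 0.5), c(120.6, 30.2, -0.5),
                 c(150.25, 170.8, 0.5), c(60.45, 160.35, -0.5),
                 c(100.2, 100.4, 0.5), c(100.2, 104.4, -0.5),
                 c(30.6, 120.2, 0.5), c(170.4, 80.9, -0.5),
                 c(80.15, 20.65, 0.5), c(20.85, 25.4, -0.5))
  for (k in c(1, 2, 10)) {
    det <- find_pinwheels(planted_field(zeros[1:k, , drop = FALSE]))
    expect_equal(nrow(det), k)
    # match each planted zero (pixel-centre coordinates are index - 0.5)
    for (r in seq_len(k)) {
      d <- sqrt((det$x - (zeros[r, 1] - 0.5))^2 +
                  (det$y - (zeros[r, 2] - 0.5))^2)
      j <- which.min(d)
      expect_lt(d[j], 0.5)
      expect_equal(det$charge[j], zeros[r, 3])
    }
  }
})

test_that("multiplicity-2 zeros are flagged degenerate with unit charge", {
  det <- find_pinwheels(planted_field(rbind(c(77.35, 91.6, 1))))
  expect_equal(nrow(det), 1)
  expect_equal(det$charge, 1)
  expect_true(det$degenerate)
  expect_lt(abs(det$x - 76.85) + abs(det$y - 91.1), 0.5)
})

test_that("generic smooth fields carry only half-integer charges that balance", {
  flt <- make_power_filter(3, 1)
  zm <- grf_sample(flt, n_px = 256, size_mm = 12, seed = 21)
  pw <- find_pinwheels(zm, lambda_mm = 1)
  expect_gt(nrow(pw), 100)
  expect_true(all(abs(pw$charge) == 0.5))
  # near charge neutrality (boundary clipping only)
  expect_lt(abs(sum(pw$charge)) / sum(abs(pw$charge)), 0.06)
})

test_that("pinwheel density is dimensionless and needs a spacing", {
  pw <- poisson_pinwheels(500, 20, seed = 2)
  rho <- pinwheel_density(pw)
  scaled <- pinwheel_set(pw$x * 2.7, pw$y * 2.7, pw$charge,
                         region = c(0, 54, 0, 54), lambda = 2.7)
  expect_equal(pinwheel_density(scaled), rho, tolerance = 1e-12)
  expect_error(pinwheel_density(pinwheel_set(1, 1, 0.5,
                                             region = c(0, 2, 0, 2))),
               "lambda")
})

test_that("density variability: Poisson scaling and seeded sampling", {
  pw <- poisson_pinwheels(3000, 50, seed = 7)
  dv <- density_variability(pw, n_samples = 150, seed = 5)
  expect_equal(dv$gamma, 0.5, tolerance = 0.07)
  expect_equal(dv$c, 1 / sqrt(dv$rho), tolerance = 0.12)
  dv2 <- density_variability(pw, n_samples = 150, seed = 5)
  expect_identical(dv$curve, dv2$curve)
  expect_error(density_variability(pw, areas = c(1, 2000)), "quarter")
})

test_that("nearest-neighbour classes obey the superset inequality", {
  pw <- poisson_pinwheels(400, 20, seed = 9)
  d_any <- nn_distances(pw, "any")$d
  d_same <- nn_distances(pw, "same")$d
  d_opp <- nn_distances(pw, "opposite")$d
  expect_true(all(d_any <= pmin(d_same, d_opp) + 1e-12))
  two <- pinwheel_set(c(1, 3), c(1, 1), c(0.5, -0.5),
                      region = c(0, 4, 0, 4), lambda = 1)
  expect_equal(nn_distances(two, "any")$d, c(2, 2))
  expect_error(nn_distances(two[1, ], "any"), "at least two")
})

test_that("circular difference is a proper metric on orientations", {
  b <- std_map_bundle()
  same <- circular_difference(b$unf, b$unf)
  expect_equal(max(same$d_deg[b$unf$valid & !is.na(same$d_deg)]), 0)
  shifted <- b$unf
  shifted$z <- b$unf$z * exp(2i * (pi / 2))
  d90 <- circular_difference(b$unf, shifted)
  expect_equal(d90$fraction_above, 1)
  expect_equal(min(d90$d_deg, na.rm = TRUE), 90, tolerance = 1e-9)
})

test_that("map cross-correlation fixed points", {
  b <- std_map_bundle()
  expect_equal(map_cross_correlation(b$unf, b$unf), 1, tolerance = 1e-12)
  shifted <- b$unf
  shifted$z <- b$unf$z * exp(2i * (pi / 2))
  expect_equal(map_cross_correlation(b$unf, shifted), -1, tolerance = 1e-12)
  expect_equal(map_cross_correlation(b$unf, b$unf, method = "circular"), 1,
               tolerance = 1e-12)
  const <- tuning_map(matrix(1 + 0i, nrow(b$unf$z), ncol(b$unf$z)),
                      b$unf$px_mm)
  expect_error(map_cross_correlation(const, const), "constant")
})

test_that("crystalline density is stable across grid resolution", {
  r32 <- sixmode_layout_density(cells_x = 4, cells_y = 3,
                                px_per_lambda = 32)
  r128 <- sixmode_layout_density(cells_x = 4, cells_y = 3,
                                 px_per_lambda = 128)
  expect_lt(abs(r32$rho - r128$rho) / r128$rho, 0.01)
})
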