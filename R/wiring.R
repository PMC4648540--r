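#' Wiring model parameters
#'
#' @param sigma_r RGC receptive-field width (um).
#' @param sigma_s afferent sampling range (um): the range over which a V1
#'   unit receives retino-thalamic inputs.  For `sigma_s` well below the
#'   lattice spacing most units are dominated by a single ON/OFF dipole.
#' @param magnification retino-cortical magnification (mm cortex per mm
#'   retina); the default identity maps cortical mm directly onto retinal
#'   mm.
#' @return a `wiring_params` list.
#' @export
wiring_params <- function(sigma_r = 70, sigma_s = 20, magnification = 1) {
  stopifnot(sigma_r > 0, sigma_s > 0, magnification > 0)
  structure(list(sigma_r = sigma_r, sigma_s = sigma_s,
                 magnification = magnification), class = "wiring_params")
}

#' Square cortical grid
#'
#' @param size_mm side length of the square cortical window (mm).
#' @param n_px samples per axis.
#' @return a `cortical_grid` with pixel-centre coordinates (mm, origin at
#'   the window centre) and the pixel size.
#' @export
cortical_grid <- function(size_mm, n_px) {
  stopifnot(size_mm > 0, n_px >= 2)
  px <- size_mm / n_px
  coords <- (seq_len(n_px) - (n_px + 1) / 2) * px
  structure(list(xg_mm = coords, yg_mm = coords, px_mm = px,
                 size_mm = size_mm, n_px = as.integer(n_px)),
            class = "cortical_grid")
}

#' Receptive-field container
#'
#' @param values matrix of RF amplitudes indexed `[i, j]` for `xg[i]`,
#'   `yg[j]` (retinal um, signed, arbitrary linear units).
#' @param xg,yg retinal grid coordinates (um).
#' @param center cortical unit position (um, retinal coordinates).
#' @param params parameter list used to build the field.
#' @export
receptive_field <- function(values, xg, yg, center, params = list()) {
  stopifnot(is.matrix(values), nrow(values) == length(xg),
            ncol(values) == length(yg))
  structure(list(values = values, xg = xg, yg = yg, center = center,
                 params = params), class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field> %d x %d samples, centre (%.0f, %.0f) um, peak |RF| %.3g\n",
              nrow(x$values), ncol(x$values), x$center[1], x$center[2],
              max(abs(x$values))))
  invisible(x)
}

#' Cortical receptive field by Gaussian-weighted afferent summation
#'
#' Numerical (brute-force) evaluation of the statistical wiring model
#' receptive field \deqn{RF_y(x) = \sum_j \pm w_j(y) \exp(-(x_j - x)^2 /
#' 2\sigma_r^2), \quad w_j(y) = \exp(-(x_j - y)^2 / 2\sigma_s^2),} sign by
#' cell polarity.  The mosaic must cover the sampling window plus the
#' Gaussian decay margin so the finite sum is a faithful evaluation of the
#' infinite one.
#'
#' @param mosaic an [rgc_mosaic()].
#' @param y cortical unit position (um, retinal coordinates).
#' @param params a [wiring_params()] object.
#' @param window RF sampling window (um), extent spec as in [rgc_mosaic()];
#'   default: `8 sigma_r` around `y`.
#' @param step sampling step (um).
#' @param w_cut afferent weight cutoff; cells with `w_j` below it are
#'   skipped (`0` keeps every cell in the mosaic).
#' @return a [receptive_field()].
#' @export
cortical_rf <- function(mosaic, y, params = wiring_params(), window = NULL,
                        step = params$sigma_r / 10, w_cut = 1e-12) {
  stopifnot(inherits(mosaic, "rgc_mosaic"), length(y) == 2L)
  if (is.null(window)) {
    w <- 4 * params$sigma_r
    window <- c(y[1] - w, y[1] + w, y[2] - w, y[2] + w)
  }
  ext <- as_extent(window)
  if (ext[2] - ext[1] < 2 * params$sigma_r) {
    stop("window too small to contain the receptive-field support",
         call. = FALSE)
  }
  xg <- seq(ext[1], ext[2], by = step)
  yg <- seq(ext[3], ext[4], by = step)
  w_j <- exp(-((mosaic$x - y[1])^2 + (mosaic$y - y[2])^2) /
               (2 * params$sigma_s^2))
  s_j <- ifelse(mosaic$polarity == "ON", 1, -1)
  keep <- w_j >= w_cut & w_j > 0
  vals <- matrix(0, length(xg), length(yg))
  for (j in which(keep)) {
    gx <- exp(-(xg - mosaic$x[j])^2 / (2 * params$sigma_r^2))
    gy <- exp(-(yg - mosaic$y[j])^2 / (2 * params$sigma_r^2))
    vals <- vals + (s_j[j] * w_j[j]) * outer(gx, gy)
  }
  receptive_field(vals, xg, yg, center = y,
                  params = list(sigma_r = params$sigma_r,
                                sigma_s = params$sigma_s,
                                source = "lattice_sum"))
}

#' Tuning extraction from a receptive field
#'
#' Computes the amplitude spectrum \eqn{|R(k)|} of the receptive field by
#' discrete Fourier transform and extracts preferred orientation
#' \eqn{\vartheta_{pref} = \arg(\mu)/2} with \deqn{\mu = \frac{\int d^2k\,
#' |R(k)|\, e^{2i\arg k}\, |k|}{\int d^2k\, |R(k)|},} preferred spatial
#' frequency by the selected estimator, and the orientation selectivity
#' index (OSI) as the normalized second angular harmonic of the tuning
#' curve at `k_pref`.
#'
#' Estimators: `"maximum"` (mode of \eqn{|R|}; the default, unaffected by
#' monotone output nonlinearities), `"cv_max"` (wavenumber maximizing the
#' angular resultant, i.e. orientation selectivity) and `"center_of_mass"`
#' (\eqn{|\mu|}; systematically smaller for two-lobed fields).
#'
#' @param rf a [receptive_field()].
#' @param k_method preferred spatial-frequency estimator.
#' @param n_phi angular samples for ring interpolation.
#' @return list with `theta` (radians in \eqn{[0,\pi)}, `NA` if untuned),
#'   `k_pref` (rad/um), `osi` and `mu`.
#' @export
rf_tuning <- function(rf, k_method = c("maximum", "cv_max",
                                       "center_of_mass"), n_phi = 90) {
  k_method <- match.arg(k_method)
  stopifnot(inherits(rf, "receptive_field"))
  v <- rf$values
  if (all(v == 0)) stop("all-zero receptive field: tuning undefined",
                        call. = FALSE)
  n <- nrow(v); m <- ncol(v)
  step <- rf$xg[2] - rf$xg[1]
  A <- Mod(fft(v))
  kx <- fft_freq(n, step); ky <- fft_freq(m, step)
  KX <- outer(kx, rep(1, m)); KY <- outer(rep(1, n), ky)
  KK <- sqrt(KX^2 + KY^2)
  kmax_valid <- min(max(abs(kx)), max(abs(ky)))  # stay inside Nyquist disc
  inside <- KK > 0 & KK <= kmax_valid
  w <- A * inside
  mu <- sum(w * KK * exp(2i * atan2(KY, KX))) / sum(w)
  # ring tuning curve by bilinear interpolation of |R| at radius k
  ring <- function(k) {
    phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
    qx <- k * cos(phi); qy <- k * sin(phi)
    dkx <- kx[2] - kx[1]; dky <- ky[2] - ky[1]
    # map wavevector to fractional index in unshifted FFT layout
    xi <- ifelse(qx >= 0, qx / dkx, n + qx / dkx) + 1
    yi <- ifelse(qy >= 0, qy / dky, m + qy / dky) + 1
    list(phi = phi, tc = Re(bilinear(A, xi, yi)))
  }
  osi_at <- function(k) {
    rg <- ring(k)
    Mod(sum(rg$tc * exp(2i * rg$phi))) / sum(rg$tc)
  }
  k_pref <- switch(
    k_method,
    maximum = KK[inside][which.max(A[inside])],
    center_of_mass = Mod(mu),
    cv_max = {
      ks <- seq(min(KK[inside]), kmax_valid, length.out = 64)
      ks[which.max(vapply(ks, osi_at, 0))]
    })
  osi <- osi_at(k_pref)
  # preferred edge orientation: perpendicular to the resultant wavevector
  # direction; undefined for rotationally symmetric fields
  theta <- if (osi < 1e-2) NA_real_ else
    fold_orientation(Arg(mu) / 2 + pi / 2)
  list(theta = theta, k_pref = k_pref, osi = osi, mu = mu)
}

#' Tuning map container
#'
#' A per-pixel description of an orientation-domain layout, canonically the
#' complex field \eqn{z = OSI \cdot e^{2i\vartheta_{pref}}} (or a raw
#' complex field for analytic/GRF stages).
#'
#' @param z complex matrix, indexed `[i, j]` for x- and y-position.
#' @param px_mm pixel size (mm).
#' @param stage one of `"unfiltered"`, `"thresholded"`, `"smoothed"`,
#'   `"analytic_unfiltered"`, `"analytic_sixmode"`, `"grf"`.
#' @param kpref optional matrix of preferred spatial frequencies (rad/um).
#' @param valid optional logical matrix flagging pixels usable for
#'   statistics (e.g. away from the boundary).
#' @param params provenance list.
#' @return a `tuning_map`.
#' @export
tuning_map <- function(z, px_mm, stage = "unfiltered", kpref = NULL,
                       valid = NULL, params = list()) {
  stopifnot(is.matrix(z), px_mm > 0)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(z), ncol(z))
  structure(list(z = z, px_mm = px_mm, stage = stage, kpref = kpref,
                 valid = valid, params = params), class = "tuning_map")
}

#' @export
print.tuning_map <- function(x, ...) {
  cat(sprintf("<tuning_map> %d x %d px, %.4f mm/px (%.2f mm), stage '%s'\n",
              nrow(x$z), ncol(x$z), x$px_mm, nrow(x$z) * x$px_mm, x$stage))
  invisible(x)
}

#' Preferred orientation / selectivity accessors
#' @param map a [tuning_map()].
#' @return matrix of orientations in \eqn{[0,\pi)} (`NA` where selectivity
#'   vanishes) or of selectivity magnitudes.
#' @export
map_theta <- function(map) {
  th <- fold_orientation(Arg(map$z) / 2)
  th[Mod(map$z) == 0] <- NA_real_
  th
}

#' @rdname map_theta
#' @export
map_osi <- function(map) Mod(map$z)

#' Numerical orientation-domain layout of the statistical wiring model
#'
#' Per-pixel receptive-field tuning over a cortical grid: for each pixel the
#' receptive-field amplitude spectrum is evaluated on a polar wavenumber
#' grid directly from the afferent sum (the Fourier transform of Eqs for
#' \eqn{RF_y} is a weighted sum of plane waves under a Gaussian envelope),
#' and \eqn{\vartheta_{pref}}, OSI and \eqn{k_{pref}} (Maximum method) are
#' extracted exactly as in [rf_tuning()].  Implemented in C++.
#'
#' @param mosaic an [rgc_mosaic()]; must cover the grid window plus a
#'   margin of about `4 sigma_s + 3 sigma_r`.
#' @param grid a [cortical_grid()].
#' @param params a [wiring_params()].
#' @param n_k,n_phi radial / angular samples of the polar spectral grid.
#' @param k_max maximum wavenumber (rad/um); default `4 / sigma_r`, beyond
#'   which the Gaussian envelope suppresses all structure.
#' @param boundary_lambda width (in expected column spacings) of the
#'   boundary exclusion zone marked invalid for downstream statistics; the
#'   spacing is taken from `lambda_mm`.
#' @param lambda_mm expected column spacing (mm) used only for the validity
#'   mask; `NULL` disables the mask.
#' @return a [tuning_map()] with stage `"unfiltered"`,
#'   `z = OSI exp(2i theta)`.
#' @export
compute_unfiltered_map <- function(mosaic, grid, params = wiring_params(),
                                   n_k = 36, n_phi = 24, k_max = NULL,
                                   boundary_lambda = 0.5, lambda_mm = NULL) {
  stopifnot(inherits(mosaic, "rgc_mosaic"), inherits(grid, "cortical_grid"))
  if (is.null(k_max)) k_max <- 4 / params$sigma_r
  um_per_mm <- 1000 / params$magnification
  xg_um <- grid$xg_mm * um_per_mm
  yg_um <- grid$yg_mm * um_per_mm
  margin <- 4 * params$sigma_s + 3 * params$sigma_r
  ext <- mosaic$extent
  if (min(xg_um) - margin < ext[1] || max(xg_um) + margin > ext[2] ||
      min(yg_um) - margin < ext[3] || max(yg_um) + margin > ext[4]) {
    stop("mosaic does not cover the cortical window plus the decay margin",
         call. = FALSE)
  }
  s_j <- ifelse(mosaic$polarity == "ON", 1, -1)
  res <- map_tuning_kernel(xg_um, yg_um, mosaic$x, mosaic$y, s_j,
                           params$sigma_r, params$sigma_s,
                           as.integer(n_k), as.integer(n_phi), k_max)
  z <- matrix(complex(modulus = res$osi, argument = 2 * res$theta),
              grid$n_px, grid$n_px)
  valid <- matrix(TRUE, grid$n_px, grid$n_px)
  if (!is.null(lambda_mm)) {
    b <- boundary_lambda * lambda_mm
    edge_x <- pmin(grid$xg_mm - min(grid$xg_mm),
                   max(grid$xg_mm) - grid$xg_mm) < b
    edge_y <- pmin(grid$yg_mm - min(grid$yg_mm),
                   max(grid$yg_mm) - grid$yg_mm) < b
    edge <- outer(edge_x, rep(TRUE, grid$n_px), "&") |
      outer(rep(TRUE, grid$n_px), edge_y, "&")
    valid <- !edge
  }
  tuning_map(z = z, px_mm = grid$px_mm, stage = "unfiltered",
             kpref = matrix(res$kpref, grid$n_px, grid$n_px),
             valid = valid,
             params = list(sigma_r = params$sigma_r,
                           sigma_s = params$sigma_s,
                           magnification = params$magnification,
                           n_k = n_k, n_phi = n_phi, k_max = k_max))
}

#' OSI thresholding and Gaussian smoothing of an orientation layout
#'
#' Sets \eqn{z} to zero wherever the OSI is at or below `osi_threshold`,
#' then convolves the masked complex field with an isotropic Gaussian
#' low-pass of standard deviation `kernel_sd_mm` (FFT, periodic
#' boundaries); orientation and selectivity are re-derived from the
#' smoothed field.
#'
#' @param map an unfiltered [tuning_map()].
#' @param osi_threshold OSI cutoff (the classical choice is 0.25).
#' @param kernel_sd_mm Gaussian kernel SD (mm); the package default in
#'   pipeline drivers is \eqn{0.15 \Lambda}.  `0` skips smoothing (returns
#'   the thresholded stage).
#' @return a [tuning_map()] with stage `"smoothed"` (or `"thresholded"`).
#' @export
threshold_and_smooth <- function(map, osi_threshold = 0.25, kernel_sd_mm) {
  stopifnot(inherits(map, "tuning_map"))
  if (!map$stage %in% c("unfiltered", "analytic_unfiltered")) {
    stop("threshold_and_smooth expects an unfiltered map", call. = FALSE)
  }
  z <- map$z
  z[is.na(z)] <- 0  # undefined orientation (zero RF) carries no tuning
  z[Mod(z) <= osi_threshold] <- 0
  if (kernel_sd_mm < 0) stop("kernel width must be non-negative", call. = FALSE)
  stage <- "thresholded"
  if (kernel_sd_mm > 0) {
    z <- gaussian_smooth_fft(z, kernel_sd_mm, map$px_mm)
    stage <- "smoothed"
  }
  tuning_map(z = z, px_mm = map$px_mm, stage = stage, kpref = map$kpref,
             valid = map$valid,
             params = c(map$params, list(osi_threshold = osi_threshold,
                                         kernel_sd_mm = kernel_sd_mm)))
}
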