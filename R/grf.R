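#' Normalized power-law x Gaussian spectral filter
#'
#' The flexible band-pass family \deqn{f(k) = a |k|^{\beta}
#' \exp(-|k|^2/b),} normalized (in scaled wavenumber units) so that
#' \eqn{\int d^2k\, f = 2\pi} and the power-weighted mean wavenumber
#' \eqn{\bar k = (1/2\pi)\int d^2k\, |k| f = 1}; the mean column spacing of
#' a field with this spectrum is then \eqn{\Lambda = 2\pi/\bar k}, mapped
#' to physical units by the `Lambda_mm` scale.  Both normalization
#' constants have closed forms via Gamma-function moments:
#' \eqn{b = [\Gamma((\beta+2)/2)/\Gamma((\beta+3)/2)]^2}.
#'
#' @param beta spectral exponent (\eqn{\beta \ge 0}); 0 gives a Gaussian
#'   low-pass, large values a narrow band-pass.
#' @param Lambda_mm physical mean column spacing (mm).
#' @return a `spectral_filter` with fields `beta`, `a`, `b`, `Lambda_mm`
#'   and the evaluator `f(k_scaled)`.
#' @export
make_power_filter <- function(beta, Lambda_mm = 1) {
  stopifnot(beta >= 0, Lambda_mm > 0)
  b <- (gamma((beta + 2) / 2) / gamma((beta + 3) / 2))^2
  a <- 2 / (b^((beta + 2) / 2) * gamma((beta + 2) / 2))
  structure(list(family = "power_gaussian", beta = beta, a = a, b = b,
                 Lambda_mm = Lambda_mm,
                 f = function(k) a * k^beta * exp(-k^2 / b)),
            class = "spectral_filter")
}

#' @export
print.spectral_filter <- function(x, ...) {
  cat(sprintf("<spectral_filter> %s, beta %.3g, b %.4f, Lambda %.2f mm\n",
              x$family, x$beta, x$b, x$Lambda_mm))
  invisible(x)
}

# physical wavenumber (rad/mm) -> scaled filter units (kbar = 1)
filter_scale_k <- function(filter, k_mm) k_mm * filter$Lambda_mm / (2 * pi)

#' Sample a Gaussian random field with a prescribed spectrum
#'
#' Independent complex Gaussian Fourier amplitudes shaped by
#' \eqn{\sqrt{f}} (so the sample power spectrum matches `f`), inverse
#' transformed to a complex field whose phase \eqn{\arg(z)/2} is the
#' orientation layout.
#'
#' @param filter a [make_power_filter()] (or compatible) filter.
#' @param n_px grid samples per axis.
#' @param size_mm physical grid side length (mm).
#' @param seed optional integer seed.
#' @return a [tuning_map()] with stage `"grf"`, unit-RMS complex field.
#' @export
grf_sample <- function(filter, n_px = 512, size_mm = 22 * filter$Lambda_mm,
                       seed = NULL) {
  stopifnot(inherits(filter, "spectral_filter"))
  px <- size_mm / n_px
  k_mm <- fft_freq(n_px, px)
  kk <- sqrt(outer(k_mm^2, k_mm^2, "+"))
  ks <- filter_scale_k(filter, kk)
  fk <- filter$f(ks)
  fk[1, 1] <- 0
  if (max(ks) < 3) {
    stop("grid Nyquist does not cover the filter support", call. = FALSE)
  }
  z <- with_seed(seed, {
    a <- matrix(complex(real = rnorm(n_px^2), imaginary = rnorm(n_px^2)),
                n_px, n_px)
    fft(a * sqrt(fk), inverse = TRUE)
  })
  z <- z / sqrt(mean(Mod(z)^2))
  tuning_map(z = z, px_mm = px, stage = "grf",
             params = list(beta = filter$beta, Lambda_mm = filter$Lambda_mm,
                           seed = seed))
}

#' Pinwheel density surface of GRF ensembles
#'
#' For each (beta, Lambda) combination: sample GRF layouts, detect
#' pinwheels and compute the density per \eqn{\Lambda^2}.  By default the
#' column spacing entering the density is the one fixed by the filter
#' normalization; `lambda_mode = "wavelet"` instead uses the
#' wavelet-estimated mean spacing of each realization.
#'
#' @param betas filter exponents.
#' @param lambdas_mm filter scales (mm).
#' @param n_real realizations per grid point.
#' @param n_px grid samples per axis.
#' @param n_lambda grid side length in units of \eqn{\Lambda}.
#' @param lambda_mode `"filter"` or `"wavelet"`.
#' @param seed integer seed; realization seeds are derived from it.
#' @return data.frame with columns `beta`, `Lambda_mm`, `rho_mean`,
#'   `rho_sem`, `n`.
#' @export
grf_density_surface <- function(betas, lambdas_mm = 0.9, n_real = 20,
                                n_px = 512, n_lambda = 22,
                                lambda_mode = c("filter", "wavelet"),
                                seed = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  grid <- expand.grid(beta = betas, Lambda_mm = lambdas_mm)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    flt <- make_power_filter(grid$beta[g], grid$Lambda_mm[g])
    rho <- vapply(seq_len(n_real), function(i) {
      s <- if (is.null(seed)) NULL else seed + 7919 * g + i
      zmap <- grf_sample(flt, n_px = n_px,
                         size_mm = n_lambda * flt$Lambda_mm, seed = s)
      lam <- if (lambda_mode == "filter") flt$Lambda_mm else {
        local_column_spacing(zmap, lambda_expected_mm = flt$Lambda_mm,
                             coarse = TRUE)$mean_lambda_mm
      }
      pw <- find_pinwheels(zmap, lambda_mm = lam)
      pinwheel_density(pw)
    }, 0)
    data.frame(beta = grid$beta[g], Lambda_mm = grid$Lambda_mm[g],
               rho_mean = mean(rho), rho_sem = sd(rho) / sqrt(n_real),
               n = n_real)
  })
  do.call(rbind, rows)
}

#' Band-pass filtering of a broadband (PIPP-derived) layout
#'
#' Applies the spectral filter `f` directly to the Fourier amplitudes of
#' the layout's complex field (amplitude shaping) and renormalizes,
#' producing a smoothed orientation-domain layout with a defined column
#' spacing.  Use [fermi_bandpass()] for the Fermi band filter variant.
#'
#' @param map a [tuning_map()] (typically a thresholded PIPP layout).
#' @param filter a [make_power_filter()] filter.
#' @return a [tuning_map()] with stage `"smoothed"`.
#' @export
pipp_layout_bandpass <- function(map, filter) {
  stopifnot(inherits(map, "tuning_map"), inherits(filter, "spectral_filter"))
  n <- nrow(map$z); m <- ncol(map$z)
  k_mm <- fft_freq(n, map$px_mm)
  kk <- sqrt(outer(k_mm^2, fft_freq(m, map$px_mm)^2, "+"))
  fk <- filter$f(filter_scale_k(filter, kk))
  fk[1, 1] <- 0
  z <- fft(fft(map$z) * fk, inverse = TRUE) / (n * m)
  z <- z / sqrt(mean(Mod(z)^2))
  tuning_map(z = z, px_mm = map$px_mm, stage = "smoothed",
             valid = map$valid,
             params = c(map$params, list(bandpass_beta = filter$beta,
                                         bandpass_Lambda = filter$Lambda_mm)))
}
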