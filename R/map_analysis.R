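#' Amplitude spectrum of an orientation-domain layout
#'
#' \eqn{|R(k)|}, the modulus of the Fourier transform of the unit-modulus
#' complex orientation field \eqn{z(x) = e^{2i\vartheta(x)}} (pixels with
#' undefined orientation contribute zero).
#'
#' @param map a [tuning_map()].
#' @param unit_modulus if `TRUE` (default) the orientation field is
#'   normalized to unit modulus before transforming; otherwise the map's
#'   raw `z` (e.g. OSI-weighted) is used.
#' @return list with `A` (modulus matrix, centred/fftshifted), `kx`, `ky`
#'   (rad/mm axes).
#' @export
amplitude_spectrum <- function(map, unit_modulus = TRUE) {
  stopifnot(inherits(map, "tuning_map"))
  z <- map$z
  z[is.na(z)] <- 0
  if (unit_modulus) {
    m <- Mod(z)
    z <- ifelse(m > 0, z / m, 0i)
  }
  n <- nrow(z); m2 <- ncol(z)
  A <- Mod(fft(z))
  shift <- function(v) {
    h <- floor(length(v) / 2)
    c(v[(h + 1):length(v)], v[1:h])
  }
  ord_x <- order(fft_freq(n, map$px_mm))
  ord_y <- order(fft_freq(m2, map$px_mm))
  list(A = A[ord_x, ord_y],
       kx = sort(fft_freq(n, map$px_mm)),
       ky = sort(fft_freq(m2, map$px_mm)))
}

#' Marginal amplitude spectrum
#'
#' Radially averaged amplitude spectrum normalized so its maximum is 1.
#'
#' @param spec output of [amplitude_spectrum()].
#' @param n_bins number of radial bins.
#' @return data.frame with columns `k` (rad/mm, bin centres) and `f`.
#' @export
marginal_spectrum <- function(spec, n_bins = 64) {
  KK <- sqrt(outer(spec$kx^2, spec$ky^2, "+"))
  kmax <- min(max(abs(spec$kx)), max(abs(spec$ky)))
  edges <- seq(0, kmax, length.out = n_bins + 1)
  bin <- findInterval(KK, edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= n_bins & KK > 0
  f <- tapply(spec$A[ok], bin[ok], mean)
  k <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(k = k[as.integer(names(f))], f = as.numeric(f))
  out$f <- out$f / max(out$f)
  out
}

#' Fermi band-pass filter
#'
#' Radially symmetric transfer function built as the product of two Fermi
#' steps in wavelength: approximately 1 for wavelengths between
#' `lambda_low_mm` (high-frequency cutoff, classically 0.3 mm) and
#' `lambda_high_mm` (low-frequency cutoff, 1.2 mm), rolling off outside.
#' The DC component is removed.
#'
#' @param img numeric or complex matrix (an image or complex orientation
#'   field).
#' @param px_mm pixel size (mm).
#' @param lambda_low_mm,lambda_high_mm cutoff wavelengths (mm),
#'   `lambda_low_mm < lambda_high_mm`.
#' @param steepness Fermi step width as a fraction of the respective cutoff
#'   wavelength.
#' @return the filtered matrix (complex if the input was complex).
#' @export
fermi_bandpass <- function(img, px_mm, lambda_low_mm = 0.3,
                           lambda_high_mm = 1.2, steepness = 0.05) {
  stopifnot(is.matrix(img), lambda_low_mm < lambda_high_mm)
  n <- nrow(img); m <- ncol(img)
  k_nyq <- pi / px_mm
  if (2 * pi / lambda_low_mm > k_nyq) {
    stop("high-frequency cutoff beyond the grid Nyquist wavenumber",
         call. = FALSE)
  }
  if (lambda_high_mm > n * px_mm) {
    stop("low-frequency cutoff wavelength exceeds the grid size",
         call. = FALSE)
  }
  kx <- fft_freq(n, px_mm); ky <- fft_freq(m, px_mm)
  KK <- sqrt(outer(kx^2, ky^2, "+"))
  lam <- ifelse(KK > 0, 2 * pi / KK, Inf)
  g <- 1 / (1 + exp(-(lam - lambda_low_mm) / (steepness * lambda_low_mm))) *
    1 / (1 + exp((lam - lambda_high_mm) / (steepness * lambda_high_mm)))
  g[!is.finite(lam)] <- 0
  out <- fft(fft(img) * g, inverse = TRUE) / (n * m)
  if (is.numeric(img)) Re(out) else out
}

#' Morlet wavelet configuration
#'
#' Complex Morlet wavelets \eqn{\phi(x) = \sigma^{-1} \exp(-x^2/2\sigma^2)
#' e^{i k_\phi x}} with carrier \eqn{k_\phi = (2\pi/\Lambda)(1,0)^T} and
#' envelope \eqn{\sigma = \xi\Lambda/2\pi} per scale \eqn{\Lambda}; the
#' orientation average runs over `n_ori` equally spaced wavelet
#' orientations in \eqn{[0, \pi)}.
#'
#' @param xi envelope size factor (the classical choice is 7, about
#'   \eqn{\xi/2\pi} carrier periods under the envelope).
#' @param n_ori number of wavelet orientations.
#' @param scales_mm strictly increasing scale grid (mm); if `NULL` it is
#'   derived from `lambda_expected_mm` at analysis time as `n_scales`
#'   log-spaced scales spanning `[lambda/3, 3 lambda]`.
#' @param n_scales number of scales for the derived grid.
#' @return a `wavelet_config`.
#' @export
wavelet_config <- function(xi = 7, n_ori = 16, scales_mm = NULL,
                           n_scales = 24) {
  stopifnot(xi > 0, n_ori >= 8)
  if (!is.null(scales_mm)) stopifnot(all(diff(scales_mm) > 0))
  structure(list(xi = xi, n_ori = n_ori, scales_mm = scales_mm,
                 n_scales = n_scales), class = "wavelet_config")
}

#' Local column spacing by Morlet wavelet analysis
#'
#' Orientation-averaged Morlet wavelet coefficient moduli are computed for
#' every scale on the grid; the local column spacing is the scale
#' maximizing the coefficient at each position, and the map's column
#' spacing estimate is its mean over the valid region.
#'
#' Coefficients are evaluated in the Fourier domain (the wavelet transfer
#' function is a Gaussian of width \eqn{1/\sigma} centred on the rotated
#' carrier).  With `coarse = TRUE` only the spectral neighbourhood of the
#' carrier is inverse-transformed, yielding the coefficient field on a
#' reduced spatial grid -- exact for the modulus, and much faster for
#' sweep-scale analyses.
#'
#' @param map a [tuning_map()].
#' @param lambda_expected_mm centre of the default scale grid (mm).
#' @param cfg a [wavelet_config()].
#' @param coarse use the cropped-spectrum evaluation (reduced spatial
#'   sampling of the coefficient fields).
#' @return list with `mean_lambda_mm`, `lambda_local_mm` (matrix), `xg_mm`,
#'   `yg_mm` (coordinates of the coefficient grid), `scales_mm` and
#'   `boundary_fraction` (share of positions whose argmax hit the scale
#'   grid boundary; a warning is raised above 10%).
#' @export
local_column_spacing <- function(map, lambda_expected_mm = NULL,
                                 cfg = wavelet_config(), coarse = FALSE) {
  stopifnot(inherits(map, "tuning_map"), inherits(cfg, "wavelet_config"))
  scales <- cfg$scales_mm
  if (is.null(scales)) {
    if (is.null(lambda_expected_mm)) {
      stop("either scales_mm or lambda_expected_mm must be given",
           call. = FALSE)
    }
    scales <- exp(seq(log(lambda_expected_mm / 3),
                      log(3 * lambda_expected_mm),
                      length.out = cfg$n_scales))
  }
  n <- nrow(map$z); m <- ncol(map$z)
  L <- n * map$px_mm
  if (L < 4 * max(scales)) {
    warning("map extent below 4x the largest wavelet scale; large-scale estimates unreliable")
  }
  zz <- map$z
  zz[is.na(zz)] <- 0
  Z <- fft(zz)
  kx <- fft_freq(n, map$px_mm); ky <- fft_freq(m, map$px_mm)
  dk <- kx[2] - kx[1]
  resp <- NULL
  if (coarse) {
    sig_min <- cfg$xi * min(scales) / (2 * pi)
    h <- ceiling(4 / (sig_min * dk))
    B <- min(2 * h + 1, n)
    idx_wrap <- function(c0) ((c0 - h):(c0 + h)) %% n + 1
    resp <- array(0, c(B, B, length(scales)))
    for (si in seq_along(scales)) {
      lam <- scales[si]
      sig <- cfg$xi * lam / (2 * pi)
      k0 <- 2 * pi / lam
      acc <- matrix(0, B, B)
      for (oi in seq_len(cfg$n_ori)) {
        phi <- (oi - 1) * pi / cfg$n_ori
        kcx <- k0 * cos(phi); kcy <- k0 * sin(phi)
        ci <- round(kcx / dk); cj <- round(kcy / dk)
        ri <- idx_wrap(ci); rj <- idx_wrap(cj)
        gk <- 2 * pi * sig *
          exp(-sig^2 * (outer((kx[ri] - kcx)^2, (ky[rj] - kcy)^2, "+")) / 2)
        blk <- Z[ri, rj] * gk
        psi <- fft(blk, inverse = TRUE) / (n * m)
        acc <- acc + Mod(psi)
      }
      resp[, , si] <- acc / cfg$n_ori
    }
    xg <- (seq_len(B) - 1) * L / B
    yg <- (seq_len(B) - 1) * (m * map$px_mm) / B
  } else {
    resp <- array(0, c(n, m, length(scales)))
    for (si in seq_along(scales)) {
      lam <- scales[si]
      sig <- cfg$xi * lam / (2 * pi)
      k0 <- 2 * pi / lam
      acc <- matrix(0, n, m)
      for (oi in seq_len(cfg$n_ori)) {
        phi <- (oi - 1) * pi / cfg$n_ori
        kcx <- k0 * cos(phi); kcy <- k0 * sin(phi)
        gk <- 2 * pi * sig *
          exp(-sig^2 * outer((kx - kcx)^2, (ky - kcy)^2, "+") / 2)
        psi <- fft(Z * gk, inverse = TRUE) / (n * m)
        acc <- acc + Mod(psi)
      }
      resp[, , si] <- acc / cfg$n_ori
    }
    xg <- (seq_len(n) - 1) * map$px_mm
    yg <- (seq_len(m) - 1) * map$px_mm
  }
  best <- apply(resp, c(1, 2), which.max)
  lambda_local <- matrix(scales[best], nrow(best), ncol(best))
  # restrict the mean to the valid region (subsampled when coarse)
  vi <- pmin(pmax(round(xg / map$px_mm) + 1, 1), n)
  vj <- pmin(pmax(round(yg / map$px_mm) + 1, 1), m)
  vmask <- map$valid[vi, vj, drop = FALSE]
  bf <- mean(best[vmask] == 1 | best[vmask] == length(scales))
  if (is.finite(bf) && bf > 0.1) {
    warning(sprintf(
      "scale grid too narrow: argmax at boundary for %.0f%% of positions",
      100 * bf))
  }
  list(mean_lambda_mm = mean(lambda_local[vmask]),
       lambda_local_mm = lambda_local, xg_mm = xg, yg_mm = yg,
       scales_mm = scales, boundary_fraction = bf)
}

#' Pinwheel set container
#'
#' @param x,y singularity positions (mm, or the map's length unit).
#' @param charge topological charges (\eqn{\pm 1/2} generically, \eqn{\pm 1}
#'   for degenerate multiplicity-2 zeros).
#' @param degenerate logical flag per pinwheel.
#' @param region analysis region `c(xmin, xmax, ymin, ymax)`.
#' @param lambda column spacing used for normalization (same unit).
#' @param confidence optional per-pinwheel confidence flag.
#' @return a `pinwheel_set` (a data.frame with attributes `region` and
#'   `lambda`).
#' @export
pinwheel_set <- function(x, y, charge, degenerate = rep(FALSE, length(x)),
                         region, lambda = NA_real_,
                         confidence = rep(1, length(x))) {
  stopifnot(all(abs(abs(charge) - 0.5) < 1e-9 | abs(abs(charge) - 1) < 1e-9))
  df <- data.frame(x = x, y = y, charge = charge, degenerate = degenerate,
                   confidence = confidence)
  attr(df, "region") <- as_extent(region)
  attr(df, "lambda") <- lambda
  class(df) <- c("pinwheel_set", "data.frame")
  df
}

#' Set / read the column spacing of a pinwheel set
#' @param set a [pinwheel_set()].
#' @param lambda column spacing (same unit as the positions).
#' @export
set_lambda <- function(set, lambda) {
  stopifnot(lambda > 0)
  attr(set, "lambda") <- lambda
  set
}

pw_region <- function(set) attr(set, "region")
pw_lambda <- function(set) attr(set, "lambda")

#' Locate phase singularities (pinwheels) of a complex field
#'
#' Singularities of \eqn{\vartheta = \arg(z)/2} are located as the common
#' zeros of \eqn{\mathrm{Re}\,z} and \eqn{\mathrm{Im}\,z}: candidate
#' neighbourhoods are flagged by the discrete winding number accumulated on
#' small grid loops, positions are refined to sub-pixel accuracy on the
#' bilinear interpolant, and the topological charge is the winding of
#' \eqn{\arg z} on a surrounding circular plaquette divided by two
#' (\eqn{\pm 1/2} generically; multiplicity-2 zeros give \eqn{\pm 1} and
#' are flagged degenerate).
#'
#' @param map a [tuning_map()] (or any complex matrix wrapped into one).
#' @param margin_lambda width of the boundary exclusion strip in units of
#'   `lambda_mm` (also excluded from the reported analysis region).
#' @param lambda_mm column spacing used for the exclusion margin and stored
#'   for normalization (optional).
#' @return a [pinwheel_set()] with positions in mm.
#' @export
find_pinwheels <- function(map, margin_lambda = 0, lambda_mm = NA_real_) {
  stopifnot(inherits(map, "tuning_map"))
  z <- map$z
  n <- nrow(z); m <- ncol(z)
  ph <- Arg(z)
  # winding on 8-point loops around 2x2 superplaquettes: robust for both
  # simple and multiplicity-2 zeros (increments stay well below pi)
  w8 <- matrix(0, n - 2, m - 2)
  path <- list(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2), c(1, 2),
               c(0, 2), c(0, 1))
  ii <- 1:(n - 2); jj <- 1:(m - 2)
  for (s in seq_along(path)) {
    p0 <- path[[s]]; p1 <- path[[if (s == length(path)) 1 else s + 1]]
    w8 <- w8 + wrap_pi(ph[ii + p1[1], jj + p1[2]] -
                         ph[ii + p0[1], jj + p0[2]])
  }
  cand <- which(abs(w8) > pi, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    reg <- c(0, n, 0, m) * map$px_mm
    return(pinwheel_set(numeric(0), numeric(0), numeric(0),
                        logical(0), reg, lambda_mm))
  }
  # refine each candidate (loop centre at index + 1 in each axis)
  pts <- refine_zeros(z, cand[, 1] + 1, cand[, 2] + 1)
  ok <- rowSums(is.na(pts)) == 0
  pts <- pts[ok, , drop = FALSE]
  if (nrow(pts) == 0) {
    reg <- c(0, n, 0, m) * map$px_mm
    return(pinwheel_set(numeric(0), numeric(0), numeric(0),
                        logical(0), reg, lambda_mm))
  }
  # cluster detections of the same zero from overlapping loops
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pts))
  for (r in seq_len(nrow(pts))) {
    if (!keep[r]) next
    d2 <- (pts[, 1] - pts[r, 1])^2 + (pts[, 2] - pts[r, 2])^2
    dup <- which(d2 < 0.6^2)
    if (length(dup) > 1) {
      pts[r, ] <- colMeans(pts[dup, , drop = FALSE])
      keep[setdiff(dup, r)] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  # charge from the winding on a sampling circle around each zero
  res <- loop_windings(z, pts[, 1], pts[, 2])
  wind <- res$winding
  conf <- res$confidence
  sel <- wind != 0
  pts <- pts[sel, , drop = FALSE]
  wind <- wind[sel]; conf <- conf[sel]
  # positions: grid index (i, j) -> ((i - 0.5) px, (j - 0.5) px)
  x_mm <- (pts[, 1] - 0.5) * map$px_mm
  y_mm <- (pts[, 2] - 0.5) * map$px_mm
  # low confidence when another singularity sits within one pixel
  if (length(x_mm) > 1) {
    d2 <- as.matrix(stats::dist(cbind(pts[, 1], pts[, 2])))^2
    diag(d2) <- Inf
    conf[apply(d2, 1, min) < 1] <- pmin(conf[apply(d2, 1, min) < 1], 0.5)
  }
  reg <- c(0, n, 0, m) * map$px_mm
  inset <- reg
  if (margin_lambda > 0 && is.finite(lambda_mm)) {
    b <- margin_lambda * lambda_mm
    inset <- reg + c(b, -b, b, -b)
  }
  inside <- x_mm >= inset[1] & x_mm <= inset[2] &
    y_mm >= inset[3] & y_mm <= inset[4]
  pinwheel_set(x_mm[inside], y_mm[inside], (wind / 2)[inside],
               degenerate = (abs(wind) == 2)[inside],
               region = inset, lambda = lambda_mm,
               confidence = conf[inside])
}

# Newton refinement (vectorized over candidates) of zeros of the complex
# field near grid indices (i0, j0) (1-based, fractional results); candidates
# with a near-singular Jacobian (multiplicity-2 zeros) fall back to a
# quadratic-surface fit of |z|
refine_zeros <- function(z, i0, j0, max_iter = 12) {
  n <- nrow(z); m <- ncol(z)
  xi <- as.numeric(i0); yi <- as.numeric(j0)
  singular <- rep(FALSE, length(xi))
  active <- rep(TRUE, length(xi))
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ic <- pmin(pmax(round(xi), 2), n - 1)
    jc <- pmin(pmax(round(yi), 2), m - 1)
    f <- bilinear(z, xi, yi)
    dzdx <- (z[cbind(ic + 1, jc)] - z[cbind(ic - 1, jc)]) / 2
    dzdy <- (z[cbind(ic, jc + 1)] - z[cbind(ic, jc - 1)]) / 2
    a11 <- Re(dzdx); a21 <- Im(dzdx); a12 <- Re(dzdy); a22 <- Im(dzdy)
    det_j <- a11 * a22 - a12 * a21
    scl <- abs(a11) + abs(a12) + abs(a21) + abs(a22)
    sing_now <- active & (scl == 0 | abs(det_j) < 1e-6 * scl^2)
    singular <- singular | sing_now
    active <- active & !sing_now
    sx <- (-a22 * Re(f) + a12 * Im(f)) / det_j
    sy <- (a21 * Re(f) - a11 * Im(f)) / det_j
    sx <- pmax(pmin(sx, 1), -1); sy <- pmax(pmin(sy, 1), -1)
    upd <- active
    xi[upd] <- xi[upd] + sx[upd]
    yi[upd] <- yi[upd] + sy[upd]
    conv <- active & sqrt(sx^2 + sy^2) < 1e-10
    active <- active & !conv
  }
  out <- cbind(xi, yi)
  # Newton converges only linearly (or not at all) on multiplicity-2 zeros:
  # route candidates with a singular Jacobian or a non-vanishing residual to
  # the quadratic |z|-surface fit
  resid <- Mod(bilinear(z, xi, yi))
  ic <- pmin(pmax(round(xi), 2), n - 1)
  jc <- pmin(pmax(round(yi), 2), m - 1)
  grad <- sqrt(Mod((z[cbind(ic + 1, jc)] - z[cbind(ic - 1, jc)]) / 2)^2 +
                 Mod((z[cbind(ic, jc + 1)] - z[cbind(ic, jc - 1)]) / 2)^2)
  # a converged simple zero has residual far below the local per-pixel
  # variation; anything else (multiplicity-2) gets the quadratic fit
  bad <- singular | resid > 0.02 * grad
  for (r in which(bad)) {
    out[r, ] <- centroid_zero(z, pmin(pmax(round(out[r, 1]), 3), n - 2),
                              pmin(pmax(round(out[r, 2]), 3), m - 2))
  }
  # discard candidates that wandered off their loop
  off <- abs(out[, 1] - i0) > 2.5 | abs(out[, 2] - j0) > 2.5
  out[off, ] <- NA_real_
  out
}

# multiplicity-2 zeros: |z| is locally a homogeneous quadratic cone, so the
# minimum of a quadratic surface fitted to |z| on a 5x5 patch localizes the
# zero to well below a pixel
centroid_zero <- function(z, ic, jc) {
  n <- nrow(z); m <- ncol(z)
  ii <- max(2, ic - 2):min(n - 1, ic + 2)
  jj <- max(2, jc - 2):min(m - 1, jc + 2)
  sub <- Mod(z[ii, jj, drop = FALSE])
  X <- as.vector(outer(ii - ic, rep(1, length(jj))))
  Y <- as.vector(outer(rep(1, length(ii)), jj - jc))
  M <- cbind(1, X, Y, X^2, X * Y, Y^2)
  cf <- tryCatch(qr.solve(M, as.vector(sub)), error = function(e) NULL)
  if (!is.null(cf)) {
    H <- matrix(c(2 * cf[4], cf[5], cf[5], 2 * cf[6]), 2, 2)
    if (det(H) > 1e-12 * sum(abs(H))^2) {
      p <- solve(H, -c(cf[2], cf[3]))
      if (max(abs(p)) <= 2) return(c(ic + p[1], jc + p[2]))
    }
  }
  w <- 1 / (as.vector(sub)^2 + 1e-12 * max(sub)^2)
  c(sum((X + ic) * w) / sum(w), sum((Y + jc) * w) / sum(w))
}

# winding numbers for many zeros at once (rows) from a sampling circle
loop_windings <- function(z, xi, yi, radius = 2, n_samp = 32) {
  np <- length(xi)
  phi <- (seq_len(n_samp) - 1) * 2 * pi / n_samp
  px <- outer(xi, radius * cos(phi), "+")
  py <- outer(yi, radius * sin(phi), "+")
  a <- matrix(Arg(bilinear(z, as.vector(px), as.vector(py))), np, n_samp)
  d <- wrap_pi(cbind(a[, -1, drop = FALSE], a[, 1, drop = FALSE]) - a)
  tot <- rowSums(d) / (2 * pi)
  w <- round(tot)
  list(winding = w,
       confidence = ifelse(abs(tot - w) > 0.25, 0.5, 1))
}

#' Pinwheel density
#'
#' Number of pinwheels per squared column spacing,
#' \eqn{\rho = \sum_i w_i / (A / \Lambda^2)} with counting weight
#' \eqn{w_i = 2|q_i|} so that a degenerate charge-magnitude-1 pinwheel
#' counts as two.
#'
#' @param set a [pinwheel_set()] with its `lambda` set.
#' @return the density \eqn{\rho}.
#' @export
pinwheel_density <- function(set) {
  lam <- pw_lambda(set)
  if (!is.finite(lam) || lam <= 0) {
    stop("column spacing lambda is not set on this pinwheel set",
         call. = FALSE)
  }
  area <- extent_area(pw_region(set))
  if (area <= 0) stop("empty analysis region", call. = FALSE)
  sum(2 * abs(set$charge)) / (area / lam^2)
}

#' Pinwheel-density variability over subregion area
#'
#' Standard deviation of pinwheel-density estimates in randomly placed
#' circular subregions of area `A` (in units of \eqn{\Lambda^2}), and the
#' power-law fit \eqn{SD(A) = c\rho A^{-\gamma}}.
#'
#' @param set a [pinwheel_set()] with `lambda` set.
#' @param areas subregion areas in units of \eqn{\Lambda^2}.
#' @param n_samples circular subregions per area (a warning is raised below
#'   30).
#' @param seed optional integer seed for the subregion placement.
#' @return list with `curve` (data.frame `A`, `sd`), `gamma`, `c` and
#'   `rho`.
#' @export
density_variability <- function(set, areas = exp(seq(log(1), log(64),
                                                     length.out = 12)),
                                n_samples = 100, seed = NULL) {
  lam <- pw_lambda(set)
  stopifnot(is.finite(lam), lam > 0)
  if (n_samples < 30) warning("fewer than 30 subregion samples; SD estimates will be noisy")
  reg <- pw_region(set)
  area_tot <- extent_area(reg) / lam^2
  if (max(areas) > area_tot / 4) {
    stop("largest subregion area exceeds a quarter of the analysis region",
         call. = FALSE)
  }
  w <- 2 * abs(set$charge)
  sds <- with_seed(seed, vapply(areas, function(A) {
    R <- lam * sqrt(A / pi)
    cx <- runif(n_samples, reg[1] + R, reg[2] - R)
    cy <- runif(n_samples, reg[3] + R, reg[4] - R)
    dens <- vapply(seq_len(n_samples), function(s) {
      inside <- (set$x - cx[s])^2 + (set$y - cy[s])^2 <= R^2
      sum(w[inside]) / A
    }, 0)
    sd(dens)
  }, 0))
  fit <- lm(log(sds) ~ log(areas))
  rho <- pinwheel_density(set)
  list(curve = data.frame(A = areas, sd = sds),
       gamma = -unname(coef(fit)[2]),
       c = exp(unname(coef(fit)[1])) / rho,
       rho = rho)
}

#' Nearest-neighbour pinwheel distances
#'
#' Distance from each pinwheel to its nearest neighbour of arbitrary, equal
#' or opposite topological charge, in units of the column spacing.
#'
#' @param set a [pinwheel_set()] with `lambda` set.
#' @param mode neighbour class.
#' @param breaks histogram bin edges (units of \eqn{\Lambda}).
#' @return list with `d` (distances, units of \eqn{\Lambda}) and `hist`
#'   (data.frame `mid`, `count`, `density`).
#' @export
nn_distances <- function(set, mode = c("any", "same", "opposite"),
                         breaks = seq(0, 1.5, by = 0.05)) {
  mode <- match.arg(mode)
  lam <- pw_lambda(set)
  stopifnot(is.finite(lam), lam > 0)
  n <- nrow(set)
  if (n < 2) stop("need at least two pinwheels", call. = FALSE)
  sgn <- sign(set$charge)
  if (mode != "any" && (!any(sgn > 0) || !any(sgn < 0))) {
    stop("need pinwheels of both signs for charge-resolved distances",
         call. = FALSE)
  }
  d2 <- outer(set$x, set$x, "-")^2 + outer(set$y, set$y, "-")^2
  diag(d2) <- Inf
  mask <- switch(mode,
                 any = matrix(TRUE, n, n),
                 same = outer(sgn, sgn, "=="),
                 opposite = outer(sgn, sgn, "!="))
  d2[!mask] <- Inf
  d <- sqrt(apply(d2, 1, min)) / lam
  d <- d[is.finite(d)]
  h <- graphics::hist(pmin(d, max(breaks)), breaks = breaks, plot = FALSE)
  list(d = d,
       hist = data.frame(mid = h$mids, count = h$counts,
                         density = h$counts / sum(h$counts) /
                           diff(breaks)[1]))
}

#' Circular difference between two orientation layouts
#'
#' \eqn{d(x) = \tfrac12 |\arg e^{2i(\vartheta_1 - \vartheta_2)}|} in
#' degrees, ranging over \eqn{[0^\circ, 90^\circ]}.
#'
#' @param map1,map2 [tuning_map()]s on the same grid.
#' @param threshold_deg threshold for the reported exceedance fraction.
#' @return list with `d_deg` (matrix), `fraction_above` and `hist`.
#' @export
circular_difference <- function(map1, map2, threshold_deg = 45) {
  stopifnot(inherits(map1, "tuning_map"), inherits(map2, "tuning_map"))
  if (!all(dim(map1$z) == dim(map2$z))) {
    stop("maps are not on the same grid", call. = FALSE)
  }
  th1 <- map_theta(map1); th2 <- map_theta(map2)
  d <- 0.5 * abs(Arg(exp(2i * (th1 - th2)))) * 180 / pi
  ok <- map1$valid & map2$valid & !is.na(d)
  h <- graphics::hist(d[ok], breaks = seq(0, 90, by = 2.5), plot = FALSE)
  list(d_deg = d, fraction_above = mean(d[ok] > threshold_deg),
       hist = data.frame(mid = h$mids, count = h$counts))
}

#' Cross-correlation between two orientation layouts
#'
#' Default (`"complex"`): Pearson correlation of the concatenated real and
#' imaginary parts of the mean-removed unit-modulus fields
#' \eqn{z = e^{2i\vartheta}} over jointly valid pixels.  `"circular"`: the
#' Fisher--Lee circular correlation coefficient of the doubled angles.
#'
#' @param map1,map2 [tuning_map()]s on the same grid.
#' @param method correlation definition.
#' @return a coefficient in \eqn{[-1, 1]}.
#' @export
map_cross_correlation <- function(map1, map2,
                                  method = c("complex", "circular")) {
  method <- match.arg(method)
  stopifnot(inherits(map1, "tuning_map"), inherits(map2, "tuning_map"))
  if (!all(dim(map1$z) == dim(map2$z))) {
    stop("maps are not on the same grid", call. = FALSE)
  }
  th1 <- map_theta(map1); th2 <- map_theta(map2)
  ok <- map1$valid & map2$valid & !is.na(th1) & !is.na(th2)
  if (sum(ok) < 3) stop("too few jointly valid pixels", call. = FALSE)
  if (method == "complex") {
    z1 <- exp(2i * th1[ok]); z2 <- exp(2i * th2[ok])
    z1 <- z1 - mean(z1); z2 <- z2 - mean(z2)
    v1 <- c(Re(z1), Im(z1)); v2 <- c(Re(z2), Im(z2))
    if (sd(v1) == 0 || sd(v2) == 0) {
      stop("constant map: correlation undefined", call. = FALSE)
    }
    stats::cor(v1, v2)
  } else {
    a <- 2 * th1[ok]; b <- 2 * th2[ok]
    num <- sum(sin(a - mean_circular(a)) * sin(b - mean_circular(b)))
    den <- sqrt(sum(sin(a - mean_circular(a))^2) *
                  sum(sin(b - mean_circular(b))^2))
    if (den == 0) stop("constant map: correlation undefined", call. = FALSE)
    num / den
  }
}

mean_circular <- function(a) Arg(mean(exp(1i * a)))

#' Common-design layout statistics of a pinwheel set
#'
#' The six layout parameters used to characterize the species-invariant
#' pinwheel arrangement: density \eqn{\rho}, mean nearest-neighbour
#' distances (any / same / opposite charge, units of \eqn{\Lambda}),
#' variability exponent \eqn{\gamma} and variability coefficient `c`.
#'
#' @param set a [pinwheel_set()] with `lambda` set.
#' @param areas,n_samples,seed passed to [density_variability()].
#' @return a `common_design_stats` list.
#' @export
compute_common_design_stats <- function(set,
                                        areas = exp(seq(log(1), log(64),
                                                        length.out = 12)),
                                        n_samples = 100, seed = NULL) {
  dv <- density_variability(set, areas = areas, n_samples = n_samples,
                            seed = seed)
  out <- list(rho = dv$rho,
              nn_any = mean(nn_distances(set, "any")$d),
              nn_same = mean(nn_distances(set, "same")$d),
              nn_opposite = mean(nn_distances(set, "opposite")$d),
              gamma = dv$gamma,
              c = dv$c)
  class(out) <- "common_design_stats"
  out
}

#' @export
print.common_design_stats <- function(x, ...) {
  cat(sprintf(
    "<common_design_stats> rho %.3f | NN any %.3f same %.3f opp %.3f | gamma %.3f | c %.3f\n",
    x$rho, x$nn_any, x$nn_same, x$nn_opposite, x$gamma, x$c))
  invisible(x)
}
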