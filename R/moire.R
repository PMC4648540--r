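#' Moire interference model parameters
#'
#' Geometry of the two perfectly hexagonal mosaics (ON: constant `r`,
#' rotation `alpha`; OFF: `r_prime`, `alpha_prime`) plus the wiring scales.
#' The detuning is \eqn{\beta = r'/r - 1} and the relative angle
#' \eqn{\Delta\alpha = \alpha' - \alpha}; the two must not both vanish or
#' the Moire scale diverges.
#'
#' @param r,r_prime ON / OFF lattice constants (um).
#' @param alpha,alpha_prime lattice rotations (radians).
#' @param sigma_r RGC receptive-field width (um).
#' @param sigma_s afferent sampling range (um).
#' @return a `moire_params` list with derived `beta` and `dalpha`.
#' @export
moire_params <- function(r = 170, r_prime = r, alpha = 0,
                         alpha_prime = alpha + 7 * pi / 180,
                         sigma_r = 70, sigma_s = 20) {
  stopifnot(r > 0, r_prime > 0, sigma_r > 0, sigma_s > 0)
  p <- list(r = r, r_prime = r_prime, alpha = alpha,
            alpha_prime = alpha_prime, sigma_r = sigma_r, sigma_s = sigma_s,
            beta = r_prime / r - 1, dalpha = alpha_prime - alpha)
  class(p) <- "moire_params"
  p
}

#' Moire scaling factor
#'
#' \deqn{S = (1+\beta) / \sqrt{\beta^2 + 2(1 - \cos\Delta\alpha)(1+\beta)}}
#' the distance between two vertices of the Moire superlattice in units of
#' the lattice constant `r`.
#'
#' @param beta detuning between the lattice constants (`r' = (1+beta) r`).
#' @param dalpha relative lattice angle (radians).
#' @return the scaling factor; `Inf` (with a warning) when both arguments
#'   vanish.
#' @export
moire_scaling_factor <- function(beta, dalpha) {
  denom2 <- beta^2 + 2 * (1 - cos(dalpha)) * (1 + beta)
  out <- (1 + beta) / sqrt(denom2)
  if (any(denom2 == 0)) {
    warning("degenerate Moire geometry (beta = 0 and dalpha = 0): scale diverges")
    out[denom2 == 0] <- Inf
  }
  out
}

# spatial-side lattice vectors entering the theta closed forms
lattice_evecs <- function(alpha, r) {
  list(e_r = -(pi / r) * c(cos(alpha), sin(alpha)),
       e_phi = -(pi / (sqrt(3) * r)) * c(-sin(alpha), cos(alpha)))
}

#' Moire geometry: critical wavenumber and column spacing
#'
#' The six dominant Fourier modes of the orientation-domain layout share the
#' wavenumber \deqn{k_c = \frac{4\pi}{\sqrt3\, r r'}
#' \sqrt{r^2 + r'^2 - 2 r r' \cos\Delta\alpha},} equivalently
#' \eqn{\Lambda_c = 2\pi/k_c = (\sqrt3/2)\, S\, r}.
#'
#' @param params a [moire_params()] object.
#' @return list with `k_c` (rad/um), `Lambda_c` (um) and `S`.
#' @export
moire_geometry <- function(params) {
  stopifnot(inherits(params, "moire_params"))
  r <- params$r; rp <- params$r_prime; da <- params$dalpha
  S <- moire_scaling_factor(params$beta, da)
  k_c <- (4 * pi / (sqrt(3) * r * rp)) *
    sqrt(r^2 + rp^2 - 2 * r * rp * cos(da))
  list(k_c = k_c, Lambda_c = 2 * pi / k_c, S = S)
}

# one hexagonal sublattice of the closed-form receptive field:
# T * (Theta3(b e_phi, tau) Theta3(b e_r, kappa) + Theta4 Theta4)
analytic_rf_sublattice <- function(bx, by, d2, alpha, r, sigma_r, sigma_s) {
  st2 <- sigma_r^2 * sigma_s^2 / (sigma_r^2 + sigma_s^2)  # merged width^2
  ev <- lattice_evecs(alpha, r)
  z_r <- bx * ev$e_r[1] + by * ev$e_r[2]
  z_phi <- bx * ev$e_phi[1] + by * ev$e_phi[2]
  tau <- exp(-2 * pi^2 * st2 / (3 * r^2))
  kap <- exp(-2 * pi^2 * st2 / r^2)
  Tfac <- (2 * pi * st2 / (sqrt(3) * r^2)) *
    exp(-d2 / (2 * (sigma_r^2 + sigma_s^2)))
  Tfac * Re(theta3(z_phi, tau) * theta3(z_r, kap) +
              theta4(z_phi, tau) * theta4(z_r, kap))
}

#' Closed-form cortical receptive field on perfect hexagonal mosaics
#'
#' Evaluates the Jacobi-theta-function expression for the receptive field of
#' a cortical unit at position `y`, i.e. the infinite Gaussian lattice sum
#' for the ON sublattice minus the OFF sublattice.  Agrees with the
#' brute-force finite lattice sum ([cortical_rf()]) to near machine
#' precision for interior positions.
#'
#' @param y cortical/retinal unit position, length-2 (um).
#' @param xg,yg grid coordinates (um) at which to evaluate the field.
#' @param params a [moire_params()] object.
#' @return a `receptive_field` (see [cortical_rf()]) with values indexed
#'   `[i, j]` for `xg[i]`, `yg[j]`.
#' @export
analytic_rf <- function(y, xg, yg, params) {
  stopifnot(inherits(params, "moire_params"), length(y) == 2L)
  X <- outer(xg, rep(1, length(yg)))
  Y <- outer(rep(1, length(xg)), yg)
  sr2 <- params$sigma_r^2; ss2 <- params$sigma_s^2
  bx <- (X * ss2 + y[1] * sr2) / (sr2 + ss2)
  by <- (Y * ss2 + y[2] * sr2) / (sr2 + ss2)
  d2 <- (X - y[1])^2 + (Y - y[2])^2
  vals <- analytic_rf_sublattice(bx, by, d2, params$alpha, params$r,
                                 params$sigma_r, params$sigma_s) -
    analytic_rf_sublattice(bx, by, d2, params$alpha_prime, params$r_prime,
                           params$sigma_r, params$sigma_s)
  receptive_field(vals, xg, yg, center = y,
                  params = list(sigma_r = params$sigma_r,
                                sigma_s = params$sigma_s,
                                source = "analytic"))
}

# Fourier-side closed form for one sublattice, vectorized over wavevectors.
# Convention: R(k) = (1/2pi) int RF(x) exp(-i k.x) d^2x.
analytic_spectrum_sublattice <- function(y, kx, ky, alpha, r,
                                         sigma_r, sigma_s) {
  ss2 <- sigma_s^2
  ev <- lattice_evecs(alpha, r)
  cx <- complex(real = y[1], imaginary = -ss2 * kx)
  cy <- complex(real = y[2], imaginary = -ss2 * ky)
  z_r <- cx * ev$e_r[1] + cy * ev$e_r[2]
  z_phi <- cx * ev$e_phi[1] + cy * ev$e_phi[2]
  nu <- exp(-2 * pi^2 * ss2 / (3 * r^2))
  zeta <- exp(-2 * pi^2 * ss2 / r^2)
  k2 <- kx^2 + ky^2
  U <- (2 * pi * sigma_r^2 * ss2 / (sqrt(3) * r^2)) *
    exp(complex(imaginary = -(kx * y[1] + ky * y[2]))) *
    exp(-k2 * (ss2 + sigma_r^2) / 2)
  U * (theta3(z_phi, nu) * theta3(z_r, zeta) +
         theta4(z_phi, nu) * theta4(z_r, zeta))
}

#' Closed-form receptive-field spectrum
#'
#' Fourier transform \eqn{R_y(k) = (2\pi)^{-1}\int RF_y(x) e^{-i k x} d^2x}
#' of the closed-form receptive field, ON minus OFF sublattice, evaluated
#' at arbitrary wavevectors.
#'
#' @param y unit position (um).
#' @param kx,ky wavevector components (rad/um), vectors of equal length (or
#'   matrices).
#' @param params a [moire_params()] object.
#' @return complex values of the spectrum, same shape as `kx`.
#' @export
analytic_spectrum <- function(y, kx, ky, params) {
  stopifnot(inherits(params, "moire_params"), length(y) == 2L)
  out <- analytic_spectrum_sublattice(y, kx, ky, params$alpha, params$r,
                                      params$sigma_r, params$sigma_s) -
    analytic_spectrum_sublattice(y, kx, ky, params$alpha_prime,
                                 params$r_prime, params$sigma_r,
                                 params$sigma_s)
  if (is.matrix(kx)) out <- matrix(out, nrow(kx), ncol(kx))
  out
}

# the non-rotationally-symmetric spectral factor G_y(k): theta products with
# the Fourier-side nomes, ON minus OFF, weighted by the 1/r^2 lattice
# densities (the Gaussian envelope is factored out)
spectral_G <- function(y1, y2, kx, ky, params) {
  g_one <- function(alpha, r) {
    ss2 <- params$sigma_s^2
    ev <- lattice_evecs(alpha, r)
    cx <- complex(real = y1, imaginary = -ss2 * kx)
    cy <- complex(real = y2, imaginary = -ss2 * ky)
    z_r <- cx * ev$e_r[1] + cy * ev$e_r[2]
    z_phi <- cx * ev$e_phi[1] + cy * ev$e_phi[2]
    nu <- exp(-2 * pi^2 * ss2 / (3 * r^2))
    zeta <- exp(-2 * pi^2 * ss2 / r^2)
    (theta3(z_phi, nu) * theta3(z_r, zeta) +
       theta4(z_phi, nu) * theta4(z_r, zeta)) / r^2
  }
  g_one(params$alpha, params$r) -
    g_one(params$alpha_prime, params$r_prime)
}

#' Hessian (closed-form) orientation layout
#'
#' Preferred orientation from the quadratic expansion of the
#' receptive-field power spectrum around \eqn{k = 0}: the direction of
#' largest increase of \eqn{|G_y(k)|^2}, i.e. the leading eigenvector of its
#' Hessian \eqn{H_y}.  This is the analytic expression for the unfiltered
#' orientation-domain layout of the Moire interference model.
#'
#' @param xg,yg cortical grid coordinates (um).
#' @param params a [moire_params()] object.
#' @param h_frac finite-difference step for the Hessian, as a fraction of
#'   the Moire wavenumber `k_c`.
#' @return list with matrices `theta` (preferred orientation in
#'   \eqn{[0,\pi)}), `a`, `b`, `c` (Hessian entries) and `z`
#'   (\eqn{e^{2i\theta}} with unit modulus, `NA` at isotropic/degenerate
#'   points), indexed `[i, j]` for `xg[i]`, `yg[j]`.
#' @export
hessian_orientation_map <- function(xg, yg, params, h_frac = 0.05) {
  stopifnot(inherits(params, "moire_params"))
  h <- h_frac * moire_geometry(params)$k_c
  Y1 <- as.vector(outer(xg, rep(1, length(yg))))
  Y2 <- as.vector(outer(rep(1, length(xg)), yg))
  G2 <- function(k1, k2) {
    Mod(spectral_G(Y1, Y2, k1, k2, params))^2
  }
  gpp <- G2(h, 0); gmm <- G2(-h, 0)
  g0 <- G2(0, 0)
  a <- (gpp - 2 * g0 + gmm) / h^2
  gpp <- G2(0, h); gmm <- G2(0, -h)
  cc <- (gpp - 2 * g0 + gmm) / h^2
  b <- (G2(h, h) - G2(h, -h) - G2(-h, h) + G2(-h, -h)) / (4 * h^2)
  # direction of largest spectral increase, rotated to the preferred-edge
  # convention used throughout the map containers
  theta <- fold_orientation(0.5 * atan2(2 * b, a - cc) + pi / 2)
  degen <- (abs(b) < 1e-12 * abs(g0)) & (abs(a - cc) < 1e-12 * abs(g0))
  theta[degen] <- NA_real_
  dims <- c(length(xg), length(yg))
  list(theta = matrix(theta, dims[1], dims[2]),
       a = matrix(a, dims[1], dims[2]),
       b = matrix(b, dims[1], dims[2]),
       c = matrix(cc, dims[1], dims[2]),
       z = matrix(exp(2i * theta), dims[1], dims[2]))
}

#' Orientation maximizing the quadratic form (explicit branch formula)
#'
#' Direct evaluation of \eqn{\vartheta_{pref} = \arctan[(\sqrt{(a-c)^2 +
#' 4b^2} - a + c) / (2b)]} with the \eqn{b \to 0} limit special-cased;
#' equivalent to the eigenvector form used by [hessian_orientation_map()].
#'
#' @param a,b,c Hessian entries.
#' @return orientation in \eqn{[0, \pi)}; `NA` for the isotropic case.
#' @export
hessian_theta_formula <- function(a, b, c) {
  out <- ifelse(
    b == 0,
    ifelse(a > c, 0, ifelse(a < c, pi / 2, NA_real_)),
    atan((sqrt((a - c)^2 + 4 * b^2) - a + c) / (2 * b))
  )
  fold_orientation(out)
}

#' Six-planar-wave (lowest spatial frequency) layout
#'
#' The smoothed orientation-domain layout of the Moire interference model:
#' \eqn{z(y) = \sum_{j=1}^{6} u_j e^{i k_j y}} over the six modes of
#' magnitude \eqn{k_c}, with phase factors built from the unit-modulus
#' constant \eqn{u_0}.  The \eqn{\sqrt3 k_c} modes are excluded (their phase
#' factors are not determined).
#'
#' @param params a [moire_params()] object.
#' @return list with `k` (3 x 2 matrix of the three independent
#'   wavevectors; the other three are their negatives), `u` (their phase
#'   factors), `u0`, and `k_c`.
#' @export
six_mode_field <- function(params) {
  stopifnot(inherits(params, "moire_params"))
  on <- lattice_evecs(params$alpha, params$r)
  off <- lattice_evecs(params$alpha_prime, params$r_prime)
  der <- on$e_r - off$e_r
  dephi <- on$e_phi - off$e_phi
  k <- rbind(2 * (der + dephi),   # u0 exp(i 4pi/3)
             2 * (der - dephi),   # u0 exp(i 2pi/3)
             4 * dephi)           # u0
  a <- params$alpha; ap <- params$alpha_prime
  r <- params$r; rp <- params$r_prime
  u0 <- exp(1i * (a + ap)) * (exp(1i * ap) * r + exp(1i * a) * rp) /
    (exp(1i * a) * r + exp(1i * ap) * rp)
  u <- u0 * exp(1i * c(4 * pi / 3, 2 * pi / 3, 0))
  # real-space superlattice basis: A solves k_{1,2} . A_j = 2 pi delta_ij
  A <- 2 * pi * solve(k[1:2, ])
  list(k = k, u = u, u0 = u0, k_c = sqrt(rowSums(k^2)), A = A)
}

#' Evaluate the six-mode layout on a grid
#'
#' @param xg,yg grid coordinates (um).
#' @param params a [moire_params()] object.
#' @param rotate evaluate the field in coordinates rotated by this angle
#'   (radians), i.e. at \eqn{\Omega(rotate)\,y}; useful for aligning the
#'   Moire superlattice with the grid axes.
#' @return a `tuning_map` (stage `"analytic_sixmode"`) whose `z` field is
#'   the raw six-mode sum; preferred orientation is \eqn{\arg(z)/2}.
#' @export
six_mode_map <- function(xg, yg, params, rotate = 0) {
  sm <- six_mode_field(params)
  X <- outer(xg, rep(1, length(yg)))
  Y <- outer(rep(1, length(xg)), yg)
  kv <- sm$k %*% rot2(rotate)  # k . (R y) = (R^T k) . y
  z <- matrix(0i, length(xg), length(yg))
  for (j in 1:3) {
    phase <- kv[j, 1] * X + kv[j, 2] * Y
    z <- z + 2 * sm$u[j] * cos(phase)  # e^{ik.y} + e^{-ik.y}
  }
  px_um <- if (length(xg) > 1) xg[2] - xg[1] else 1
  # same preferred-edge orientation convention as the numerical maps
  # (a global sign on z, i.e. a 90 degree shift of theta = arg(z)/2)
  tuning_map(z = -z, px_mm = px_um / 1000, stage = "analytic_sixmode",
             params = list(moire = unclass(params)))
}

#' Pinwheel density of the six-mode layout, measured on the map
#'
#' Evaluates the six-mode field over a window commensurate with its Moire
#' superlattice (grid axes aligned with a superlattice vector, the counting
#' region an exact integer number of unit cells), detects the phase
#' singularities and returns the density per \eqn{\Lambda_c^2} with
#' multiplicity-2 zeros counted twice.  For the perfect layout this is
#' \eqn{2\sqrt3} up to detection error.
#'
#' @param params a [moire_params()] object.
#' @param cells_x,cells_y counting region size in superlattice cells
#'   (columns of width \eqn{a} and rows of height \eqn{\sqrt3 a}, two cells
#'   per rectangle, \eqn{a = 2\Lambda_c/\sqrt3}).
#' @param px_per_lambda grid resolution.
#' @return list with `rho`, the [pinwheel_set()] and the exact cell count.
#' @export
sixmode_layout_density <- function(params = moire_params(), cells_x = 6,
                                   cells_y = 4, px_per_lambda = 96) {
  geo <- moire_geometry(params)
  lam <- geo$Lambda_c
  a <- 2 * lam / sqrt(3)
  px <- lam / px_per_lambda
  sm <- six_mode_field(params)
  rot <- atan2(sm$A[2, 2], sm$A[1, 2])  # align A2 with the x axis
  wx <- cells_x * a; wy <- cells_y * sqrt(3) * a
  nx <- ceiling((wx + lam) / px); ny <- ceiling((wy + lam) / px)
  bx <- (nx * px - wx) / 2; by <- (ny * px - wy) / 2
  # generic offset keeps singularities off the counting-region boundary
  off <- c(0.217, 0.143) * a
  xg <- off[1] + (seq_len(nx) - 0.5) * px
  yg <- off[2] + (seq_len(ny) - 0.5) * px
  map <- six_mode_map(xg, yg, params, rotate = rot)
  pw <- find_pinwheels(map, lambda_mm = lam / 1000)
  reg <- attr(pw, "region")  # mm; margins computed in um
  ins <- c(reg[1] + bx / 1000, reg[2] - bx / 1000,
           reg[3] + by / 1000, reg[4] - by / 1000)
  keep <- pw$x >= ins[1] & pw$x <= ins[2] & pw$y >= ins[3] & pw$y <= ins[4]
  set <- pinwheel_set(pw$x[keep], pw$y[keep], pw$charge[keep],
                      pw$degenerate[keep], region = ins,
                      lambda = lam / 1000)
  list(rho = pinwheel_density(set), set = set,
       n_cells = 2 * cells_x * cells_y)
}

#' Crystalline pinwheel point pattern of the six-mode layout
#'
#' The pinwheels of the perfect six-mode layout form a hexagonal
#' superlattice: one charge-1 (multiplicity-2, counted twice) pinwheel at
#' each superlattice site and two charge \eqn{-1/2} pinwheels at the two
#' triangle centres of each unit cell.  Used for the crystalline
#' density-variability benchmark.
#'
#' @param n_cells approximate number of superlattice cells per axis.
#' @param lambda column spacing \eqn{\Lambda_c} (any length unit).
#' @return a [pinwheel_set()] over a square region of side about
#'   `n_cells * a` where \eqn{a = 2\Lambda/\sqrt3} is the superlattice
#'   constant.
#' @export
crystalline_pinwheels <- function(n_cells = 30, lambda = 1) {
  a <- 2 * lambda / sqrt(3)
  side <- n_cells * a
  lmax <- ceiling(n_cells / (sqrt(3) / 2)) + 2
  kl <- expand.grid(k = (-ceiling(lmax / 2) - 2):(n_cells + 2), l = -2:lmax)
  sx <- (kl$k + kl$l / 2) * a
  sy <- kl$l * (sqrt(3) / 2) * a
  # triangle centres at (a1 + a2)/3 and 2 (a1 + a2)/3 relative to each site
  cx1 <- sx + (a + a / 2) / 3; cy1 <- sy + (sqrt(3) / 2 * a) / 3
  cx2 <- sx + 2 * (a + a / 2) / 3; cy2 <- sy + 2 * (sqrt(3) / 2 * a) / 3
  x <- c(sx, cx1, cx2)
  y <- c(sy, cy1, cy2)
  charge <- rep(c(1, -0.5, -0.5), each = length(sx))
  keep <- x >= 0 & x <= side & y >= 0 & y <= side
  pinwheel_set(x = x[keep], y = y[keep], charge = charge[keep],
               degenerate = charge[keep] == 1,
               region = c(0, side, 0, side), lambda = lambda)
}
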