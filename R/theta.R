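#' Jacobi theta functions
#'
#' Third and fourth Jacobi theta functions evaluated by their defining
#' series, \deqn{\Theta_3(z, q) = 1 + 2\sum_{n\ge1} q^{n^2}\cos(2nz), \qquad
#' \Theta_4(z, q) = 1 + 2\sum_{n\ge1} (-1)^n q^{n^2}\cos(2nz),} truncated
#' once the remaining terms are below `tol` in magnitude.  The argument may
#' be complex (as needed for the Fourier-side receptive-field closed forms,
#' where the theta argument acquires an imaginary part proportional to the
#' wavenumber); the nome must satisfy \eqn{0 \le q < 1} for convergence.
#'
#' @param z complex (or numeric) vector of arguments.
#' @param q nome, a single number in \eqn{[0, 1)}.
#' @param tol truncation tolerance for the series remainder.
#' @return complex vector of the same length as `z` (numeric input with a
#'   real nome yields numerically real output with zero imaginary part).
#' @examples
#' theta3(0.3, 0.1)
#' theta4(0, 0.1)  # 1 - 2 q + 2 q^4 - ...
#' @export
theta3 <- function(z, q, tol = 1e-15) {
  theta_series(z, q, alternate = FALSE, tol = tol)
}

#' @rdname theta3
#' @export
theta4 <- function(z, q, tol = 1e-15) {
  theta_series(z, q, alternate = TRUE, tol = tol)
}

theta_series <- function(z, q, alternate, tol) {
  stopifnot(length(q) == 1L, is.finite(q))
  if (q < 0 || q >= 1) {
    stop("theta series diverges: nome must lie in [0, 1)", call. = FALSE)
  }
  z <- as.complex(z)
  out <- rep(1 + 0i, length(z))
  if (q == 0 || length(z) == 0L) return(out)
  # terms are q^{n^2} cos(2nz); with complex z they grow like exp(2n|Im z|)
  # before the q^{n^2} factor wins, so bound the remainder accordingly
  m <- max(abs(Im(z)))
  lq <- log(q)
  n <- 1L
  repeat {
    bound <- exp(n^2 * lq + 2 * n * m)
    if (bound < tol && n > 1L) break
    s <- if (alternate && n %% 2L == 1L) -2 else 2
    out <- out + s * q^(n^2) * cos(2 * n * z)
    n <- n + 1L
    if (n > 400L) {
      stop("theta series failed to converge (nome too close to 1)",
           call. = FALSE)
    }
  }
  out
}
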