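#' Reference consistency ranges for the common design
#'
#' The six pinwheel layout parameters of the species-invariant common
#' design: the ensemble (grand) average, the common-design consistency
#' range (95% bootstrap CI of the pooled data) and the one-species
#' consistency range (union of the single-species CIs).  These are
#' embedded experimental reference constants; the package does not
#' recompute them from imaging data.
#'
#' @return data.frame with one row per parameter (`rho`, `nn_any`,
#'   `nn_same`, `nn_opposite`, `gamma`, `c`) and columns `ensemble`,
#'   `cd_lo`, `cd_hi`, `os_lo`, `os_hi`.
#' @export
common_design_ranges <- function() {
  data.frame(
    parameter = c("rho", "nn_any", "nn_same", "nn_opposite", "gamma", "c"),
    ensemble = c(3.14, 0.359, 0.525, 0.396, 0.40, 1.05),
    cd_lo = c(3.09, 0.344, 0.506, 0.387, 0.37, 0.99),
    cd_hi = c(3.19, 0.357, 0.522, 0.399, 0.42, 1.11),
    os_lo = c(2.93, 0.334, 0.499, 0.366, 0.34, 0.68),
    os_hi = c(3.42, 0.381, 0.556, 0.428, 0.58, 1.19),
    stringsAsFactors = FALSE
  )
}

#' Consistency of layout statistics with the common design
#'
#' Scores each layout parameter against the embedded consistency ranges
#' (closed intervals): inside the common-design range, inside only the
#' one-species range, or outside both (`inconsistent` -- data from every
#' species rejects the layout).  The overall verdict is the weakest
#' per-parameter verdict.
#'
#' @param stats a [compute_common_design_stats()] result (or named list
#'   with the six parameters).
#' @param ranges reference ranges, by default [common_design_ranges()].
#' @return list with `per_parameter` (data.frame) and `overall`.
#' @export
assess_consistency <- function(stats, ranges = common_design_ranges()) {
  levels_ <- c("common_design", "one_species_only", "inconsistent")
  verdicts <- character(nrow(ranges))
  values <- numeric(nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    p <- ranges$parameter[i]
    v <- stats[[p]]
    if (is.null(v) || !is.finite(v)) {
      stop(sprintf("missing layout parameter '%s'", p), call. = FALSE)
    }
    values[i] <- v
    verdicts[i] <-
      if (v >= ranges$cd_lo[i] && v <= ranges$cd_hi[i]) "common_design"
      else if (v >= ranges$os_lo[i] && v <= ranges$os_hi[i]) "one_species_only"
      else "inconsistent"
  }
  list(per_parameter = data.frame(parameter = ranges$parameter,
                                  value = values, verdict = verdicts,
                                  stringsAsFactors = FALSE),
       overall = levels_[max(match(verdicts, levels_))])
}

#' Squared deviation between two (normalized) histograms
#'
#' Both histograms are normalized to unit mass and compared bin by bin:
#' \eqn{\sum_b (p_b - q_b)^2}.  Binning must agree.
#'
#' @param model_hist,reference_hist data.frames with columns `mid` and
#'   `count` (as produced by [nn_distances()]).
#' @return a scalar deviation.
#' @export
squared_histogram_deviation <- function(model_hist, reference_hist) {
  if (nrow(model_hist) != nrow(reference_hist) ||
      max(abs(model_hist$mid - reference_hist$mid)) > 1e-9) {
    stop("histogram binning mismatch", call. = FALSE)
  }
  p <- model_hist$count / sum(model_hist$count)
  q <- reference_hist$count / sum(reference_hist$count)
  sum((p - q)^2)
}

#' Full layout pipeline for one disordered hexagonal mosaic realization
#'
#' Generates a hexagonal ON/OFF Moire mosaic with the requested disorder,
#' computes the unfiltered wiring-model map, thresholds and smooths it,
#' estimates the column spacing by wavelet analysis, detects pinwheels and
#' returns the common-design statistics.
#'
#' @param eta disorder strength (units of the lattice constant).
#' @param sigma_corr correlation length in lattice constants (`NULL` for
#'   uncorrelated jitter).
#' @param params a [moire_params()] object (lattice + wiring scales).
#' @param n_lambda cortical window side in units of \eqn{\Lambda_c}.
#' @param px_per_lambda grid resolution (pixels per \eqn{\Lambda_c}).
#' @param osi_threshold,smooth_sd_lambda thresholding / smoothing settings
#'   (kernel SD in units of \eqn{\Lambda_c}).
#' @param lambda_mode `"wavelet"` (measured spacing, as for experimental
#'   layouts) or `"moire"` (theoretical \eqn{\Lambda_c}).
#' @param seed integer seed.
#' @param keep_maps return the maps alongside the statistics.
#' @return list with `stats` ([compute_common_design_stats()]),
#'   `lambda_mm`, `n_pinwheels`, `pinwheels`, and optionally `maps`.
#' @export
moire_layout_realization <- function(eta = 0, sigma_corr = NULL,
                                     params = moire_params(),
                                     n_lambda = 10, px_per_lambda = 48,
                                     osi_threshold = 0.25,
                                     smooth_sd_lambda = 0.15,
                                     lambda_mode = c("wavelet", "moire"),
                                     seed = NULL, keep_maps = FALSE) {
  lambda_mode <- match.arg(lambda_mode)
  geo <- moire_geometry(params)
  lam_mm <- geo$Lambda_c / 1000
  size_mm <- n_lambda * lam_mm
  n_px <- round(n_lambda * px_per_lambda)
  wp <- wiring_params(params$sigma_r, params$sigma_s)
  margin <- 4 * params$sigma_s + 3 * params$sigma_r +
    3 * params$r * max(eta, 0.1)
  ext <- c(size_mm / 2 * 1000 + margin) * c(-1, 1, -1, 1)
  on <- hexagonal_mosaic(params$r, params$alpha, ext, "ON")
  off <- hexagonal_mosaic(params$r_prime, params$alpha_prime, ext, "OFF")
  if (eta > 0) {
    if (is.null(sigma_corr)) {
      on <- apply_uncorrelated_jitter(on, eta, seed = seed)
      off <- apply_uncorrelated_jitter(off, eta,
                                       seed = if (is.null(seed)) NULL
                                       else seed + 1)
    } else {
      sig_um <- sigma_corr * params$r
      f_on <- sample_displacement_field(ext, sig_um, seed = seed)
      f_off <- sample_displacement_field(ext, sig_um,
                                         seed = if (is.null(seed)) NULL
                                         else seed + 1)
      on <- apply_correlated_jitter(on, eta, f_on)
      off <- apply_correlated_jitter(off, eta, f_off)
    }
  }
  mosaic <- merge_mosaics(on, off)
  grid <- cortical_grid(size_mm, n_px)
  unf <- compute_unfiltered_map(mosaic, grid, wp, lambda_mm = lam_mm)
  sm <- threshold_and_smooth(unf, osi_threshold,
                             kernel_sd_mm = smooth_sd_lambda * lam_mm)
  lam_use <- if (lambda_mode == "moire") lam_mm else {
    local_column_spacing(sm, lambda_expected_mm = lam_mm,
                         coarse = TRUE)$mean_lambda_mm
  }
  pw <- find_pinwheels(sm, margin_lambda = 0.5, lambda_mm = lam_use)
  stats <- compute_common_design_stats(pw, seed = seed,
                                       areas = sdA_areas_for(pw))
  out <- list(stats = stats, lambda_mm = lam_use, n_pinwheels = nrow(pw),
              pinwheels = pw, seed = seed)
  if (keep_maps) out$maps <- list(unfiltered = unf, smoothed = sm)
  out
}

# areas for the SD(A) fit, capped to the region size (the region can be
# only a few squared spacings when the measured spacing is large)
sdA_areas_for <- function(set) {
  amax <- min(64, extent_area(pw_region(set)) / pw_lambda(set)^2 / 4.5)
  amin <- min(1, amax / 8)
  exp(seq(log(amin), log(amax), length.out = 12))
}

#' Disorder parameter sweep of the statistical wiring model
#'
#' Runs [moire_layout_realization()] over a grid of disorder strengths
#' (and, for correlated disorder, correlation lengths), with several
#' realizations per grid point, and scores every realization against the
#' common-design consistency ranges.  All randomness derives from the
#' master seed.
#'
#' @param etas disorder strengths.
#' @param sigma_corrs correlation lengths in lattice constants (`NULL` for
#'   an uncorrelated sweep).
#' @param n_real realizations per grid point.
#' @param seed master seed.
#' @param ... forwarded to [moire_layout_realization()].
#' @return a long-form data.frame with one row per realization: the six
#'   layout parameters, measured `lambda_mm`, pinwheel count, per-run seed
#'   and the overall consistency verdict.
#' @export
run_disorder_sweep <- function(etas, sigma_corrs = NULL, n_real = 5,
                               seed = 1, ...) {
  grid <- if (is.null(sigma_corrs)) {
    data.frame(eta = etas, sigma_corr = NA_real_)
  } else {
    expand.grid(eta = etas, sigma_corr = sigma_corrs)
  }
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    for (i in seq_len(n_real)) {
      run_seed <- seed + 7919L * g + 131L * i
      res <- tryCatch(
        moire_layout_realization(
          eta = grid$eta[g],
          sigma_corr = if (is.na(grid$sigma_corr[g])) NULL
                       else grid$sigma_corr[g],
          seed = run_seed, ...),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          eta = grid$eta[g], sigma_corr = grid$sigma_corr[g],
          realization = i, seed = run_seed, rho = NA, nn_any = NA,
          nn_same = NA, nn_opposite = NA, gamma = NA, c = NA,
          lambda_mm = NA, n_pinwheels = NA,
          verdict = paste("error:", conditionMessage(res)))
        next
      }
      v <- assess_consistency(res$stats)
      rows[[length(rows) + 1]] <- data.frame(
        eta = grid$eta[g], sigma_corr = grid$sigma_corr[g],
        realization = i, seed = run_seed,
        rho = res$stats$rho, nn_any = res$stats$nn_any,
        nn_same = res$stats$nn_same, nn_opposite = res$stats$nn_opposite,
        gamma = res$stats$gamma, c = res$stats$c,
        lambda_mm = res$lambda_mm, n_pinwheels = res$n_pinwheels,
        verdict = v$overall)
    }
  }
  do.call(rbind, rows)
}
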