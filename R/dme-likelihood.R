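#' Summary-statistic DME log-likelihood
#'
#' Log-likelihood of a DME parameter set given per-strain selection-coefficient
#' estimates and their standard errors. For each strain, the model density of
#' the estimated effect is the strain-effect density convolved with the
#' regularising kernel and a Gaussian with that strain's error SD; the density
#' is computed by inverse FFT and evaluated at the strain's `s_hat` by linear
#' interpolation (cubic spline optional).
#'
#' Strains sharing an error SD share one FFT, so the cost scales with the
#' number of distinct `se_s` values, not the number of strains.
#'
#' @param estimates a data frame with columns `s_hat` and `se_s` (one row per
#'   strain), e.g. from [estimate_strain_effects()].
#' @param params a [dme_params()] object.
#' @param config a [fit_config()] object.
#' @param interpolation `"linear"` (default) or `"spline"`.
#' @return the total log-likelihood (sum over strains).
#' @export
summary_loglik <- function(estimates, params, config,
                           interpolation = c("linear", "spline")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.data.frame(estimates),
            all(c("s_hat", "se_s") %in% names(estimates)))
  if (any(!is.finite(estimates$s_hat)) || any(estimates$se_s <= 0))
    stop("estimates must have finite 's_hat' and positive 'se_s'",
         call. = FALSE)
  half <- config$grid_span / 2
  if (any(abs(estimates$s_hat) >= half))
    stop("'s_hat' outside the density grid span; widen 'grid_span'",
         call. = FALSE)
  ll <- 0
  for (se in unique(estimates$se_s)) {
    dens <- dme_pdf(params, config, error_sd = se)
    sh <- estimates$s_hat[estimates$se_s == se]
    fx <- if (interpolation == "linear") {
      stats::approx(dens$s_values, dens$density, xout = sh)$y
    } else {
      pmax(stats::spline(dens$s_values, dens$density, xout = sh)$y, 0)
    }
    if (any(!is.finite(fx) | fx <= 0)) return(-Inf)
    ll <- ll + sum(log(fx))
  }
  ll
}

#' Full colony-data DME log-likelihood
#'
#' Joint log-likelihood of a DME parameter set given the raw within-field
#' MA-minus-reference growth-rate differences, integrating over each strain's
#' latent net mutational effect `S`. For strain `i` with differences
#' `D_1..D_v` the contribution is
#' `log integral f_S(s) * prod_j mixture(D_j; mu_anc (1 + s), rho_i) ds`,
#' where `f_S` is the kernel-smoothed effect density (no per-strain error
#' term: measurement noise enters through the mixture components) and the
#' mixture is the four-component pairwise-difference density of
#' [diff_loglik()].
#'
#' The integral is evaluated on the FFT grid nodes restricted to the support
#' of `f_S`, with the per-strain product accumulated in log space and
#' exponentiated only after subtracting its maximum (log-sum-exp trapezoid
#' quadrature), so ~500-term products cannot underflow.
#'
#' @param diffs a data frame of growth differences with columns `strain_id`
#'   and `d_value`, e.g. from [pair_colonies()].
#' @param params a [dme_params()] object.
#' @param general a [general_params()] object.
#' @param rho named numeric vector of per-strain petite proportions (names =
#'   strain ids present in `diffs`).
#' @param config a [fit_config()] object.
#' @param support_mass the integration range keeps grid nodes covering all but
#'   this much of the `f_S` probability mass at each end (default `1e-12`).
#' @return the total log-likelihood (sum over strains of log integrals).
#' @export
full_data_loglik <- function(diffs, params, general, rho, config,
                             support_mass = 1e-12) {
  stopifnot(is.data.frame(diffs),
            all(c("strain_id", "d_value") %in% names(diffs)))
  ids <- unique(as.character(diffs$strain_id))
  if (!all(ids %in% names(rho)))
    stop("'rho' must supply a petite proportion for every strain in 'diffs'",
         call. = FALSE)
  # kernel-only density: ringing up to ~1e-3 of the peak is expected at the
  # default kernel width and is clipped + renormalised below
  dens <- dme_pdf(params, config, error_sd = 0, ringing_tol = 5e-3)
  cdf <- density_cdf(dens)
  keep <- which(cdf > support_mass & cdf < max(cdf) - support_mass)
  if (length(keep) < 4) keep <- which.max(dens$density) + (-2:2)
  keep <- keep[keep >= 1 & keep <= length(dens$s_values)]
  s <- dens$s_values[keep]
  f_kept <- pmax(dens$density[keep], .Machine$double.xmin)
  # trapezoid weights on the retained nodes
  w <- rep(dens$spacing, length(s))
  w[c(1, length(s))] <- dens$spacing / 2
  # renormalise on the retained support: clipping of FFT ringing can leave
  # the discrete mass a fraction of a percent away from one, which would
  # bias every per-strain integral by the same factor
  logf <- log(f_kept) - log(sum(f_kept * w))
  total <- 0
  for (id in ids) {
    d <- diffs$d_value[diffs$strain_id == id]
    # log product over this strain's differences of the mixture density,
    # as a function of s (vectorised: matrix of diffs x s-nodes)
    logprod <- colSums(diff_loglik_matrix(d, s, rho[[id]], general))
    lg <- logf + logprod + log(w)
    mx <- max(lg)
    if (!is.finite(mx)) return(-Inf)
    total <- total + mx + log(sum(exp(lg - mx)))
  }
  total
}
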