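#' Characteristic function of the reflected gamma effect distribution
#'
#' A single mutational effect Z has magnitude Gamma(shape `k`, mean `m`) and
#' positive sign with probability `q`. Its characteristic function is
#' `(1 - q) * (1 + i w m / k)^(-k) + q * (1 - i w m / k)^(-k)` (principal
#' branch).
#'
#' @param omega numeric vector of frequencies.
#' @param m gamma mean (magnitude scale, s-units); `m > 0`.
#' @param k gamma shape; `k > 0`.
#' @param q probability of a positive effect, in `[0, 1]`.
#' @return complex vector, same length as `omega`.
#' @export
cf_reflected_gamma <- function(omega, m, k, q) {
  stopifnot(is.numeric(omega), m > 0, k > 0, q >= 0, q <= 1)
  z <- complex(real = 0, imaginary = omega * m / k)
  (1 - q) * (1 + z)^(-k) + q * (1 - z)^(-k)
}

#' Characteristic function of a compound Poisson sum
#'
#' If each of N ~ Poisson(`u`) iid effects has characteristic function
#' `cf_z`, their sum has characteristic function `exp(u * (cf_z - 1))`.
#'
#' @param cf_z complex vector: the single-effect CF evaluated on the frequency
#'   grid.
#' @param u Poisson mean; `u >= 0`.
#' @return complex vector elementwise `exp(u * (cf_z - 1))`.
#' @export
cf_compound_poisson <- function(cf_z, u) {
  stopifnot(is.numeric(u), length(u) == 1L, u >= 0)
  exp(u * (cf_z - 1))
}

# Gaussian CF exp(i w mu - w^2 sd^2 / 2)
cf_gaussian <- function(omega, mu = 0, sd) {
  exp(complex(real = -omega^2 * sd^2 / 2, imaginary = omega * mu))
}

#' Characteristic function of a strain's total mutational effect
#'
#' Assembles the model-specific CF of the per-strain net effect S: a compound
#' Poisson of reflected-gamma SNM effects, optionally multiplied (i.e. the
#' effects convolved) by a second compound Poisson (`two_gamma`) or by a
#' Gaussian unidentified-mutation component (`gaussian_unid`).
#'
#' @param params a [dme_params()] object.
#' @param config a [fit_config()] object.
#' @param omega numeric vector of frequencies.
#' @return complex vector, same length as `omega`.
#' @export
cf_total <- function(params, config, omega) {
  stopifnot(inherits(params, "dme_params"), inherits(config, "dme_fit_config"))
  u_snm <- snm_poisson_mean(params, config)
  cfz <- cf_reflected_gamma(omega, params$m, params$k, params$q)
  cf <- cf_compound_poisson(cfz, u_snm)
  if (params$model == "two_gamma") {
    cfz2 <- cf_reflected_gamma(omega, params$m_unid, params$k_unid,
                               params$q_unid)
    cf <- cf * cf_compound_poisson(cfz2, params$u_unid)
  } else if (params$model == "gaussian_unid") {
    cf <- cf * cf_gaussian(omega, params$mu_unid, params$sigma_unid)
  }
  cf
}

#' Probability density of a strain's (estimated) total mutational effect
#'
#' Computes the density of the per-strain net mutational effect on a uniform
#' selection-coefficient grid by inverse FFT of the model characteristic
#' function, after multiplying by the CFs of (a) the narrow regularising
#' Gaussian kernel and (b) an optional per-strain measurement-error Gaussian
#' with SD `error_sd`. The kernel spreads the compound-Poisson atom at zero so
#' no separate discrete mass needs handling.
#'
#' @param params a [dme_params()] object.
#' @param config a [fit_config()] object; `grid_n` points spanning
#'   `[-grid_span/2, grid_span/2]`.
#' @param error_sd per-strain estimation error SD (s-units); 0 for the pure
#'   kernel-smoothed effect density.
#' @param ringing_tol warn when negative FFT ringing exceeds this fraction of
#'   the density maximum. With a smoothing scale (kernel + error SD) well
#'   above the grid spacing, ringing is at round-off level and the strict
#'   default applies; a kernel-only density at the resolution limit
#'   legitimately rings at up to ~1e-3 of its peak and callers that clip and
#'   renormalise pass a looser value.
#' @return a list of class `"dme_density"` with elements `s_values`, `density`
#'   (both length `grid_n`) and `spacing`.
#' @export
dme_pdf <- function(params, config, error_sd = 0, ringing_tol = 1e-10) {
  stopifnot(error_sd >= 0)
  n <- config$grid_n
  ds <- config$grid_span / n
  s0 <- -config$grid_span / 2
  # frequency grid in DFT order: k = 0..n-1 mapped to [0, n/2) U [-n/2, 0)
  kk <- c(seq_len(n / 2) - 1L, seq.int(-n / 2, -1L))
  omega <- 2 * pi * kk / (n * ds)
  cf <- cf_total(params, config, omega)
  cf <- cf * cf_gaussian(omega, 0, config$kernel_sd)
  if (error_sd > 0) cf <- cf * cf_gaussian(omega, 0, error_sd)
  # f(s_j) = (1/(n ds)) * sum_k cf(w_k) exp(-i w_k s0) exp(-2 pi i k j / n)
  phase <- exp(complex(real = 0, imaginary = -omega * s0))
  f <- Re(stats::fft(cf * phase)) / (n * ds)
  neg <- min(f)
  if (neg < -ringing_tol * max(f))
    warning("FFT density has negative ringing beyond tolerance: ", neg)
  f[f < 0] <- 0
  s <- s0 + ds * (seq_len(n) - 1L)
  # aliasing guard: significant mass at the grid edges means the grid span
  # does not contain the distribution
  edge <- max(f[c(1:4, (n - 3):n)]) * ds
  if (edge > 1e-4)
    stop("density mass detected at grid edges; widen 'grid_span' ",
         "or re-centre the grid", call. = FALSE)
  structure(list(s_values = s, density = f, spacing = ds),
            class = "dme_density")
}

#' Trapezoid integral of a density grid
#' @param dens a `"dme_density"` object.
#' @return the trapezoid-rule integral of `density` over `s_values`.
#' @export
density_integral <- function(dens) {
  f <- dens$density
  dens$spacing * (sum(f) - (f[1] + f[length(f)]) / 2)
}

#' Cumulative distribution on the density grid
#' @param dens a `"dme_density"` object.
#' @return numeric vector of cumulative probabilities at `s_values`.
#' @export
density_cdf <- function(dens) {
  f <- dens$density
  n <- length(f)
  c(0, cumsum((f[-1] + f[-n]) / 2)) * dens$spacing
}

#' Export a density grid as a data frame
#' @param x a `"dme_density"` object.
#' @param ... unused.
#' @return `data.frame(s, density)`.
#' @export
as.data.frame.dme_density <- function(x, ...) {
  data.frame(s = x$s_values, density = x$density)
}
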