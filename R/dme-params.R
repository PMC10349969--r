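#' Distribution-of-mutational-effects (DME) model parameters
#'
#' Construct a validated parameter set for one of the four DME model variants
#' used throughout the package. A single mutational effect is drawn from a
#' reflected gamma distribution: its magnitude is Gamma(shape `k`, mean `m`)
#' and its sign is positive with probability `q`. A strain carries a Poisson
#' number of such mutations, so the per-strain net effect is compound Poisson.
#'
#' The variants differ in how mutations missed by sequencing ("unidentified"
#' mutations, chiefly simple-sequence-repeat indels) are treated:
#' \describe{
#'   \item{`snm_only`}{Only sequenced single-nucleotide mutations (SNMs)
#'     contribute. The Poisson mean is tied to the sequenced diploid-parent
#'     mutation count: `U = (m_diploid / 2) * (1 - p0)`, where `p0` is the
#'     fitted proportion of SNMs with exactly zero effect.}
#'   \item{`single_dme`}{All mutations (identified or not) share one reflected
#'     gamma; the Poisson mean `u_free` is a free parameter.}
#'   \item{`two_gamma`}{SNMs as in `snm_only`, plus an independent compound
#'     Poisson of unidentified mutations with its own reflected gamma
#'     (`k_unid`, `m_unid`, `q_unid`) and Poisson mean `u_unid`.}
#'   \item{`gaussian_unid`}{SNMs as in `snm_only`, plus a per-strain Gaussian
#'     `N(mu_unid, sigma_unid^2)` for the combined effect of all unidentified
#'     mutations in a strain.}
#' }
#'
#' @param model one of `"snm_only"`, `"single_dme"`, `"two_gamma"`,
#'   `"gaussian_unid"`.
#' @param k,m gamma shape and mean (absolute effect magnitude, s-units) of the
#'   SNM (or shared, for `single_dme`) effect distribution.
#' @param q proportion of non-neutral SNMs with a positive growth-rate effect.
#' @param p0 proportion of SNMs with zero effect (`snm_only`, `two_gamma`,
#'   `gaussian_unid`).
#' @param u_free free Poisson mean of non-neutral mutations (`single_dme`).
#' @param k_unid,m_unid,q_unid,u_unid unidentified-mutation reflected gamma and
#'   Poisson mean (`two_gamma`).
#' @param mu_unid,sigma_unid mean and SD of the combined per-strain
#'   unidentified-mutation effect (`gaussian_unid`).
#' @return an object of class `"dme_params"`.
#' @examples
#' dme_params("gaussian_unid", k = 5.5e-2, m = 4.1e-3, q = 0.06, p0 = 0.059,
#'            mu_unid = -3.3e-3, sigma_unid = 5.5e-3)
#' @export
dme_params <- function(model = c("snm_only", "single_dme", "two_gamma",
                                 "gaussian_unid"),
                       k = NULL, m = NULL, q = NULL, p0 = NULL,
                       u_free = NULL,
                       k_unid = NULL, m_unid = NULL, q_unid = NULL,
                       u_unid = NULL,
                       mu_unid = NULL, sigma_unid = NULL) {
  model <- match.arg(model)
  chk_pos <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a positive finite number for model '%s'",
                   nm, model), call. = FALSE)
    x
  }
  chk_prop <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must lie in [0, 1] for model '%s'", nm, model),
           call. = FALSE)
    x
  }
  p <- list(model = model,
            k = chk_pos(k, "k"), m = chk_pos(m, "m"), q = chk_prop(q, "q"))
  if (model %in% c("snm_only", "two_gamma", "gaussian_unid"))
    p$p0 <- chk_prop(p0, "p0")
  if (model == "single_dme") {
    if (is.null(u_free) || !is.finite(u_free) || u_free < 0)
      stop("'u_free' must be a non-negative number for model 'single_dme'",
           call. = FALSE)
    p$u_free <- u_free
  }
  if (model == "two_gamma") {
    p$k_unid <- chk_pos(k_unid, "k_unid")
    p$m_unid <- chk_pos(m_unid, "m_unid")
    p$q_unid <- chk_prop(q_unid, "q_unid")
    if (is.null(u_unid) || !is.finite(u_unid) || u_unid < 0)
      stop("'u_unid' must be a non-negative number for model 'two_gamma'",
           call. = FALSE)
    p$u_unid <- u_unid
  }
  if (model == "gaussian_unid") {
    if (is.null(mu_unid) || !is.finite(mu_unid))
      stop("'mu_unid' must be finite for model 'gaussian_unid'", call. = FALSE)
    if (is.null(sigma_unid) || !is.finite(sigma_unid) || sigma_unid < 0)
      stop("'sigma_unid' must be >= 0 for model 'gaussian_unid'",
           call. = FALSE)
    p$mu_unid <- mu_unid
    p$sigma_unid <- sigma_unid
  }
  structure(p, class = "dme_params")
}

#' @export
print.dme_params <- function(x, ...) {
  cat("DME parameters [", x$model, "]\n", sep = "")
  flds <- setdiff(names(x), "model")
  for (f in flds) cat(sprintf("  %-10s %g\n", f, x[[f]]))
  invisible(x)
}

#' Fitting / density-grid configuration
#'
#' Numerical configuration shared by the FFT density computation and the
#' likelihood fits.
#'
#' @param m_diploid mean number of sequenced SNMs per diploid MA parent strain;
#'   each assayed haploid progeny inherits on average half of them, so the
#'   SNM Poisson mean is `(m_diploid / 2) * (1 - p0)`.
#' @param kernel_sd standard deviation (s-units) of the narrow Gaussian kernel
#'   that regularises the compound-Poisson point mass at zero before Fourier
#'   inversion. Default `2^-16`.
#' @param grid_n FFT grid size; must be a power of two.
#' @param grid_span total width of the selection-coefficient grid, centred on
#'   zero (the grid covers `[-grid_span/2, grid_span/2]`).
#' @param u_uses_p0_directly if `TRUE`, the SNM Poisson mean is computed as
#'   `(m_diploid/2) * p0` instead of `(m_diploid/2) * (1 - p0)`. The default
#'   (`FALSE`) treats `p0` as the *neutral* proportion, which is the
#'   interpretation consistent with the fitted parameter values; the switch is
#'   provided because the alternative algebraic reading exists.
#' @return an object of class `"dme_fit_config"`.
#' @export
fit_config <- function(m_diploid = 8, kernel_sd = 2^-16,
                       grid_n = 2^16, grid_span = 1,
                       u_uses_p0_directly = FALSE) {
  if (grid_n < 8 || bitwAnd(as.integer(grid_n), as.integer(grid_n) - 1L) != 0L)
    stop("'grid_n' must be a power of two >= 8", call. = FALSE)
  if (grid_span <= 0) stop("'grid_span' must be positive", call. = FALSE)
  if (kernel_sd <= 0) stop("'kernel_sd' must be positive", call. = FALSE)
  if (m_diploid < 0) stop("'m_diploid' must be non-negative", call. = FALSE)
  structure(list(m_diploid = m_diploid, kernel_sd = kernel_sd,
                 grid_n = as.integer(grid_n), grid_span = grid_span,
                 u_uses_p0_directly = isTRUE(u_uses_p0_directly)),
            class = "dme_fit_config")
}

#' SNM Poisson mean implied by a model's parameters
#'
#' @param params a [dme_params()] object.
#' @param config a [fit_config()] object (supplies `m_diploid`).
#' @return the Poisson mean of non-neutral SNMs per assayed haploid strain.
#' @export
snm_poisson_mean <- function(params, config) {
  if (params$model == "single_dme") return(params$u_free)
  frac <- if (config$u_uses_p0_directly) params$p0 else (1 - params$p0)
  (config$m_diploid / 2) * frac
}
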