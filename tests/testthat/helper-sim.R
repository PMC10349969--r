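# Shared simulation helpers for the test suite. All draws are made under the
# caller's seed; tests set seeds explicitly.

# published-fit reference parameter sets used across tests
ref_snm_only <- function() {
  dme_params("snm_only", k = 1.4e-1, m = 5.0e-3, q = 0.105, p0 = 0.001)
}
ref_gaussian <- function() {
  dme_params("gaussian_unid", k = 5.5e-2, m = 4.1e-3, q = 0.06, p0 = 0.059,
             mu_unid = -3.3e-3, sigma_unid = 5.5e-3)
}
# printed 95% CIs of the snm_only reference fit (k, m, q)
ref_snm_only_ci <- function() {
  list(k = c(7.8e-2, 4.9e-1), m = c(3.4e-3, 1.4e-2), q = c(0.025, 0.24))
}

# brute-force Monte-Carlo draws of per-strain net mutational effects under a
# DME model, plus Gaussian observation noise with SD 'error_sd' and the
# regularising kernel; this is the sampling oracle that the FFT density is
# checked against
mc_total_effects <- function(params, config, n, error_sd = 0) {
  draw_refgamma <- function(nn, k, m, q) {
    if (nn == 0) return(numeric(0))
    ifelse(stats::runif(nn) < q, 1, -1) *
      stats::rgamma(nn, shape = k, scale = m / k)
  }
  u <- snm_poisson_mean(params, config)
  nm <- stats::rpois(n, u)
  eff <- draw_refgamma(sum(nm), params$k, params$m, params$q)
  tot <- as.vector(rowsum(c(eff, rep(0, n)),
                          c(rep(seq_len(n), nm), seq_len(n))))
  if (params$model == "two_gamma") {
    nm2 <- stats::rpois(n, params$u_unid)
    eff2 <- draw_refgamma(sum(nm2), params$k_unid, params$m_unid,
                          params$q_unid)
    tot <- tot + as.vector(rowsum(c(eff2, rep(0, n)),
                                  c(rep(seq_len(n), nm2), seq_len(n))))
  } else if (params$model == "gaussian_unid") {
    tot <- tot + stats::rnorm(n, params$mu_unid, params$sigma_unid)
  }
  tot + stats::rnorm(n, 0, sqrt(error_sd^2 + config$kernel_sd^2))
}

# Kolmogorov-Smirnov distance between draws and a density-grid CDF
ks_vs_grid <- function(draws, dens) {
  cdf <- density_cdf(dens)
  fm <- stats::approx(dens$s_values, cdf, xout = sort(draws), rule = 2)$y
  n <- length(draws)
  max(abs(fm - (seq_len(n) - 0.5) / n))
}

# simulated per-strain summary estimates under a DME model (shared se)
sim_summary_estimates <- function(params, config, n_strains, se = 0.002) {
  tot <- mc_total_effects(params, config, n_strains, error_sd = 0)
  # mc_total_effects already added kernel-scale noise (negligible here);
  # add the measurement error explicitly
  data.frame(s_hat = tot + stats::rnorm(n_strains, 0, se), se_s = se)
}

# small complete colony experiment for strain-effect tests
sim_small_experiment <- function(n_strains = 8, pairs_target = 100,
                                 rho_ref = 0.1, seed = 1,
                                 dme = ref_gaussian(),
                                 rho_concentration = 30) {
  set.seed(seed)
  ps <- pipeline_preset("tiny")
  ps$design$n_ma_strains <- n_strains
  ps$design$ma_colonies_per_well <- pairs_target
  ps$design$ref_colonies_per_well <- pairs_target
  ps$design$n_control_strains <- 0
  ps$sim$rho_ref <- rho_ref
  truths <- draw_strain_truths(dme, ps$design, ps$config,
                               rho_ref = rho_ref,
                               rho_concentration = rho_concentration)
  colonies <- simulate_colonies(truths, ps$sim, ps$design)
  list(truths = truths, colonies = colonies,
       petites = attr(colonies, "petite_controls"),
       sim = ps$sim, config = ps$config,
       general = as_general_params(ps$sim))
}
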