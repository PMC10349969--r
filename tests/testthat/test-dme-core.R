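test_that("reflected-gamma CF satisfies its closed-form identities", {
  w <- seq(-200, 200, length.out = 401)
  # normalisation at omega = 0, arbitrary params
  expect_equal(cf_reflected_gamma(0, m = 0.01, k = 0.3, q = 0.2), 1 + 0i)
  # q = 1 collapses to the one-sided gamma CF
  expect_equal(cf_reflected_gamma(w, 0.02, 0.7, 1),
               (1 - complex(imaginary = w * 0.02 / 0.7))^(-0.7))
  # q = 1/2, k = 1: symmetric reflected exponential, CF = 1 / (1 + w^2 m^2)
  cf <- cf_reflected_gamma(w, 0.01, 1, 0.5)
  expect_equal(Im(cf), rep(0, length(w)), tolerance = 1e-12)
  expect_equal(Re(cf), 1 / (1 + w^2 * 1e-4), tolerance = 1e-12)
})

test_that("compound-Poisson CF limits and zero-class mass are exact", {
  w <- seq(-50, 50, length.out = 101)
  cfz <- cf_reflected_gamma(w, 0.01, 0.5, 0.3)
  expect_equal(cf_compound_poisson(cfz, 0), rep(1 + 0i, length(w)))
  expect_equal(cf_compound_poisson(rep(1 + 0i, length(w)), 3.7),
               rep(1 + 0i, length(w)))
  # degenerate effect c: inverted density's mass near 0 is the Poisson(2)
  # zero class exp(-2) (kernel spreads the atom; integrate a window around 0
  # far narrower than c)
  cfg <- fit_config(grid_n = 2^16, grid_span = 1)
  n <- cfg$grid_n; ds <- cfg$grid_span / n
  kk <- c(seq_len(n / 2) - 1L, seq.int(-n / 2, -1L))
  omega <- 2 * pi * kk / (n * ds)
  cc <- 0.05
  cf <- cf_compound_poisson(exp(complex(imaginary = omega * cc)), 2) *
    exp(-omega^2 * cfg$kernel_sd^2 / 2)
  phase <- exp(complex(imaginary = -omega * (-cfg$grid_span / 2)))
  f <- Re(stats::fft(cf * phase)) / (n * ds)
  s <- -cfg$grid_span / 2 + ds * (seq_len(n) - 1L)
  zero_mass <- sum(f[abs(s) < cc / 2]) * ds
  expect_equal(zero_mass, exp(-2), tolerance = 1e-6)
})

test_that("total CF respects model structure and the modulus bound", {
  cfg <- fit_config(m_diploid = 8)
  w <- seq(-500, 500, length.out = 201)
  # gaussian_unid with no SNMs (p0 = 1 so U = 0) is the pure Gaussian CF
  p <- dme_params("gaussian_unid", k = 0.1, m = 5e-3, q = 0.1, p0 = 1,
                  mu_unid = -2e-3, sigma_unid = 4e-3)
  expect_equal(cf_total(p, cfg, w),
               exp(complex(real = -w^2 * 16e-6 / 2,
                           imaginary = w * -2e-3)))
  # two_gamma with u_unid = 0 matches snm_only at the same SNM params
  p2 <- dme_params("two_gamma", k = 0.14, m = 5e-3, q = 0.105, p0 = 0.1,
                   k_unid = 1, m_unid = 0.01, q_unid = 0.5, u_unid = 0)
  p1 <- dme_params("snm_only", k = 0.14, m = 5e-3, q = 0.105, p0 = 0.1)
  expect_equal(cf_total(p2, cfg, w), cf_total(p1, cfg, w))
  # |CF| <= 1 across models and random valid parameters
  set.seed(401)
  for (i in 1:25) {
    draws <- list(
      dme_params("snm_only", k = runif(1, 0.01, 5), m = runif(1, 1e-4, 0.1),
                 q = runif(1), p0 = runif(1)),
      dme_params("single_dme", k = runif(1, 0.01, 5),
                 m = runif(1, 1e-4, 0.1), q = runif(1),
                 u_free = runif(1, 0, 10)),
      dme_params("two_gamma", k = runif(1, 0.01, 5), m = runif(1, 1e-4, 0.1),
                 q = runif(1), p0 = runif(1), k_unid = runif(1, 0.01, 5),
                 m_unid = runif(1, 1e-4, 0.1), q_unid = runif(1),
                 u_unid = runif(1, 0, 10)),
      dme_params("gaussian_unid", k = runif(1, 0.01, 5),
                 m = runif(1, 1e-4, 0.1), q = runif(1), p0 = runif(1),
                 mu_unid = runif(1, -0.05, 0.05),
                 sigma_unid = runif(1, 0, 0.05)))
    for (p in draws)
      expect_true(all(Mod(cf_total(p, cfg, w)) <= 1 + 1e-12))
  }
})

test_that("FFT density reduces to the exact Gaussian when U = 0", {
  cfg <- fit_config(m_diploid = 8)
  p <- dme_params("snm_only", k = 0.14, m = 5e-3, q = 0.105, p0 = 1)
  err <- 0.01
  d <- dme_pdf(p, cfg, error_sd = err)
  sd_tot <- sqrt(err^2 + cfg$kernel_sd^2)
  expect_lt(max(abs(d$density - dnorm(d$s_values, 0, sd_tot))), 1e-6)
  expect_equal(density_integral(d), 1, tolerance = 1e-6)
})

test_that("FFT density integrates to one and obeys reflection symmetry", {
  cfg <- fit_config(m_diploid = 8)
  p <- ref_gaussian()
  d <- dme_pdf(p, cfg, error_sd = 0.005)
  expect_equal(density_integral(d), 1, tolerance = 1e-6)
  expect_true(all(d$density >= 0))
  # q <-> 1-q with mu_unid negated mirrors the density about s = 0
  p_flip <- dme_params("gaussian_unid", k = p$k, m = p$m, q = 1 - p$q,
                       p0 = p$p0, mu_unid = -p$mu_unid,
                       sigma_unid = p$sigma_unid)
  d_flip <- dme_pdf(p_flip, cfg, error_sd = 0.005)
  # grid is [-span/2, span/2): node j reflects onto node (n - j), node 0 has
  # no mirror
  n <- cfg$grid_n
  expect_equal(d_flip$density[2:n], rev(d$density[2:n]), tolerance = 1e-6)
})

test_that("grid mean of the density matches the compound-Poisson mean", {
  cfg <- fit_config(m_diploid = 8)
  for (p in list(ref_snm_only(), ref_gaussian())) {
    d <- dme_pdf(p, cfg, error_sd = 0.005)
    u <- snm_poisson_mean(p, cfg)
    mu_th <- u * p$m * (2 * p$q - 1) +
      if (p$model == "gaussian_unid") p$mu_unid else 0
    mu_grid <- sum(d$s_values * d$density) * d$spacing
    # agreement up to the gamma tail mass beyond the grid edge
    expect_equal(mu_grid, mu_th, tolerance = 5e-3)
  }
})

test_that("narrow grids that cannot hold the distribution are refused", {
  cfg <- fit_config(m_diploid = 8, grid_n = 2^10, grid_span = 0.02)
  p <- dme_params("single_dme", k = 1, m = 0.05, q = 0.5, u_free = 5)
  expect_error(dme_pdf(p, cfg, error_sd = 0.005), "grid")
})

test_that("summary likelihood matches the exact normal for U = 0 and is
           additive over duplicated strains", {
  cfg <- fit_config(m_diploid = 8)
  p <- dme_params("snm_only", k = 0.14, m = 5e-3, q = 0.105, p0 = 1)
  est <- data.frame(s_hat = 0.004, se_s = 0.006)
  ll <- summary_loglik(est, p, cfg)
  expect_equal(ll,
               dnorm(0.004, 0, sqrt(0.006^2 + cfg$kernel_sd^2), log = TRUE),
               tolerance = 1e-6)
  est2 <- rbind(est, est)
  expect_equal(summary_loglik(est2, p, cfg), 2 * ll, tolerance = 1e-10)
  # estimates outside the grid span are a resolution error
  expect_error(summary_loglik(data.frame(s_hat = 0.7, se_s = 0.01), p, cfg),
               "grid")
})

test_that("u_uses_p0_directly switch flips the Poisson-mean convention", {
  p <- dme_params("snm_only", k = 0.14, m = 5e-3, q = 0.105, p0 = 0.2)
  expect_equal(snm_poisson_mean(p, fit_config(m_diploid = 8)), 4 * 0.8)
  expect_equal(snm_poisson_mean(
    p, fit_config(m_diploid = 8, u_uses_p0_directly = TRUE)), 4 * 0.2)
})

test_that("model constructors reject inconsistent parameter sets", {
  expect_error(dme_params("snm_only", k = -1, m = 5e-3, q = 0.1, p0 = 0.1),
               "k")
  expect_error(dme_params("snm_only", k = 0.1, m = 5e-3, q = 1.2, p0 = 0.1),
               "q")
  expect_error(dme_params("single_dme", k = 0.1, m = 5e-3, q = 0.1,
                          u_free = -2), "u_free")
  expect_error(dme_params("gaussian_unid", k = 0.1, m = 5e-3, q = 0.1,
                          p0 = 0.1, mu_unid = 0), "sigma_unid")
})
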