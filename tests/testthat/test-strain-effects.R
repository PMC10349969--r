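gen_ref <- function(rho_ref = 0.05) {
  general_params(mu_anc = 0.55, mu_petite = 0.35, rho_ref = rho_ref,
                 sigma_nonpetite = 0.03, sigma_petite = 0.05)
}

test_that("difference mixture collapses to one Gaussian when both rho are 0", {
  g <- gen_ref(rho_ref = 0)
  d <- seq(-0.1, 0.1, length.out = 21)
  ll <- vapply(d, function(x) diff_loglik(x, s = -0.02, rho_i = 0, g),
               numeric(1))
  expect_equal(ll, dnorm(d, 0.55 * -0.02, sqrt(2) * 0.03, log = TRUE),
               tolerance = 1e-12)
  # identical to the dedicated no-petite likelihood
  expect_equal(diff_loglik(d, -0.02, 0, g),
               single_gaussian_loglik(d, -0.02, g), tolerance = 1e-12)
})

test_that("difference mixture density integrates to one", {
  g <- general_params(mu_anc = 0.55, mu_petite = 0.35, rho_ref = 0.05,
                      sigma_nonpetite = 0.03, sigma_petite = 0.05)
  dens <- function(x) exp(vapply(x, function(xx)
    diff_loglik(xx, s = -0.02, rho_i = 0.1, g), numeric(1)))
  expect_equal(integrate(dens, -1.5, 1.5, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
})

test_that("pairing obeys the min rule and respects field boundaries", {
  col <- data.frame(
    strain_id = c(rep("A", 3), rep("REF", 5), rep("B", 4)),
    plate = "P1",
    well = c(rep("w1", 8), rep("w2", 4)),
    field = c(rep("f1", 8), rep("f2", 4)),
    is_reference = c(0, 0, 0, 1, 1, 1, 1, 1, 0, 0, 0, 0),
    growth_rate = 0.5)
  diffs <- pair_colonies(col, seed = 1)
  # field f1: min(3 MA, 5 ref) = 3 pairs; field f2 has no reference: 0 pairs
  expect_equal(nrow(diffs), 3)
  expect_true(all(diffs$strain_id == "A"))
  # identical rates give all-zero differences
  expect_true(all(diffs$d_value == 0))
  expect_identical(attr(diffs, "pairing_seed"), 1L)
  expect_error(pair_colonies(col[col$is_reference == 0, ]), "reference")
})

test_that("petite-control likelihood is a sum of normal log-densities", {
  g <- gen_ref()
  expect_equal(petite_control_loglik(0.35, g), dnorm(0, 0, 0.05, log = TRUE))
  # two identical colonies double the single-colony value
  expect_equal(petite_control_loglik(c(0.3, 0.3), g),
               2 * petite_control_loglik(0.3, g))
  # single observation maximises over mu_petite at the observed value
  lls <- vapply(seq(0.30, 0.40, by = 0.005), function(mu)
    petite_control_loglik(0.36, general_params(
      mu_anc = 0.55, mu_petite = mu, rho_ref = 0.05,
      sigma_nonpetite = 0.03, sigma_petite = 0.05)), numeric(1))
  expect_equal(seq(0.30, 0.40, by = 0.005)[which.max(lls)], 0.36)
  expect_error(petite_control_loglik(numeric(0), g), "empty")
})

test_that("ML recovers petite parameters from a large control sample", {
  set.seed(5)
  rates <- rnorm(3000, 0.35, 0.04)
  nll <- function(p) -petite_control_loglik(
    rates, general_params(mu_anc = 0.55, mu_petite = p[1], rho_ref = 0,
                          sigma_nonpetite = 0.03, sigma_petite = p[2]))
  opt <- optim(c(0.3, 0.05), nll)
  expect_lt(abs(opt$par[1] - 0.35), 3 * 0.04 / sqrt(3000))
  expect_lt(abs(opt$par[2] - 0.04), 3 * 0.04 / sqrt(2 * 3000))
})

test_that("strain estimation recovers a known effect and petite proportion", {
  g <- gen_ref(rho_ref = 0.05)
  set.seed(88)
  n <- 500
  draw_side <- function(n, mu, rho) {
    pet <- runif(n) < rho
    rnorm(n, ifelse(pet, g$mu_petite, mu),
          ifelse(pet, g$sigma_petite, g$sigma_nonpetite))
  }
  d <- draw_side(n, g$mu_anc * (1 - 0.03), 0.15) - draw_side(n, g$mu_anc,
                                                             g$rho_ref)
  f <- madfe:::fit_one_strain(d, g)
  pr <- madfe:::profile_strain_s(d, g, f$s, f$loglik)
  expect_lt(abs(f$s - (-0.03)), 3 * pr$se)
  expect_lt(abs(f$rho - 0.15), 0.06)
  expect_false(f$flagged)
})

test_that("an all-petite strain is flagged as unidentifiable", {
  g <- gen_ref(rho_ref = 0.05)
  set.seed(12)
  d <- rnorm(200, 0.35, 0.05) - rnorm(200, 0.55, 0.03)
  f <- madfe:::fit_one_strain(d, g)
  expect_true(f$flagged)
})

test_that("batch shifts leave the whole estimation chain unchanged", {
  ex <- sim_small_experiment(n_strains = 5, pairs_target = 60, seed = 17)
  shifted <- ex$colonies
  key <- interaction(shifted$plate, shifted$well, drop = TRUE)
  set.seed(18)
  shift <- stats::setNames(runif(nlevels(key), -0.2, 0.2), levels(key))
  shifted$growth_rate <- shifted$growth_rate + shift[as.character(key)]
  fit1 <- estimate_strain_effects(pair_colonies(ex$colonies, seed = 4),
                                  ex$petites, init = ex$general,
                                  n_starts = 1, seed = 6)
  fit2 <- estimate_strain_effects(pair_colonies(shifted, seed = 4),
                                  ex$petites, init = ex$general,
                                  n_starts = 1, seed = 6)
  expect_equal(fit2$estimates$s_hat, fit1$estimates$s_hat,
               tolerance = 1e-10)
  expect_equal(fit2$general$mu_anc, fit1$general$mu_anc, tolerance = 1e-10)
})

test_that("significance calls control sign and obvious cases", {
  est <- data.frame(strain_id = c("big", sprintf("null%d", 1:9)),
                    s_hat = c(-0.5, rnorm(9, 0, 1e-4)),
                    se_s = c(0.005, rep(1, 9)))
  out <- classify_significance(est)
  expect_equal(out$call[1], "decrease")
  expect_true(all(out$call[-1] == "ns"))
  empty <- classify_significance(est[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("p_value", "q_value", "call") %in% names(empty)))
})

test_that("FDR calibration: all-null experiments rarely produce calls", {
  set.seed(19)
  fdp <- replicate(1000, {
    est <- data.frame(strain_id = sprintf("s%d", 1:50),
                      s_hat = rnorm(50, 0, 0.004), se_s = 0.004)
    out <- classify_significance(est, fdr = 0.05)
    v <- sum(out$call != "ns")
    v / max(v, 1)
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("mixture LRT does not reject on petite-free data", {
  # with no petites in truth, the mixture's extra parameters sit on their
  # boundary and the chi-square reference is conservative
  ex <- sim_small_experiment(n_strains = 6, pairs_target = 80, seed = 222,
                             rho_ref = 0,
                             dme = dme_params("snm_only", k = 0.14, m = 5e-3,
                                              q = 0.105, p0 = 1),
                             rho_concentration = Inf)
  # petite-control colonies still exist (they calibrate mu_petite)
  lrt <- petite_mixture_lrt(pair_colonies(ex$colonies, seed = 2),
                            ex$petites, init = ex$general,
                            n_starts = 1, seed = 3)
  expect_gt(lrt$p_value, 0.05)
})

test_that("rebaselining composes selection coefficients correctly", {
  expect_equal(rebaseline_s(0.05, 0.05), 0)
  expect_equal(rebaseline_s(-0.03, 0.02), (1 - 0.03) / (1 + 0.02) - 1)
  expect_equal(rebaseline_s(0, 0), 0)
})
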