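test_that("strain truths honour degenerate DME limits", {
  design <- simulation_design(n_ma_strains = 50, n_control_strains = 2,
                              n_plates = 2)
  cfg <- fit_config(m_diploid = 8)
  # p0 = 1 means U = 0: no mutations, zero effects everywhere
  set.seed(1)
  tr <- draw_strain_truths(
    dme_params("snm_only", k = 0.14, m = 5e-3, q = 0.105, p0 = 1),
    design, cfg)
  expect_true(all(tr$n_mutations == 0))
  expect_true(all(tr$total_effect == 0))
  # q = 0: strictly non-positive per-mutation effects
  set.seed(2)
  tr2 <- draw_strain_truths(
    dme_params("single_dme", k = 0.3, m = 0.01, q = 0, u_free = 5),
    simulation_design(n_ma_strains = 200, n_plates = 2), cfg)
  expect_true(all(unlist(tr2$per_mutation_effects) <= 0))
  # controls always have zero effect
  expect_true(all(tr$total_effect[tr$is_control] == 0))
  expect_true(all(tr$true_rho >= 0 & tr$true_rho <= 1))
})

test_that("mean total effect matches -U m (1 - 2q) at reference parameters", {
  # closed form: E[sum of N reflected-gamma effects] = U * m * (2q - 1)
  p <- ref_snm_only()
  cfg <- fit_config(m_diploid = 8)
  u <- snm_poisson_mean(p, cfg)
  design <- simulation_design(n_ma_strains = 1e5, n_control_strains = 0,
                              n_plates = 2)
  set.seed(33)
  tr <- draw_strain_truths(p, design, cfg)
  mu_th <- -u * p$m * (1 - 2 * p$q)
  # SE of the mean of a compound-Poisson: sqrt(U E[Z^2] / n)
  ez2 <- p$m^2 * (1 + 1 / p$k)
  se <- sqrt(u * ez2 / nrow(tr))
  expect_lt(abs(mean(tr$total_effect) - mu_th), 3 * se)
  expect_equal(tr$total_effect,
               vapply(tr$per_mutation_effects, sum, numeric(1)))
})

test_that("noise-free colonies are exactly the genetic means", {
  sp <- sim_params(sigma_plate = 0, sigma_well = 0, sigma_col = 0,
                   sigma_nonpetite_bio = 0, rho_ref = 0)
  design <- simulation_design(n_ma_strains = 3, n_plates = 1,
                              ma_colonies_per_well = 20,
                              ref_colonies_per_well = 20,
                              fields_per_well = 2, exact_counts = TRUE,
                              n_control_strains = 0,
                              n_petite_control_samples = 0)
  tr <- data.frame(strain_id = c("A", "B", "C"), is_control = FALSE,
                   n_mutations = 1, total_effect = c(-0.05, 0, 0.02),
                   true_rho = 0)
  set.seed(9)
  col <- simulate_colonies(tr, sp, design)
  for (i in 1:3) {
    g <- col$growth_rate[col$strain_id == tr$strain_id[i]]
    expect_equal(g, rep(sp$mu_anc * (1 + tr$total_effect[i]), length(g)))
  }
  expect_equal(unique(col$growth_rate[col$is_reference == 1]), sp$mu_anc)
})

test_that("within-well pairs share batch draws so differences cancel them", {
  # re-simulating with different plate/well SDs but identical colony-level
  # draws (same seed) leaves within-well differences unchanged
  design <- simulation_design(n_ma_strains = 2, n_plates = 2,
                              ma_colonies_per_well = 30,
                              ref_colonies_per_well = 30,
                              fields_per_well = 3, exact_counts = TRUE,
                              n_control_strains = 0,
                              n_petite_control_samples = 0)
  tr <- data.frame(strain_id = c("A", "B"), is_control = FALSE,
                   n_mutations = 0, total_effect = c(-0.02, 0.01),
                   true_rho = c(0.1, 0.2))
  base <- sim_params()
  loud <- sim_params(sigma_plate = 0.2, sigma_well = 0.1)
  set.seed(55); col1 <- simulate_colonies(tr, base, design)
  set.seed(55); col2 <- simulate_colonies(tr, loud, design)
  d1 <- pair_colonies(col1, seed = 2)$d_value
  d2 <- pair_colonies(col2, seed = 2)$d_value
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("per-strain MA-minus-reference means recover mu_anc * s", {
  design <- simulation_design(n_ma_strains = 2, n_plates = 4,
                              ma_colonies_per_well = 2500,
                              ref_colonies_per_well = 2500,
                              fields_per_well = 5, exact_counts = TRUE,
                              n_control_strains = 0,
                              n_petite_control_samples = 0)
  tr <- data.frame(strain_id = c("A", "B"), is_control = FALSE,
                   n_mutations = 1, total_effect = c(-0.04, 0.02),
                   true_rho = 0)
  sp <- sim_params(rho_ref = 0)
  set.seed(101)
  col <- simulate_colonies(tr, sp, design)
  sd_col <- sqrt(sp$sigma_nonpetite_bio^2 + sp$sigma_col^2)
  for (i in 1:2) {
    ma <- col[col$strain_id == tr$strain_id[i], ]
    delta <- sapply(split(seq_len(nrow(ma)), ma$well), function(ix) {
      w <- ma$well[ix[1]]
      rf <- col[col$well == w & col$is_reference == 1, ]
      mean(ma$growth_rate[match(ix, seq_len(nrow(ma)))]) -
        mean(rf$growth_rate)
    })
    n_w <- design$ma_colonies_per_well
    se <- sqrt(2 * sd_col^2 / n_w / length(delta))
    expect_lt(abs(mean(delta) - sp$mu_anc * tr$total_effect[i]), 3 * se)
  }
})

test_that("simulated variance decomposes into its components", {
  # non-petite ancestor colonies: Var = sigma_plate^2 + sigma_well^2 +
  # sigma_col^2 + sigma_nonpetite_bio^2; check the total and the
  # between-well component separately (method-of-moments ANOVA)
  sp <- sim_params(rho_ref = 0)
  design <- simulation_design(n_ma_strains = 60, n_plates = 12,
                              ma_colonies_per_well = 200,
                              ref_colonies_per_well = 200,
                              fields_per_well = 1, exact_counts = TRUE,
                              n_control_strains = 0,
                              n_petite_control_samples = 0)
  tr <- data.frame(strain_id = sprintf("S%02d", 1:60), is_control = FALSE,
                   n_mutations = 0, total_effect = 0, true_rho = 0)
  set.seed(202)
  col <- simulate_colonies(tr, sp, design)
  rf <- col[col$is_reference == 1, ]
  within_var <- mean(tapply(rf$growth_rate, rf$well, var))
  between_var <- var(tapply(rf$growth_rate, rf$well, mean))
  sigma2_within <- sp$sigma_nonpetite_bio^2 + sp$sigma_col^2
  sigma2_between <- sp$sigma_plate^2 + sp$sigma_well^2 +
    sigma2_within / design$ref_colonies_per_well
  expect_equal(within_var, sigma2_within, tolerance = 0.1)
  expect_equal(between_var, sigma2_between, tolerance = 0.35)
})

test_that("petite fractions converge to each strain's true rho", {
  design <- simulation_design(n_ma_strains = 3, n_plates = 3,
                              ma_colonies_per_well = 4000,
                              ref_colonies_per_well = 10,
                              fields_per_well = 1, exact_counts = TRUE,
                              n_control_strains = 0,
                              n_petite_control_samples = 0)
  tr <- data.frame(strain_id = c("A", "B", "C"), is_control = FALSE,
                   n_mutations = 0, total_effect = 0,
                   true_rho = c(0.05, 0.2, 0.5))
  set.seed(303)
  col <- simulate_colonies(tr, sim_params(), design)
  for (i in 1:3) {
    sub <- col[col$strain_id == tr$strain_id[i], ]
    se <- sqrt(tr$true_rho[i] * (1 - tr$true_rho[i]) / nrow(sub))
    expect_lt(abs(mean(sub$true_is_petite) - tr$true_rho[i]), 3 * se)
  }
})

test_that("simulation is byte-reproducible under a fixed seed", {
  f1 <- make_fixture("tiny", seed = 42, out_dir = tempfile())
  f2 <- make_fixture("tiny", seed = 42, out_dir = tempfile())
  expect_identical(readLines(f1$colonies), readLines(f2$colonies))
  expect_identical(readLines(f1$truths), readLines(f2$truths))
  expect_identical(readLines(f1$petite_controls),
                   readLines(f2$petite_controls))
})

test_that("time-series simulation is flat through lag then linear", {
  ts <- simulate_timeseries(rate = 0.5, lag = 3, init_log_area = 4,
                            n_timepoints = 11, noise_sd = 0)
  expect_equal(ts$log_area[1:4], rep(4, 4))
  expect_equal(diff(ts$log_area[5:11]), rep(0.5, 6))
  ts0 <- simulate_timeseries(rate = 0, lag = 0, n_timepoints = 8,
                             noise_sd = 0)
  expect_true(all(ts0$log_area == ts0$log_area[1]))
  expect_error(simulate_timeseries(0.5, n_timepoints = 1), "n_timepoints")
})
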