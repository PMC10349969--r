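# Nested maximum-likelihood estimation of per-strain selection coefficients
# and petite proportions from pairwise growth-rate differences.

# inner fit: maximise the difference likelihood of one strain over (s, rho)
# at fixed general parameters. Coarse (s, rho) grid scan followed by a
# bounded quasi-Newton refinement; the grid guards against the multimodality
# that the (s, rho) surface can show at small rho.
fit_one_strain <- function(d, general, s_bounds = c(-0.5, 0.5),
                           s_grid_n = 41L, rho_grid = NULL, refine = TRUE) {
  if (is.null(rho_grid))
    rho_grid <- c(0, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.8, 0.95)
  s_center <- stats::median(d) / general$mu_anc
  s_half <- max(6 * stats::mad(d) / (general$mu_anc * sqrt(length(d))), 0.02)
  s_grid <- seq(max(s_bounds[1], s_center - s_half),
                min(s_bounds[2], s_center + s_half), length.out = s_grid_n)
  best <- c(ll = -Inf, s = s_center, rho = 0)
  cmp <- diff_mixture_components(d, s_grid, general)
  rr <- general$rho_ref
  for (r in rho_grid) {
    lls <- colSums(log((1 - r) * (1 - rr) * cmp$m1 + (1 - r) * rr * cmp$m2 +
                         r * (1 - rr) * cmp$c3 + r * rr * cmp$c4))
    i <- which.max(lls)
    if (lls[i] > best["ll"]) best <- c(ll = lls[i], s = s_grid[i], rho = r)
  }
  if (!refine)
    return(list(s = unname(best["s"]), rho = unname(best["rho"]),
                loglik = unname(best["ll"]), flagged = FALSE))
  nll <- function(p) -diff_loglik(d, p[1], p[2], general)
  opt <- try(stats::optim(c(best["s"], best["rho"]), nll,
                          method = "L-BFGS-B",
                          lower = c(s_bounds[1], 0),
                          upper = c(s_bounds[2], 1)),
             silent = TRUE)
  out <- if (inherits(opt, "try-error") || -opt$value < best["ll"]) {
    list(s = unname(best["s"]), rho = unname(best["rho"]),
         loglik = unname(best["ll"]))
  } else {
    list(s = opt$par[1], rho = opt$par[2], loglik = -opt$value)
  }
  # s is unidentifiable when the data cannot rule out an (almost) all-petite
  # strain: at rho = 1 the likelihood no longer depends on s, so a small
  # log-likelihood gap to the unconstrained optimum means the (s, rho) ridge
  # is flat and the fit must be flagged rather than reported silently
  ll_allpet <- diff_loglik(d, out$s, 1, general)
  out$flagged <- out$rho > 0.98 || (out$loglik - ll_allpet) < 3
  out
}

# profile log-likelihood of s for one strain (rho re-maximised at each s)
profile_strain_s <- function(d, general, s_hat, ll_hat, delta_ll = 1.92,
                             n_points = 25L, s_bounds = c(-0.5, 0.5)) {
  prof_ll <- function(s) {
    o <- stats::optimize(function(r) diff_loglik(d, s, r, general),
                         interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    o$objective
  }
  # initial half-width from a crude Wald guess, then expand until the profile
  # drops below the target on both sides (or the bounds are hit)
  half <- max(2 * sqrt(2) * general$sigma_nonpetite /
                (general$mu_anc * sqrt(length(d))), 1e-4)
  target <- ll_hat - delta_ll
  for (iter in 1:8) {
    lo <- max(s_bounds[1], s_hat - half)
    hi <- min(s_bounds[2], s_hat + half)
    s_grid <- sort(unique(c(seq(lo, hi, length.out = n_points), s_hat)))
    ll <- vapply(s_grid, prof_ll, numeric(1))
    drops_lo <- ll[1] < target || lo <= s_bounds[1]
    drops_hi <- ll[length(ll)] < target || hi >= s_bounds[2]
    if (drops_lo && drops_hi) break
    half <- half * 2.5
  }
  ci_lo <- profile_crossing(s_grid, ll, target, "lower")
  ci_hi <- profile_crossing(s_grid, ll, target, "upper")
  if (!is.finite(ci_lo)) ci_lo <- lo
  if (!is.finite(ci_hi)) ci_hi <- hi
  list(ci = c(ci_lo, ci_hi), se = (ci_hi - ci_lo) / (2 * 1.96))
}

#' Estimate per-strain selection coefficients and petite proportions
#'
#' Nested maximum-likelihood fit of the pairwise-difference mixture model.
#' Inner loop: for each strain, the conditional MLE of its selection
#' coefficient `s_i` and petite proportion `rho_i` given the shared
#' experiment-level ("general") parameters (strains are conditionally
#' independent). Outer loop: multi-start quasi-Newton maximisation of the
#' total log-likelihood (difference terms plus petite-control terms) over the
#' general parameters. Per-strain standard errors come from the profile
#' likelihood of `s_i` at the ML general parameters (95% profile interval,
#' `se = half-width / 1.96`).
#'
#' @param diffs data frame of growth differences (from [pair_colonies()]),
#'   columns `strain_id`, `d_value`.
#' @param petite_rates numeric vector of growth rates from petite-only
#'   control samples.
#' @param init a [general_params()] object used as the optimisation start
#'   (petite parameters are re-initialised from `petite_rates` moments).
#' @param n_starts number of outer optimisation starts (first at `init`,
#'   others perturbed).
#' @param delta_ll profile drop defining the per-strain CI; the default 1.92
#'   is the two-sided 95% chi-square(1) threshold.
#' @param maxit outer Nelder-Mead iteration cap per start (default 800).
#' @param seed seed for start-point perturbations.
#' @return a list with `general` (fitted [general_params()], batch SDs `NA`),
#'   `estimates` (data frame: `strain_id`, `s_hat`, `rho_hat`, `se_s`,
#'   `ci_low`, `ci_high`, `n_diffs`, `flagged`), `loglik`, `converged`, and
#'   `starts_used`.
#' @export
estimate_strain_effects <- function(diffs, petite_rates, init,
                                    n_starts = 3L, delta_ll = 1.92,
                                    maxit = 800L, seed = 1L) {
  stopifnot(inherits(init, "general_params"))
  ids <- unique(as.character(diffs$strain_id))
  if (length(ids) < 1) stop("no strains in 'diffs'", call. = FALSE)
  d_by <- split(diffs$d_value, as.character(diffs$strain_id))[ids]
  if (any(vapply(d_by, length, 1L) < 2))
    stop("every strain needs at least 2 differences", call. = FALSE)

  mu_pet0 <- mean(petite_rates)
  sig_pet0 <- stats::sd(petite_rates)
  # theta = (mu_anc, log gap to mu_petite, logit rho_ref,
  #          log sigma_np, log sigma_pet)
  pack <- function(g) c(g$mu_anc, log(g$mu_anc - g$mu_petite),
                        logit(g$rho_ref), log(g$sigma_nonpetite),
                        log(g$sigma_petite))
  unpack <- function(th) general_params(
    mu_anc = th[1], mu_petite = th[1] - exp(th[2]),
    rho_ref = inv_logit(th[3]),
    sigma_nonpetite = exp(th[4]), sigma_petite = exp(th[5]))

  total_nll <- function(th) {
    g <- try(unpack(th), silent = TRUE)
    if (inherits(g, "try-error")) return(1e10)
    ll <- petite_control_loglik(petite_rates, g)
    for (d in d_by) {
      # grid-only inner maximisation while searching over general
      # parameters; the full refinement happens once at the optimum
      f <- fit_one_strain(d, g, refine = FALSE)
      ll <- ll + f$loglik
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  th0 <- pack(general_params(
    mu_anc = init$mu_anc, mu_petite = mu_pet0,
    rho_ref = max(min(init$rho_ref, 0.95), 0.005),
    sigma_nonpetite = init$sigma_nonpetite, sigma_petite = sig_pet0))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  best <- NULL; lls <- numeric(0)
  for (st in seq_len(n_starts)) {
    th_start <- if (st == 1) th0 else
      th0 + stats::rnorm(5, 0, c(0.02, 0.1, 0.5, 0.1, 0.1))
    opt <- try(stats::optim(th_start, total_nll, method = "Nelder-Mead",
                            control = list(maxit = maxit)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    lls <- c(lls, -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)
  converged <- sum(abs(lls - max(lls)) < 1e-4) >= min(2L, n_starts)

  g_hat <- unpack(best$par)
  est <- lapply(ids, function(id) {
    d <- d_by[[id]]
    f <- fit_one_strain(d, g_hat)
    pr <- profile_strain_s(d, g_hat, f$s, f$loglik, delta_ll = delta_ll)
    data.frame(strain_id = id, s_hat = f$s, rho_hat = f$rho,
               se_s = pr$se, ci_low = pr$ci[1], ci_high = pr$ci[2],
               n_diffs = length(d), flagged = f$flagged,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, est)
  rownames(est) <- NULL
  list(general = g_hat, estimates = est, loglik = -best$value,
       converged = converged, starts_used = length(lls))
}

#' FDR-controlled significance calls for strain effects
#'
#' Two-sided Wald p-values from `s_hat / se_s`, Benjamini-Hochberg adjusted;
#' strains with `q_value <= fdr` are called `"increase"` or `"decrease"` by
#' the sign of `s_hat`, others `"ns"`.
#'
#' @param estimates data frame with columns `s_hat` and `se_s`.
#' @param fdr false discovery rate (default 0.05).
#' @return `estimates` with added columns `p_value`, `q_value`, `call`.
#' @export
classify_significance <- function(estimates, fdr = 0.05) {
  if (nrow(estimates) == 0) {
    estimates$p_value <- numeric(0)
    estimates$q_value <- numeric(0)
    estimates$call <- character(0)
    return(estimates)
  }
  stopifnot(all(estimates$se_s > 0))
  p <- 2 * stats::pnorm(-abs(estimates$s_hat / estimates$se_s))
  q <- stats::p.adjust(p, method = "BH")
  estimates$p_value <- p
  estimates$q_value <- q
  estimates$call <- ifelse(q > fdr, "ns",
                           ifelse(estimates$s_hat > 0, "increase", "decrease"))
  estimates
}

#' Likelihood-ratio test of the petite mixture against a single Gaussian
#'
#' Compares the full four-component difference mixture (strain-specific petite
#' proportions) to the null model with every petite proportion fixed at zero,
#' in which each strain's differences are a single Gaussian with a common SD.
#' Petite-control terms appear in both models with freely fitted petite
#' parameters and cancel from the statistic up to shared-parameter coupling;
#' degrees of freedom are `n_strains + 3` (per-strain `rho_i`, plus
#' `rho_ref`, and the petite mean/SD entering the mixture).
#'
#' @inheritParams estimate_strain_effects
#' @param fit an optional precomputed result of [estimate_strain_effects()]
#'   on the same `diffs`/`petite_rates` (avoids refitting the full model).
#' @return list with `lrt_stat`, `df`, `p_value`, `loglik_full`,
#'   `loglik_null`.
#' @export
petite_mixture_lrt <- function(diffs, petite_rates, init, fit = NULL, ...) {
  if (is.null(fit))
    fit <- estimate_strain_effects(diffs, petite_rates, init, ...)
  d_by <- split(diffs$d_value, as.character(diffs$strain_id))
  # null: D_i ~ N(m_i, 2 sigma^2) with closed-form MLEs
  n_tot <- sum(lengths(d_by))
  ss <- sum(vapply(d_by, function(d) sum((d - mean(d))^2), numeric(1)))
  sig_np0 <- sqrt(ss / n_tot / 2)
  ll_null <- sum(vapply(d_by, function(d)
    sum(stats::dnorm(d, mean(d), sqrt(2) * sig_np0, log = TRUE)),
    numeric(1)))
  ll_null <- ll_null + sum(stats::dnorm(petite_rates, mean(petite_rates),
                                        stats::sd(petite_rates) *
                                          sqrt((length(petite_rates) - 1) /
                                                 length(petite_rates)),
                                        log = TRUE))
  stat <- 2 * (fit$loglik - ll_null)
  df <- length(d_by) + 3L
  list(lrt_stat = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       loglik_full = fit$loglik, loglik_null = ll_null)
}

#' Re-express selection coefficients relative to another fitted strain
#'
#' When the in-well reference strain differs in growth rate from the true
#' ancestor (as for the msh3-delta design, where the GFP-marked reference is
#' not the unmarked ancestor), selection coefficients fitted against the
#' reference are rebaselined against the ancestor strain's own fitted
#' coefficient: `s' = (1 + s) / (1 + s_anchor) - 1`.
#'
#' @param s numeric vector of selection coefficients (vs the reference).
#' @param s_anchor the anchor strain's fitted coefficient (vs the reference).
#' @return rebaselined coefficients.
#' @export
rebaseline_s <- function(s, s_anchor) (1 + s) / (1 + s_anchor) - 1
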