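#' Tail mass of the SNM effect distribution
#'
#' Fraction of all SNMs (counting the neutral class `p0` as zero-effect)
#' whose effect magnitude exceeds `threshold` on the queried side, computed
#' in closed form from the regularized incomplete gamma function:
#' positive side `(1 - p0) * q * P(Gamma(k, m) > t)`, negative side
#' `(1 - p0) * (1 - q) * P(Gamma(k, m) > t)`, `both` their sum.
#'
#' @param params a [dme_params()] object (its SNM reflected-gamma fields are
#'   used; `p0` is taken as 0 for `single_dme`).
#' @param threshold effect-magnitude cutoff (s-units, >= 0).
#' @param side `"negative"`, `"positive"` or `"both"`.
#' @return the probability (proportion of all SNMs).
#' @export
tail_mass <- function(params, threshold, side = c("both", "negative",
                                                  "positive")) {
  side <- match.arg(side)
  stopifnot(inherits(params, "dme_params"), threshold >= 0)
  p0 <- if (is.null(params$p0)) 0 else params$p0
  tail_p <- stats::pgamma(threshold, shape = params$k,
                          scale = params$m / params$k, lower.tail = FALSE)
  w <- switch(side,
              positive = params$q,
              negative = 1 - params$q,
              both = 1)
  (1 - p0) * w * tail_p
}

#' Mean per-mutation effect of simple sequence repeat mutations
#'
#' Converts a mean selection-coefficient change per 100 generations and an
#' SSR mutation count per 200-generation strain into the mean per-SSR-mutation
#' growth-rate decrease, expressed as a percent:
#' `|mean_s_per_100gen| * 200 / (100 * ssr_mutations_per_200gen) * 100`.
#'
#' @param mean_s_per_100gen mean selection-coefficient change per 100
#'   generations (s-units; sign ignored).
#' @param ssr_mutations_per_200gen mean SSR mutation count per 200-generation
#'   strain (> 0).
#' @return percent decrease in growth rate per SSR mutation.
#' @export
ssr_per_mutation_effect <- function(mean_s_per_100gen,
                                    ssr_mutations_per_200gen) {
  stopifnot(ssr_mutations_per_200gen > 0)
  abs(mean_s_per_100gen) * 200 / (100 * ssr_mutations_per_200gen) * 100
}

# ---- parameter transforms for optimisation -------------------------------
# positive parameters on log scale, proportions on logit scale, mu_unid
# identity; keeps the optimiser well conditioned and the bounds implicit.

model_par_info <- function(model) {
  switch(model,
    snm_only = data.frame(
      name = c("k", "m", "q", "p0"),
      trans = c("log", "log", "logit", "logit"),
      lower = c(1e-3, 1e-6, 0, 0), upper = c(50, 0.5, 1, 1),
      stringsAsFactors = FALSE),
    single_dme = data.frame(
      name = c("k", "m", "q", "u_free"),
      trans = c("log", "log", "logit", "log"),
      lower = c(1e-3, 1e-6, 0, 1e-6), upper = c(50, 0.5, 1, 50),
      stringsAsFactors = FALSE),
    two_gamma = data.frame(
      name = c("k", "m", "q", "p0", "k_unid", "m_unid", "q_unid", "u_unid"),
      trans = c("log", "log", "logit", "logit", "log", "log", "logit",
                "log"),
      lower = c(1e-3, 1e-6, 0, 0, 1e-3, 1e-6, 0, 1e-6),
      upper = c(50, 0.5, 1, 1, 50, 0.5, 1, 50),
      stringsAsFactors = FALSE),
    gaussian_unid = data.frame(
      name = c("k", "m", "q", "p0", "mu_unid", "sigma_unid"),
      trans = c("log", "log", "logit", "logit", "identity", "log"),
      lower = c(1e-3, 1e-6, 0, 0, -0.1, 1e-6),
      upper = c(50, 0.5, 1, 1, 0.1, 0.1),
      stringsAsFactors = FALSE),
    stop("unknown model tag: ", model, call. = FALSE))
}

to_transformed <- function(vals, info) {
  out <- numeric(nrow(info))
  for (i in seq_len(nrow(info))) {
    v <- min(max(vals[i], info$lower[i]), info$upper[i])
    out[i] <- switch(info$trans[i],
                     log = log(v),
                     logit = logit((v - info$lower[i]) /
                                     (info$upper[i] - info$lower[i])),
                     identity = v)
  }
  out
}

from_transformed <- function(th, info) {
  out <- numeric(nrow(info))
  for (i in seq_len(nrow(info))) {
    out[i] <- switch(info$trans[i],
                     log = exp(th[i]),
                     logit = info$lower[i] +
                       (info$upper[i] - info$lower[i]) * inv_logit(th[i]),
                     identity = th[i])
  }
  names(out) <- info$name
  out
}

build_dme_params <- function(model, vals) {
  args <- as.list(vals)
  names(args) <- names(vals)
  do.call(dme_params, c(list(model = model), args))
}

# log-likelihood dispatcher: data is either a summary-estimates data frame
# (s_hat/se_s) or a list(diffs=, general=, rho=) for the full-data fit
dme_data_loglik <- function(data, params, config) {
  if (is.data.frame(data)) {
    summary_loglik(data, params, config)
  } else {
    full_data_loglik(data$diffs, params, data$general, data$rho, config)
  }
}

#' Fit a DME model by multi-start maximum likelihood
#'
#' Maximises the summary-statistic likelihood (when `data` is a data frame of
#' per-strain `s_hat`/`se_s`) or the full colony-difference likelihood (when
#' `data` is a list with `diffs`, `general` and `rho`) over the model's
#' parameters, using Nelder-Mead on log/logit-transformed parameters from
#' multiple start points. The fit is marked converged when the best
#' log-likelihood is reproduced (within 1e-4) from at least two distinct
#' starts.
#'
#' @param data summary estimates data frame, or
#'   `list(diffs =, general =, rho =)`.
#' @param model model tag (see [dme_params()]).
#' @param config a [fit_config()] object.
#' @param n_starts number of optimisation starts (the first at a
#'   moment-informed default, the rest spread over the parameter box).
#' @param init optional named vector of natural-scale start values for the
#'   first start.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed seed for start-point draws.
#' @param se_quantize for summary-data fits, quantise the per-strain error
#'   SDs onto geometric bins of this relative width before fitting, so
#'   strains with near-identical precision share one FFT per likelihood
#'   evaluation (default 0.02, i.e. SDs matched to 2%; 0 disables). The
#'   reported MLE is computed with the quantised SDs.
#' @return an object of class `"dme_fit"`: list with `model`, `mle` (a
#'   [dme_params()]), `mle_values` (named vector), `loglik`, `n_params`,
#'   `aic`, `converged`, `starts_used`, `data`, `config`.
#' @export
fit_model <- function(data, model, config = fit_config(), n_starts = 6L,
                      init = NULL, maxit = 500L, seed = 1L,
                      se_quantize = 0.02) {
  info <- model_par_info(model)
  if (is.data.frame(data) && se_quantize > 0 && nrow(data) > 0) {
    lo <- min(data$se_s)
    data$se_s <- lo * (1 + se_quantize) ^
      round(log(data$se_s / lo) / log(1 + se_quantize))
  }
  nll <- function(th) {
    vals <- from_transformed(th, info)
    p <- try(build_dme_params(model, vals), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ll <- try(dme_data_loglik(data, p, config), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  defaults <- c(k = 0.2, m = 5e-3, q = 0.1, p0 = 0.1, u_free = 2,
                k_unid = 0.2, m_unid = 5e-3, q_unid = 0.1, u_unid = 1,
                mu_unid = 0, sigma_unid = 5e-3)
  start0 <- defaults[info$name]
  if (!is.null(init)) start0[names(init)] <- init
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # scale of the observed effects, used to keep random starts inside the
  # region where the likelihood is representable (an effect-size start
  # orders of magnitude below the data scale underflows every density)
  s_scale <- if (is.data.frame(data)) max(stats::sd(data$s_hat), 1e-3) else
    max(stats::sd(data$diffs$d_value) / data$general$mu_anc, 1e-3)
  starts <- list(to_transformed(start0, info))
  if (n_starts > 1) {
    rlog <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
    for (j in seq_len(n_starts - 1L)) {
      v <- start0
      for (i in seq_len(nrow(info))) {
        nm <- info$name[i]
        v[i] <- if (nm %in% c("m", "m_unid")) {
          rlog(max(info$lower[i], s_scale / 30),
               min(info$upper[i], s_scale * 3))
        } else if (nm %in% c("k", "k_unid")) {
          rlog(0.03, 3)
        } else if (nm %in% c("u_free", "u_unid")) {
          rlog(0.3, 10)
        } else if (nm == "sigma_unid") {
          rlog(max(info$lower[i], s_scale / 30),
               min(info$upper[i], s_scale))
        } else if (nm == "mu_unid") {
          stats::runif(1, -s_scale / 3, s_scale / 3)
        } else {
          stats::runif(1, 0.02, 0.6)   # proportions q, p0, q_unid
        }
      }
      starts[[j + 1]] <- to_transformed(v, info)
    }
  }
  run_start <- function(th0) {
    opt <- try(stats::optim(th0, nll, method = "Nelder-Mead",
                            control = list(maxit = maxit,
                                           reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error") || opt$value >= 1e10) return(NULL)
    # polish the simplex endpoint with quasi-Newton steps: Nelder-Mead can
    # collapse prematurely, and the gradient polish lets distinct starts in
    # one basin agree to tight tolerance
    opt2 <- try(stats::optim(opt$par, nll, method = "BFGS",
                             control = list(maxit = 200, reltol = 1e-12)),
                silent = TRUE)
    if (!inherits(opt2, "try-error") && opt2$value < opt$value) opt <- opt2
    opt
  }
  best <- NULL; lls <- numeric(0)
  for (th0 in starts) {
    opt <- run_start(th0)
    if (is.null(opt)) next
    lls <- c(lls, -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all optimisation starts failed for model '", model, "'",
         call. = FALSE)
  reproduced <- function() sum(abs(lls - (-best$value)) < 1e-4) >=
    min(2L, n_starts)
  # a second round of restarts: each surviving endpoint is restarted from a
  # jittered copy of the incumbent optimum, mirroring the repeat-from-the-
  # previous-optimum search until the maximum is reproduced
  if (!reproduced() && n_starts > 1) {
    for (j in seq_len(n_starts - 1L)) {
      opt <- run_start(best$par + stats::rnorm(length(best$par), 0, 0.05))
      if (is.null(opt)) next
      lls <- c(lls, -opt$value)
      if (opt$value < best$value) best <- opt
    }
  }
  mle_vals <- from_transformed(best$par, info)
  k_par <- nrow(info)
  converged <- reproduced()
  structure(list(model = model, mle = build_dme_params(model, mle_vals),
                 mle_values = mle_vals, theta = best$par,
                 loglik = -best$value, n_params = k_par,
                 aic = 2 * k_par - 2 * (-best$value),
                 converged = converged, starts_used = length(lls),
                 data = data, config = config, par_info = info),
            class = "dme_fit")
}

#' @export
print.dme_fit <- function(x, ...) {
  cat(sprintf("DME fit [%s]: loglik = %.4f, AIC = %.4f (%d params, %s)\n",
              x$model, x$loglik, x$aic,
              x$n_params, if (x$converged) "converged" else "NOT converged"))
  print(round(x$mle_values, 6))
  invisible(x)
}

#' Profile-likelihood confidence interval for one DME parameter
#'
#' Scans the named parameter over a grid, re-maximising all other parameters
#' at each point, and locates by quadratic interpolation where the profile
#' log-likelihood falls `delta_ll` below the maximum. Sides where the profile
#' never drops below the target within the parameter's bounds are reported as
#' the bound itself with an `open` flag (e.g. a neutral-proportion CI running
#' to its boundary).
#'
#' @param fit a `"dme_fit"` object.
#' @param param parameter name (one of `names(fit$mle_values)`).
#' @param delta_ll profile drop; the default 2.5 matches the study
#'   convention, 1.92 is the standard chi-square(1) 95% value.
#' @param n_points grid points per side.
#' @param span_factor initial scan half-width as a multiple of the MLE scale
#'   (transformed units).
#' @param maxit re-maximisation iteration cap.
#' @return list with `low`, `high`, `open_low`, `open_high`, and the scanned
#'   `profile` (data frame of parameter value and profile log-likelihood).
#' @export
profile_ci <- function(fit, param, delta_ll = 2.5, n_points = 9L,
                       span_factor = 1.5, maxit = 300L) {
  stopifnot(inherits(fit, "dme_fit"), param %in% fit$par_info$name)
  info <- fit$par_info
  ip <- match(param, info$name)
  free <- setdiff(seq_len(nrow(info)), ip)
  prof_ll <- function(th_p) {
    nll_free <- function(th_f) {
      th <- numeric(nrow(info)); th[ip] <- th_p; th[free] <- th_f
      vals <- from_transformed(th, info)
      p <- try(build_dme_params(fit$model, vals), silent = TRUE)
      if (inherits(p, "try-error")) return(1e10)
      ll <- try(dme_data_loglik(fit$data, p, fit$config), silent = TRUE)
      if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
      -ll
    }
    if (length(free) == 0) return(-nll_free(numeric(0)))
    o <- try(stats::optim(fit$theta[free], nll_free,
                          method = "Nelder-Mead",
                          control = list(maxit = maxit)), silent = TRUE)
    if (inherits(o, "try-error")) return(-Inf)
    -o$value
  }
  target <- fit$loglik - delta_ll
  th_hat <- fit$theta[ip]
  width <- max(abs(th_hat) * 0.25, 0.5) * span_factor
  scan_side <- function(dir) {
    w <- width
    for (rep in 1:6) {
      grid <- th_hat + dir * seq(0, w, length.out = n_points + 1L)[-1]
      ll <- vapply(grid, prof_ll, numeric(1))
      if (any(ll < target)) {
        x <- c(th_hat, grid); l <- c(fit$loglik, ll)
        ord <- order(x)
        cross <- profile_crossing(x[ord], l[ord], target,
                                  if (dir < 0) "lower" else "upper")
        if (is.finite(cross)) return(list(val = cross, open = FALSE))
      }
      # transformed scale is unbounded; a very wide scan that never drops
      # means the natural-scale bound is effectively open on this side
      if (w > 25) return(list(val = dir * Inf, open = TRUE))
      w <- w * 2.5
    }
    list(val = dir * Inf, open = TRUE)
  }
  lo <- scan_side(-1); hi <- scan_side(+1)
  nat <- function(th_p, side) {
    if (!is.finite(th_p))
      return(if (th_p < 0) info$lower[ip] else info$upper[ip])
    th <- fit$theta; th[ip] <- th_p
    from_transformed(th, info)[[param]]
  }
  list(low = nat(lo$val), high = nat(hi$val),
       open_low = lo$open, open_high = hi$open)
}

#' Compare fitted DME models by AIC and likelihood-ratio tests
#'
#' Builds a comparison table: delta-AIC relative to a named baseline and,
#' for nested pairs (the SNM-only model is nested in both the Gaussian
#' unidentified-mutation model and the two-gamma model), a likelihood-ratio
#' test with degrees of freedom equal to the parameter-count difference.
#' Non-nested pairs get AIC only.
#'
#' @param fits a named or unnamed list of `"dme_fit"` objects fitted to the
#'   same data.
#' @param baseline model tag used as the delta-AIC (and LRT) reference;
#'   default `"snm_only"` if present, else the first fit.
#' @return data frame with columns `model`, `loglik`, `n_params`, `aic`,
#'   `delta_aic`, `lrt_df`, `lrt_p`.
#' @export
compare_models <- function(fits, baseline = NULL) {
  stopifnot(length(fits) >= 1)
  hashes <- vapply(fits, function(f)
    paste(class(f$data), digest_data(f$data), sep = ":"), character(1))
  if (length(unique(hashes)) != 1)
    stop("all fits must share identical data", call. = FALSE)
  tags <- vapply(fits, `[[`, character(1), "model")
  if (is.null(baseline))
    baseline <- if ("snm_only" %in% tags) "snm_only" else tags[1]
  ib <- match(baseline, tags)
  if (is.na(ib)) stop("baseline model not among the fits", call. = FALSE)
  base <- fits[[ib]]
  nested <- list(gaussian_unid = "snm_only", two_gamma = "snm_only")
  out <- lapply(fits, function(f) {
    d_aic <- f$aic - base$aic
    lrt_df <- NA_integer_; lrt_p <- NA_real_
    if (f$model == base$model) {
      lrt_df <- 0L; lrt_p <- 1
    } else if (identical(nested[[f$model]], base$model)) {
      lrt_df <- f$n_params - base$n_params
      stat <- max(2 * (f$loglik - base$loglik), 0)
      lrt_p <- stats::pchisq(stat, lrt_df, lower.tail = FALSE)
    } else if (identical(nested[[base$model]], f$model)) {
      lrt_df <- base$n_params - f$n_params
      stat <- max(2 * (base$loglik - f$loglik), 0)
      lrt_p <- stats::pchisq(stat, lrt_df, lower.tail = FALSE)
    }
    data.frame(model = f$model, loglik = f$loglik, n_params = f$n_params,
               aic = f$aic, delta_aic = d_aic, lrt_df = lrt_df,
               lrt_p = lrt_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# order-insensitive lightweight data fingerprint for compare_models
digest_data <- function(data) {
  if (is.data.frame(data)) {
    paste(nrow(data), format(sum(data$s_hat), digits = 12),
          format(sum(data$se_s), digits = 12))
  } else {
    paste(nrow(data$diffs), format(sum(data$diffs$d_value), digits = 12))
  }
}
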