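#' Experiment-level ("general") parameters
#'
#' The parameters shared across all strains in one growth-rate experiment.
#' `sigma_nonpetite` and `sigma_petite` are the *pooled* colony SDs
#' (biological variation plus iid per-colony measurement noise — the two are
#' not separately identifiable). `sigma_plate` and `sigma_well` are the batch
#' effect SDs; they cancel exactly from the pairwise-difference likelihood and
#' are carried only for simulation or reporting (NA when estimated from
#' differences).
#'
#' @param mu_anc mean non-petite growth rate of the ancestral/reference strain
#'   (per hour, ln-area units).
#' @param mu_petite mean growth rate of petite colonies (per hour); must be
#'   below `mu_anc`.
#' @param rho_ref petite proportion of the reference strain, in `[0, 1]`.
#' @param sigma_nonpetite pooled non-petite colony growth-rate SD (per hour).
#' @param sigma_petite pooled petite colony growth-rate SD (per hour).
#' @param sigma_plate,sigma_well batch-effect SDs (per hour); may be `NA`.
#' @return an object of class `"general_params"`.
#' @export
general_params <- function(mu_anc, mu_petite, rho_ref,
                           sigma_nonpetite, sigma_petite,
                           sigma_plate = NA_real_, sigma_well = NA_real_) {
  if (!is.finite(mu_anc) || !is.finite(mu_petite))
    stop("'mu_anc' and 'mu_petite' must be finite", call. = FALSE)
  if (mu_petite >= mu_anc)
    stop("'mu_petite' must be below 'mu_anc'", call. = FALSE)
  if (rho_ref < 0 || rho_ref > 1)
    stop("'rho_ref' must lie in [0, 1]", call. = FALSE)
  if (sigma_nonpetite <= 0 || sigma_petite <= 0)
    stop("colony-level sigma parameters must be positive", call. = FALSE)
  if (!is.na(sigma_plate) && sigma_plate < 0)
    stop("'sigma_plate' must be >= 0", call. = FALSE)
  if (!is.na(sigma_well) && sigma_well < 0)
    stop("'sigma_well' must be >= 0", call. = FALSE)
  structure(list(mu_anc = mu_anc, mu_petite = mu_petite, rho_ref = rho_ref,
                 sigma_nonpetite = sigma_nonpetite,
                 sigma_petite = sigma_petite,
                 sigma_plate = sigma_plate, sigma_well = sigma_well),
            class = "general_params")
}

#' @export
print.general_params <- function(x, ...) {
  cat("General (experiment-level) parameters\n")
  for (f in names(x)) cat(sprintf("  %-16s %g\n", f, x[[f]]))
  invisible(x)
}

# log density matrix of the four-component difference mixture:
# rows = differences d, columns = selection coefficients s.
# Components (weights, means, variances), with mu_i = mu_anc (1 + s) and the
# reference at mu_anc:
#   (1-rho_i)(1-rho_ref)  N(mu_i - mu_anc,        2 sigma_np^2)
#   (1-rho_i) rho_ref     N(mu_i - mu_petite,     sigma_np^2 + sigma_pet^2)
#   rho_i (1-rho_ref)     N(mu_petite - mu_anc,   sigma_np^2 + sigma_pet^2)
#   rho_i rho_ref         N(0,                    2 sigma_pet^2)
diff_loglik_matrix <- function(d, s, rho_i, general) {
  cmp <- diff_mixture_components(d, s, general)
  log((1 - rho_i) * (1 - general$rho_ref) * cmp$m1 +
        (1 - rho_i) * general$rho_ref * cmp$m2 +
        rho_i * (1 - general$rho_ref) * cmp$c3 +
        rho_i * general$rho_ref * cmp$c4)
}

# the four mixture component densities, separated so that scans over rho can
# reuse the expensive s-dependent Gaussian evaluations
diff_mixture_components <- function(d, s, general) {
  g <- general
  mu_i <- g$mu_anc * (1 + s)                      # length(s)
  sd1 <- sqrt(2) * g$sigma_nonpetite
  sd2 <- sqrt(g$sigma_nonpetite^2 + g$sigma_petite^2)
  sd4 <- sqrt(2) * g$sigma_petite
  # components 3 and 4 do not depend on s
  list(m1 = outer(d, mu_i - g$mu_anc,
                  function(dd, mm) stats::dnorm(dd, mm, sd1)),
       m2 = outer(d, mu_i - g$mu_petite,
                  function(dd, mm) stats::dnorm(dd, mm, sd2)),
       c3 = stats::dnorm(d, g$mu_petite - g$mu_anc, sd2),
       c4 = stats::dnorm(d, 0, sd4))
}

#' Log-likelihood of growth-rate differences under the petite mixture
#'
#' The within-field difference `D` between an MA colony and a reference colony
#' is free of plate and well batch effects and follows a four-component
#' Gaussian mixture indexed by which of the two colonies are petite. Weights
#' are products of the strain's petite proportion `rho_i` and the reference's
#' `rho_ref`; the non-petite MA mean is `mu_anc * (1 + s)`.
#'
#' @param d numeric vector of growth-rate differences (per hour).
#' @param s strain selection coefficient (dimensionless).
#' @param rho_i strain petite proportion in `[0, 1]`.
#' @param general a [general_params()] object.
#' @return total log-likelihood over `d` (a scalar).
#' @export
diff_loglik <- function(d, s, rho_i, general) {
  if (any(!is.finite(d))) stop("non-finite difference values", call. = FALSE)
  if (rho_i < 0 || rho_i > 1) stop("'rho_i' must lie in [0, 1]", call. = FALSE)
  sum(diff_loglik_matrix(d, s, rho_i, general))
}

#' Single-Gaussian (no-petite) difference log-likelihood
#'
#' The null model for the mixture-vs-single-Gaussian likelihood-ratio test:
#' all petite proportions fixed at zero, so `D ~ N(mu_anc * s, 2 sigma_np^2)`.
#'
#' @inheritParams diff_loglik
#' @return total log-likelihood over `d`.
#' @export
single_gaussian_loglik <- function(d, s, general) {
  sum(stats::dnorm(d, general$mu_anc * s,
                   sqrt(2) * general$sigma_nonpetite, log = TRUE))
}

#' Log-likelihood of petite-only control colonies
#'
#' Petite-control samples contain only petite-distributed colonies and
#' calibrate `mu_petite` and `sigma_petite`. By default their rates are
#' modelled without batch terms; `batch_var` adds plate + well variance
#' inflation if desired.
#'
#' @param rates numeric vector of petite-control colony growth rates.
#' @param general a [general_params()] object.
#' @param batch_var extra variance added to `sigma_petite^2` (default 0).
#' @return total log-likelihood over `rates`.
#' @export
petite_control_loglik <- function(rates, general, batch_var = 0) {
  if (length(rates) == 0)
    stop("empty petite-control set: supply 'mu_petite'/'sigma_petite' ",
         "externally instead", call. = FALSE)
  sum(stats::dnorm(rates, general$mu_petite,
                   sqrt(general$sigma_petite^2 + batch_var), log = TRUE))
}

#' Pair MA and reference colonies within imaging fields
#'
#' Within each (plate, well, field), forms `min(#MA, #reference)` random pairs
#' without replacement and returns the MA-minus-reference growth-rate
#' differences. Fields lacking one class contribute no pairs.
#'
#' @param colonies a colony table (data frame) with columns `strain_id`,
#'   `plate`, `well`, `field`, `is_reference` (0/1) and `growth_rate`.
#' @param seed integer seed for the pairing randomisation; recorded in the
#'   output's `pairing_seed` attribute.
#' @return a data frame with columns `strain_id`, `plate`, `well`, `field`,
#'   `d_value` (one row per pair).
#' @export
pair_colonies <- function(colonies, seed = 1L) {
  req <- c("strain_id", "plate", "well", "field", "is_reference",
           "growth_rate")
  stopifnot(is.data.frame(colonies), all(req %in% names(colonies)))
  if (!any(colonies$is_reference == 1) || !any(colonies$is_reference == 0))
    stop("colony table must contain both MA and reference colonies",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  key <- interaction(colonies$plate, colonies$well, colonies$field,
                     drop = TRUE)
  out <- vector("list", nlevels(key))
  i <- 0L
  for (grp in split(seq_len(nrow(colonies)), key)) {
    sub <- colonies[grp, ]
    ma <- sub[sub$is_reference == 0, ]
    rf <- sub[sub$is_reference == 1, ]
    npair <- min(nrow(ma), nrow(rf))
    if (npair == 0L) next
    mi <- sample.int(nrow(ma), npair)
    ri <- sample.int(nrow(rf), npair)
    i <- i + 1L
    out[[i]] <- data.frame(strain_id = ma$strain_id[mi],
                           plate = ma$plate[1], well = ma$well[1],
                           field = ma$field[1],
                           d_value = ma$growth_rate[mi] - rf$growth_rate[ri],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(i)])
  if (is.null(res))
    res <- data.frame(strain_id = character(), plate = character(),
                      well = character(), field = character(),
                      d_value = numeric())
  rownames(res) <- NULL
  attr(res, "pairing_seed") <- as.integer(seed)
  res
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
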