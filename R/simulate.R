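#' Simulation design for a synthetic growth-rate experiment
#'
#' Describes the block structure of a microcolony growth-rate assay: how many
#' plates, how many wells per strain per plate, target colony counts per well,
#' imaging fields per well, and the numbers of MA, control and petite-control
#' samples. Presets mirror the two study designs: a 2000-generation style
#' layout (each MA strain in a single well, 14 plates) and an msh3-delta
#' style layout (18 strains x 3 wells x 10 plates with 9 ancestor wells per
#' plate).
#'
#' @param n_plates number of experimental plates.
#' @param wells_per_strain_per_plate wells occupied by each MA strain on each
#'   plate it appears on.
#' @param ma_colonies_per_well target MA-strain colonies per well.
#' @param ref_colonies_per_well target reference colonies per well.
#' @param fields_per_well imaging fields per well (colonies are split across
#'   fields).
#' @param n_ma_strains number of MA strains.
#' @param n_control_strains unmarked ancestor-derived control strains
#'   (simulated with zero mutational effect).
#' @param n_petite_control_samples petite-only control wells.
#' @param exact_counts if `TRUE`, wells get exactly the target colony counts;
#'   otherwise counts are Poisson around the target (field-to-field
#'   variation).
#' @return an object of class `"simulation_design"`.
#' @export
simulation_design <- function(n_plates = 14, wells_per_strain_per_plate = 1,
                              ma_colonies_per_well = 500,
                              ref_colonies_per_well = 500,
                              fields_per_well = 10,
                              n_ma_strains = 70, n_control_strains = 2,
                              n_petite_control_samples = 6,
                              exact_counts = FALSE) {
  counts <- c(n_plates, wells_per_strain_per_plate, ma_colonies_per_well,
              ref_colonies_per_well, fields_per_well, n_ma_strains)
  if (any(counts < 1)) stop("all design counts must be >= 1", call. = FALSE)
  if (n_control_strains < 0 || n_petite_control_samples < 0)
    stop("control counts must be >= 0", call. = FALSE)
  structure(list(n_plates = n_plates,
                 wells_per_strain_per_plate = wells_per_strain_per_plate,
                 ma_colonies_per_well = ma_colonies_per_well,
                 ref_colonies_per_well = ref_colonies_per_well,
                 fields_per_well = fields_per_well,
                 n_ma_strains = n_ma_strains,
                 n_control_strains = n_control_strains,
                 n_petite_control_samples = n_petite_control_samples,
                 exact_counts = isTRUE(exact_counts)),
            class = "simulation_design")
}

#' Simulation noise/mean parameters
#'
#' The generative counterpart of [general_params()], keeping the per-colony
#' measurement noise (`sigma_col`) separate from the biological colony SDs
#' (they are pooled during estimation, where they are not separately
#' identifiable).
#'
#' @param mu_anc ancestor non-petite mean growth rate (per hour).
#' @param mu_petite petite mean growth rate (per hour).
#' @param sigma_nonpetite_bio,sigma_petite_bio biological colony SDs.
#' @param sigma_col iid per-colony measurement noise SD.
#' @param sigma_plate,sigma_well batch-effect SDs.
#' @param rho_ref reference-strain petite proportion.
#' @return an object of class `"sim_params"`.
#' @export
sim_params <- function(mu_anc = 0.55, mu_petite = 0.35,
                       sigma_nonpetite_bio = 0.015, sigma_petite_bio = 0.025,
                       sigma_col = 0.01, sigma_plate = 0.01,
                       sigma_well = 0.005, rho_ref = 0.1) {
  sig <- c(sigma_nonpetite_bio, sigma_petite_bio, sigma_col, sigma_plate,
           sigma_well)
  if (any(sig < 0)) stop("sigma parameters must be >= 0", call. = FALSE)
  if (rho_ref < 0 || rho_ref > 1)
    stop("'rho_ref' must lie in [0, 1]", call. = FALSE)
  structure(list(mu_anc = mu_anc, mu_petite = mu_petite,
                 sigma_nonpetite_bio = sigma_nonpetite_bio,
                 sigma_petite_bio = sigma_petite_bio, sigma_col = sigma_col,
                 sigma_plate = sigma_plate, sigma_well = sigma_well,
                 rho_ref = rho_ref),
            class = "sim_params")
}

# pooled estimation-scale parameters implied by simulation parameters
#' Convert simulation parameters to pooled estimation-scale parameters
#' @param sp a [sim_params()] object.
#' @return the corresponding [general_params()] with pooled colony SDs.
#' @export
as_general_params <- function(sp) {
  general_params(mu_anc = sp$mu_anc, mu_petite = sp$mu_petite,
                 rho_ref = sp$rho_ref,
                 sigma_nonpetite = sqrt(sp$sigma_nonpetite_bio^2 +
                                          sp$sigma_col^2),
                 sigma_petite = sqrt(sp$sigma_petite_bio^2 + sp$sigma_col^2),
                 sigma_plate = sp$sigma_plate, sigma_well = sp$sigma_well)
}

#' Draw per-strain mutational truths from a DME model
#'
#' For each MA strain, draws a Poisson number of mutations with the model's
#' SNM Poisson mean, each mutation's effect from the reflected gamma (sign
#' positive with probability `q`), plus the model's unidentified component
#' (a second compound Poisson for `two_gamma`, a per-strain Gaussian for
#' `gaussian_unid`). Control strains get zero total effect. Each strain's
#' true petite proportion is Beta-distributed around `rho_ref` to reproduce
#' the across-strain petite variation seen in real assays.
#'
#' @param dme a [dme_params()] object.
#' @param design a [simulation_design()] object.
#' @param config a [fit_config()] object (supplies `m_diploid`).
#' @param rho_ref centre of the petite-proportion distribution.
#' @param rho_concentration Beta concentration (`shape1 + shape2`); larger
#'   means less across-strain petite variation. `Inf` fixes all strains at
#'   `rho_ref`.
#' @return a data frame (one row per strain, controls last) with columns
#'   `strain_id`, `is_control`, `n_mutations`, `total_effect`, `true_rho`,
#'   plus a list-column `per_mutation_effects`.
#' @export
draw_strain_truths <- function(dme, design, config = fit_config(),
                               rho_ref = 0.1, rho_concentration = 30) {
  stopifnot(inherits(dme, "dme_params"),
            inherits(design, "simulation_design"))
  n_ma <- design$n_ma_strains
  n_ctl <- design$n_control_strains
  u_snm <- snm_poisson_mean(dme, config)
  draw_reflected_gamma <- function(n, k, m, q) {
    if (n == 0) return(numeric(0))
    sign <- ifelse(stats::runif(n) < q, 1, -1)
    sign * stats::rgamma(n, shape = k, scale = m / k)
  }
  n_mut <- stats::rpois(n_ma, u_snm)
  effects <- lapply(n_mut, draw_reflected_gamma, k = dme$k, m = dme$m,
                    q = dme$q)
  total <- vapply(effects, sum, numeric(1))
  if (dme$model == "two_gamma") {
    n2 <- stats::rpois(n_ma, dme$u_unid)
    eff2 <- lapply(n2, draw_reflected_gamma, k = dme$k_unid, m = dme$m_unid,
                   q = dme$q_unid)
    n_mut <- n_mut + n2
    effects <- Map(c, effects, eff2)
    total <- total + vapply(eff2, sum, numeric(1))
  } else if (dme$model == "gaussian_unid") {
    total <- total + stats::rnorm(n_ma, dme$mu_unid, dme$sigma_unid)
  }
  n_all <- n_ma + n_ctl
  rho <- if (is.infinite(rho_concentration)) rep(rho_ref, n_all) else
    stats::rbeta(n_all, rho_ref * rho_concentration,
                 (1 - rho_ref) * rho_concentration)
  out <- data.frame(
    strain_id = c(sprintf("MA%03d", seq_len(n_ma)),
                  if (n_ctl) sprintf("CTL%02d", seq_len(n_ctl))),
    is_control = rep(c(FALSE, TRUE), c(n_ma, n_ctl)),
    n_mutations = c(n_mut, rep(0L, n_ctl)),
    total_effect = c(total, rep(0, n_ctl)),
    true_rho = rho,
    stringsAsFactors = FALSE)
  out$per_mutation_effects <- c(effects,
                                rep(list(numeric(0)), n_ctl))
  out
}

#' Simulate a colony-level growth-rate table
#'
#' Lays strains out on plates/wells/fields per the design and draws each
#' colony's observed growth rate as: genetic mean (petite with its strain's
#' probability, using the petite mean/SD, else `mu_anc * (1 + s)` with the
#' non-petite SD) + a shared plate effect + a shared well effect + iid colony
#' noise. Reference colonies in a well share that well's batch draws with the
#' MA colonies, so within-well differences cancel the batch terms exactly.
#' Petite-control samples contain only petite-distributed colonies (no
#' batch terms, matching how they are modelled during estimation).
#'
#' @param truths data frame from [draw_strain_truths()].
#' @param sp a [sim_params()] object.
#' @param design a [simulation_design()] object.
#' @return a data frame with columns `strain_id`, `plate`, `well`, `field`,
#'   `is_reference` (0/1), `growth_rate`, `true_is_petite`, plus an attribute
#'   `petite_controls`: a numeric vector of petite-control colony rates.
#' @export
simulate_colonies <- function(truths, sp, design) {
  stopifnot(inherits(sp, "sim_params"), inherits(design, "simulation_design"))
  n_strains <- nrow(truths)
  # strains are distributed round-robin across plates; each strain occupies
  # wells_per_strain_per_plate wells on each plate it is assigned to
  wpp <- design$wells_per_strain_per_plate
  if (wpp >= 2) {
    # msh3-delta style: every strain on every plate
    assign_plates <- rep(list(seq_len(design$n_plates)), n_strains)
  } else {
    assign_plates <- lapply(seq_len(n_strains), function(i)
      ((i - 1) %% design$n_plates) + 1)
  }
  plate_eff <- stats::rnorm(design$n_plates, 0, sp$sigma_plate)
  rows <- list(); ri <- 0L
  count <- function(target) {
    if (design$exact_counts) target else stats::rpois(1, target)
  }
  per_field_ma <- design$ma_colonies_per_well / design$fields_per_well
  per_field_ref <- design$ref_colonies_per_well / design$fields_per_well
  for (i in seq_len(n_strains)) {
    s_i <- truths$total_effect[i]
    rho_i <- truths$true_rho[i]
    for (pl in assign_plates[[i]]) {
      for (w in seq_len(wpp)) {
        well_id <- sprintf("%s_p%02d_w%d", truths$strain_id[i], pl, w)
        well_eff <- stats::rnorm(1, 0, sp$sigma_well)
        batch <- plate_eff[pl] + well_eff
        for (fd in seq_len(design$fields_per_well)) {
          n_ma <- count(per_field_ma)
          n_ref <- count(per_field_ref)
          draw <- function(n, rho, s) {
            if (n == 0) return(NULL)
            pet <- stats::runif(n) < rho
            mu <- ifelse(pet, sp$mu_petite, sp$mu_anc * (1 + s))
            sd_bio <- ifelse(pet, sp$sigma_petite_bio, sp$sigma_nonpetite_bio)
            g <- stats::rnorm(n, mu, sd_bio) + batch +
              stats::rnorm(n, 0, sp$sigma_col)
            list(g = g, pet = pet)
          }
          ma <- draw(n_ma, rho_i, s_i)
          rf <- draw(n_ref, sp$rho_ref, 0)
          if (!is.null(ma)) {
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              strain_id = truths$strain_id[i], plate = sprintf("P%02d", pl),
              well = well_id, field = sprintf("F%02d", fd),
              is_reference = 0L, growth_rate = ma$g,
              true_is_petite = ma$pet, stringsAsFactors = FALSE)
          }
          if (!is.null(rf)) {
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
              strain_id = "REF", plate = sprintf("P%02d", pl),
              well = well_id, field = sprintf("F%02d", fd),
              is_reference = 1L, growth_rate = rf$g,
              true_is_petite = rf$pet, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # petite-only control samples
  n_pc <- design$n_petite_control_samples
  pc <- if (n_pc > 0) {
    n_col <- sum(vapply(seq_len(n_pc), function(i)
      count(design$ma_colonies_per_well), numeric(1)))
    stats::rnorm(n_col, sp$mu_petite,
                 sqrt(sp$sigma_petite_bio^2 + sp$sigma_col^2))
  } else numeric(0)
  attr(out, "petite_controls") <- pc
  out
}

#' Simulate a per-colony log-area time series
#'
#' ln(area) is flat at `init_log_area` until `lag` hours, then linear with
#' the given slope, plus iid Gaussian noise. Lag is a hard changepoint; it
#' exists to exercise the window-based slope fitter, not to model lag biology.
#'
#' @param rate per-hour ln-area slope after the lag.
#' @param lag lag duration (hours).
#' @param init_log_area starting ln(area).
#' @param n_timepoints number of hourly timepoints (>= 2).
#' @param noise_sd iid measurement noise SD (ln-area units).
#' @param dt timepoint spacing in hours (default 1).
#' @return a data frame with columns `time` (hours) and `log_area`.
#' @export
simulate_timeseries <- function(rate, lag = 0, init_log_area = 5,
                                n_timepoints = 11, noise_sd = 0, dt = 1) {
  stopifnot(n_timepoints >= 2, noise_sd >= 0, lag >= 0, dt > 0)
  t <- dt * (seq_len(n_timepoints) - 1)
  y <- init_log_area + rate * pmax(t - lag, 0)
  if (noise_sd > 0) y <- y + stats::rnorm(n_timepoints, 0, noise_sd)
  data.frame(time = t, log_area = y)
}
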