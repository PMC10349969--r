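# Pipeline orchestration: simulate -> fit strains -> fit DME -> report,
# with explicit seeds and a JSON run manifest. The numbered scripts under
# analysis/ are thin drivers over these functions.

#' Named simulation presets
#'
#' `ma2000`: 70 MA strains + 2 unmarked controls, one well per strain across
#' 14 plates, ~500 MA + ~500 reference colonies per well, 6 petite-control
#' samples; generative truth is the fitted Gaussian-model DME
#' (k = 5.5e-2, m = 4.1e-3, q = 6%, p0 = 5.9%, mu_unid = -3.3e-3,
#' sigma_unid = 5.5e-3; mean SNM count 8 per diploid parent).
#' `msh3d`: 18 strains x 3 wells x 10 plates; generative truth is a
#' single-DME summary of the slippage-repair-deficient lines (mean effect
#' -0.0024 per 100 generations spread over ~1.8 SSR mutations per
#' 200-generation strain).
#' `tiny`: 10 strains, 50 colonies per well, 2 plates — an end-to-end smoke
#' configuration.
#'
#' @param preset one of `"ma2000"`, `"msh3d"`, `"tiny"`.
#' @return list with `design` ([simulation_design()]), `dme` ([dme_params()]),
#'   `sim` ([sim_params()]), `config` ([fit_config()]).
#' @export
pipeline_preset <- function(preset = c("ma2000", "msh3d", "tiny")) {
  preset <- match.arg(preset)
  if (preset == "ma2000") {
    list(design = simulation_design(n_plates = 14,
                                    wells_per_strain_per_plate = 1,
                                    ma_colonies_per_well = 500,
                                    ref_colonies_per_well = 500,
                                    fields_per_well = 10,
                                    n_ma_strains = 70,
                                    n_control_strains = 2,
                                    n_petite_control_samples = 6),
         dme = dme_params("gaussian_unid", k = 5.5e-2, m = 4.1e-3,
                          q = 0.06, p0 = 0.059, mu_unid = -3.3e-3,
                          sigma_unid = 5.5e-3),
         sim = sim_params(),
         config = fit_config(m_diploid = 8))
  } else if (preset == "msh3d") {
    # mean per-SSR-mutation effect ~ -0.00267 (0.0024 per 100 gen over
    # 1.8 mutations per 200 gen); leptokurtic single DME with that mean:
    # u * m * (2q - 1) = 1.8 * m * (2q - 1) matching -0.0024 * 2
    list(design = simulation_design(n_plates = 10,
                                    wells_per_strain_per_plate = 3,
                                    ma_colonies_per_well = 500,
                                    ref_colonies_per_well = 500,
                                    fields_per_well = 10,
                                    n_ma_strains = 18,
                                    n_control_strains = 1,
                                    n_petite_control_samples = 3),
         dme = dme_params("single_dme", k = 0.1, m = 3.335e-3, q = 0.1,
                          u_free = 1.8),
         sim = sim_params(),
         config = fit_config(m_diploid = 0))
  } else {
    list(design = simulation_design(n_plates = 2,
                                    wells_per_strain_per_plate = 1,
                                    ma_colonies_per_well = 50,
                                    ref_colonies_per_well = 50,
                                    fields_per_well = 2,
                                    n_ma_strains = 10,
                                    n_control_strains = 1,
                                    n_petite_control_samples = 2),
         dme = dme_params("gaussian_unid", k = 5.5e-2, m = 4.1e-3,
                          q = 0.06, p0 = 0.059, mu_unid = -3.3e-3,
                          sigma_unid = 5.5e-3),
         sim = sim_params(),
         config = fit_config(m_diploid = 8))
  }
}

#' Write colony and truth tables for a named preset
#'
#' @param preset preset name (see [pipeline_preset()]).
#' @param seed integer seed.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list of written file paths (`colonies`, `truths`,
#'   `petite_controls`).
#' @export
make_fixture <- function(preset = "tiny", seed = 1L, out_dir = ".") {
  ps <- pipeline_preset(preset)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  truths <- draw_strain_truths(ps$dme, ps$design, ps$config,
                               rho_ref = ps$sim$rho_ref)
  colonies <- simulate_colonies(truths, ps$sim, ps$design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f_col <- file.path(out_dir, sprintf("colonies_%s.csv", preset))
  f_tru <- file.path(out_dir, sprintf("truths_%s.csv", preset))
  f_pet <- file.path(out_dir, sprintf("petite_controls_%s.csv", preset))
  utils::write.csv(colonies, f_col, row.names = FALSE)
  tr <- truths[, c("strain_id", "is_control", "n_mutations", "total_effect",
                   "true_rho")]
  utils::write.csv(tr, f_tru, row.names = FALSE)
  utils::write.csv(data.frame(growth_rate = attr(colonies,
                                                 "petite_controls")),
                   f_pet, row.names = FALSE)
  invisible(list(colonies = f_col, truths = f_tru, petite_controls = f_pet))
}

#' Run the simulate / fit-strains / fit-dme / report pipeline
#'
#' Executes the selected stages in order against a preset (or an explicit
#' configuration), writing per-stage CSV/JSON artifacts and a JSON run
#' manifest to `out_dir`. Stages are pure functions of (inputs, config,
#' seeds): re-running with the same seed reproduces all outputs.
#'
#' @param preset preset name passed to [pipeline_preset()], or a list with
#'   the same structure.
#' @param seed integer master seed (stage seeds are derived from it).
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("simulate", "fit_strains", "fit_dme", "report")`, executed in
#'   canonical order.
#' @param dme_models model tags to fit in the `fit_dme` stage.
#' @param n_starts optimisation starts for the DME fits.
#' @param fit_grid_n FFT grid size used during iterative fitting (a coarser
#'   grid than the reporting default is ample once the per-strain error SD
#'   dominates the density's smoothness).
#' @return (invisibly) the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(preset = "tiny", seed = 1L, out_dir = "results",
                         stages = c("simulate", "fit_strains", "fit_dme",
                                    "report"),
                         dme_models = c("snm_only", "gaussian_unid"),
                         n_starts = 4L, fit_grid_n = 2^13) {
  t_start <- Sys.time()
  stages <- match.arg(stages, several.ok = TRUE)
  ps <- if (is.character(preset)) pipeline_preset(preset) else preset
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  manifest <- list(preset = if (is.character(preset)) preset else "custom",
                   seed = seed, stages = stages,
                   package_version = as.character(
                     utils::packageVersion("madfe")),
                   started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = list(), status = "running")
  log_stage <- function(name) message(sprintf("[madfe] stage: %s", name))
  fail <- function(stage, err) {
    manifest$status <<- paste0("failed:", stage)
    manifest$error <<- conditionMessage(err)
    write_manifest(manifest, out_dir)
    stop(err)
  }

  colonies <- NULL; petites <- NULL; truths <- NULL
  if ("simulate" %in% stages) {
    log_stage("simulate")
    tryCatch({
      old <- .Random.seed_save()
      set.seed(seed)
      truths <- draw_strain_truths(ps$dme, ps$design, ps$config,
                                   rho_ref = ps$sim$rho_ref)
      colonies <- simulate_colonies(truths, ps$sim, ps$design)
      petites <- attr(colonies, "petite_controls")
      .Random.seed_restore(old)
      utils::write.csv(colonies, file.path(out_dir, "colonies.csv"),
                       row.names = FALSE)
      utils::write.csv(
        truths[, c("strain_id", "is_control", "n_mutations", "total_effect",
                   "true_rho")],
        file.path(out_dir, "truths.csv"), row.names = FALSE)
      utils::write.csv(data.frame(growth_rate = petites),
                       file.path(out_dir, "petite_controls.csv"),
                       row.names = FALSE)
      manifest$outputs$simulate <- c("colonies.csv", "truths.csv",
                                      "petite_controls.csv")
    }, error = function(e) fail("simulate", e))
  }

  estimates <- NULL
  if ("fit_strains" %in% stages) {
    log_stage("fit_strains")
    tryCatch({
      if (is.null(colonies)) {
        colonies <- utils::read.csv(file.path(out_dir, "colonies.csv"))
        petites <- utils::read.csv(
          file.path(out_dir, "petite_controls.csv"))$growth_rate
      }
      diffs <- pair_colonies(colonies, seed = seed + 1L)
      fit <- estimate_strain_effects(
        diffs, petites, init = as_general_params(ps$sim),
        n_starts = 2L, seed = seed + 2L)
      estimates <- classify_significance(fit$estimates)
      estimates$pairing_seed <- attr(diffs, "pairing_seed")
      utils::write.csv(estimates,
                       file.path(out_dir, "strain_estimates.csv"),
                       row.names = FALSE)
      jsonlite::write_json(unclass(fit$general),
                           file.path(out_dir, "general_params.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$outputs$fit_strains <- c("strain_estimates.csv",
                                         "general_params.json")
    }, error = function(e) fail("fit_strains", e))
  }

  fits <- NULL
  if ("fit_dme" %in% stages) {
    log_stage("fit_dme")
    tryCatch({
      if (is.null(estimates))
        estimates <- utils::read.csv(file.path(out_dir,
                                               "strain_estimates.csv"))
      est <- estimates[!estimates$flagged,
                       c("s_hat", "se_s"), drop = FALSE]
      cfg <- fit_config(m_diploid = ps$config$m_diploid,
                        grid_n = fit_grid_n)
      fits <- lapply(dme_models, function(mtag)
        fit_model(est, mtag, cfg, n_starts = n_starts, seed = seed + 3L))
      names(fits) <- dme_models
      for (mtag in dme_models) {
        f <- fits[[mtag]]
        jsonlite::write_json(
          list(model = f$model, mle = as.list(f$mle_values),
               loglik = f$loglik, aic = f$aic,
               converged = f$converged),
          file.path(out_dir, sprintf("dme_fit_%s.json", mtag)),
          auto_unbox = TRUE, digits = NA)
      }
      manifest$outputs$fit_dme <- sprintf("dme_fit_%s.json", dme_models)
    }, error = function(e) fail("fit_dme", e))
  }

  if ("report" %in% stages && !is.null(fits) && length(fits) > 1) {
    log_stage("report")
    tryCatch({
      cmp <- compare_models(fits)
      utils::write.csv(cmp, file.path(out_dir, "model_comparison.csv"),
                       row.names = FALSE)
      best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
      tails <- data.frame(
        quantity = c("neg_tail_gt_1e-6_pct", "neg_tail_gt_0.01_pct",
                     "both_tail_gt_1e-6_pct"),
        value = c(100 * tail_mass(best$mle, 1e-6, "negative"),
                  100 * tail_mass(best$mle, 0.01, "negative"),
                  100 * tail_mass(best$mle, 1e-6, "both")))
      utils::write.csv(tails, file.path(out_dir, "tail_masses.csv"),
                       row.names = FALSE)
      manifest$outputs$report <- c("model_comparison.csv",
                                    "tail_masses.csv")
    }, error = function(e) fail("report", e))
  }

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file with optional `design`, `sim`, `dme` and `config`
#' sections (fields as in [simulation_design()], [sim_params()],
#' [dme_params()] and [fit_config()]); unspecified fields fall back to a
#' preset's values.
#'
#' @param path YAML file path.
#' @param base preset name supplying defaults (default `"tiny"`).
#' @return a preset-structured list usable as `run_pipeline(preset = ...)`.
#' @export
read_pipeline_config <- function(path, base = "tiny") {
  ps <- pipeline_preset(base)
  y <- yaml::read_yaml(path)
  merge_into <- function(ctor, current, new) {
    cur <- unclass(current)
    cur[names(new)] <- new
    do.call(ctor, cur)
  }
  if (!is.null(y$design))
    ps$design <- merge_into(simulation_design,
                            ps$design[setdiff(names(ps$design), NULL)],
                            y$design)
  if (!is.null(y$sim)) ps$sim <- merge_into(sim_params, ps$sim, y$sim)
  if (!is.null(y$config))
    ps$config <- merge_into(fit_config, ps$config, y$config)
  if (!is.null(y$dme)) ps$dme <- do.call(dme_params, y$dme)
  ps
}
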