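#!/usr/bin/env Rscript
# Stage 3: fit distribution-of-mutational-effects models to the per-strain
# estimates by maximum likelihood. The per-strain effect density under each
# model is computed by characteristic functions and inverse FFT, convolved
# with each strain's estimation-error Gaussian, and the SNM-only and
# Gaussian-unidentified variants are fitted from multiple starts.
#
# Reads results/strain_estimates.csv (run 02_fit_strains.R first); writes
# results/dme_fit_<model>.json

library(madfe)

seed <- 1L
ps <- pipeline_preset("ma2000")
run_pipeline(ps, seed = seed, out_dir = "results", stages = "fit_dme")

for (tag in c("snm_only", "gaussian_unid")) {
  f <- jsonlite::read_json(sprintf("results/dme_fit_%s.json", tag),
                           simplifyVector = TRUE)
  cat(sprintf("%-14s loglik %.2f  AIC %.2f  converged %s\n",
              tag, f$loglik, f$aic, f$converged))
  cat("  MLE:", paste(sprintf("%s=%.3g", names(f$mle), unlist(f$mle)),
                      collapse = ", "), "\n")
}
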