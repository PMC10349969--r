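#!/usr/bin/env Rscript
# Stage 1: simulate a 2000-generation-style microcolony growth-rate
# experiment. 70 MA strains (plus 2 unmarked ancestor controls) are laid out
# one well each across 14 plates, with a GFP-reference subpopulation in every
# well and petite-only control samples. Strain net mutational effects are
# drawn from the Gaussian-unidentified DME at its fitted parameter values.
# Colony counts per well are scaled to 200 (from the assay's ~500) to keep
# this driver interactive; rerun with full counts for final figures.
#
# Writes results/colonies.csv, results/truths.csv,
# results/petite_controls.csv, results/manifest.json

library(madfe)

seed <- 1L
ps <- pipeline_preset("ma2000")
ps$design$ma_colonies_per_well <- 200
ps$design$ref_colonies_per_well <- 200

run_pipeline(ps, seed = seed, out_dir = "results", stages = "simulate")

col <- read.csv("results/colonies.csv")
tru <- read.csv("results/truths.csv")
cat(sprintf("simulated %d colonies across %d wells (%d strains)\n",
            nrow(col), length(unique(col$well)), nrow(tru)))
cat(sprintf("petite fraction (all colonies): %.3f\n",
            mean(col$true_is_petite)))
cat(sprintf("mean true strain effect: %.5f (min %.4f, max %.4f)\n",
            mean(tru$total_effect), min(tru$total_effect),
            max(tru$total_effect)))
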