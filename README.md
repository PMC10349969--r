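# madfe — distributions of mutational effects from microcolony growth rates

`madfe` infers the distribution of spontaneous mutational effects (DFE/DME)
on growth rate from mutation-accumulation (MA) experiments phenotyped by
high-throughput microcolony imaging, in budding yeast or any system with the
same structure: many MA strains, each measured as hundreds of individual
colony growth rates alongside an in-well reference strain, contaminated by
slow-growing respiration-deficient ("petite") subpopulations and by
plate/well batch effects.

It is written for quantitative geneticists who want the full likelihood
chain — colony measurements to per-strain selection coefficients to DME
parameters — as composable, tested R functions, with a synthetic-data
generator standing in for the raw microscopy data.

## The model

**Stage one.** The growth-rate difference between an MA colony and a
reference colony from the same imaging field cancels additive batch effects
exactly and follows a four-component Gaussian mixture over the pair's petite
statuses:

    D ~ (1-ρ_i)(1-ρ_ref) N(μ_i - μ_anc,     2σ²_np)
      + (1-ρ_i) ρ_ref    N(μ_i - μ_pet,     σ²_np + σ²_pet)
      + ρ_i (1-ρ_ref)    N(μ_pet - μ_anc,   σ²_np + σ²_pet)
      + ρ_i ρ_ref        N(0,               2σ²_pet)

with μ_i = μ_anc (1 + s_i). Nested maximum likelihood (per-strain (s_i, ρ_i)
inside, experiment-level parameters outside, petite-only control samples
calibrating the petite component) yields each strain's selection coefficient
with a profile-likelihood standard error and an FDR-controlled call.

**Stage two.** A single mutation's effect is a reflected gamma — magnitude
Γ(shape k, mean m), positive with probability q — and a strain carries a
Poisson(U) number of them, so the per-strain net effect has characteristic
function

    F_S(ω) = exp{ U (F_Z(ω) − 1) },
    F_Z(ω) = (1−q)(1 + iωm/k)^(−k) + q(1 − iωm/k)^(−k),

optionally multiplied by a Gaussian CF for the combined effect of
unidentified (unsequenced, mostly simple-sequence-repeat) mutations.
Densities come from inverse FFT of the CF times a narrow regularising
kernel; models are fitted to the per-strain summaries (or to the raw
differences via numerical integration), compared by AIC and likelihood-ratio
tests, and summarised by closed-form tail masses of the fitted SNM effect
distribution.

## Worked example

The numbered scripts under `analysis/` run the pipeline on a simulated
2000-generation-style experiment (70 MA strains + 2 ancestor controls, one
well each across 14 plates, 200 colonies of strain and reference per well,
petite controls; strain effects drawn from the fitted Gaussian-model DME):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_strains.R
Rscript analysis/03_fit_dme.R
Rscript analysis/04_report.R
```

Stage 1 and 2 print, for seed 1:

```
simulated 28732 colonies across 72 wells (72 strains)
petite fraction (all colonies): 0.102
mean true strain effect: -0.01214 (min -0.1222, max 0.1575)

fitted 72 strains (0 flagged unidentifiable)
significant increase: 4%, decrease: 50%
truth inside the 95% profile interval: 96% of strains
correlation of s_hat with truth: 0.993
```

— about 4% of strains are called significantly faster-growing and half
significantly slower at FDR 0.05, the 95% profile intervals cover the
simulated truth at their nominal rate, and the per-strain point estimates
track the true net mutational effects almost perfectly. Stages 3–4 fit the
SNM-only and Gaussian-unidentified DME models to those estimates, prefer
the Gaussian model by AIC (the generative model), and convert its fitted
SNM distribution into tail masses: the fraction of SNMs with any
discernible effect, and with effects beyond a 1% growth-rate cost (see
`results/model_comparison.csv` and `results/tail_masses.csv`).

The same machinery is exposed directly:

```r
library(madfe)
snm <- dme_params("gaussian_unid", k = 5.5e-2, m = 4.1e-3, q = 0.06,
                  p0 = 0.059, mu_unid = -3.3e-3, sigma_unid = 5.5e-3)
100 * tail_mass(snm, 1e-6, "negative")   # 39.31  % of SNMs deleterious beyond 1e-6
100 * tail_mass(snm, 0.01, "negative")   # 7.45   % of SNMs costing > 1% growth
100 * tail_mass(snm, 1e-6, "both")       # 41.82  % of SNMs visible to selection
ssr_per_mutation_effect(0.0024, 1.8)     # 0.267  % growth decrease per SSR mutation
```

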