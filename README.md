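# TraceMet

Multi-tissue stable-isotope tracer metabolomics and ¹³C metabolic flux
analysis for disease-progression cohorts, built as an R/Bioconductor-style
package.

Cancer cachexia reshapes metabolism across essentially every host tissue.
Tracing a [U-¹³C₆]glucose bolus through plasma, liver, adipose depots,
heart, skeletal muscles and the tumour of a four-group cohort (healthy
control → non-cachectic tumour → pre-cachexia → cachexia) yields, per
tissue, a metabolite intensity matrix and per-metabolite isotopologue
intensities. TraceMet provides the full analysis path for such data, for
metabolomics researchers and bioinformaticians who want each stage tested,
deterministic and reusable:

- **Isotope correction** — natural-abundance / tracer-purity correction of
  isotopologue vectors by non-negative least squares against a
  convolution-built correction matrix; mean enrichment and percentage
  summaries.
- **Preprocessing** — log transform, outlier masking above mean + 4·sd,
  removal above 25% missingness, removal above the 80th RSD percentile in
  any condition, knn imputation (k = 5, metabolite-row neighbours).
- **Differential analysis** — per-tissue one-way ANOVA with Tukey HSD
  contrasts, log₂ fold changes, and a cross-tissue signature rule
  (significant and direction-consistent versus both control groups in at
  least two target tissues).
- **Trajectory clustering** — pseudo-time profiles
  (Ctrl → Pre-cax → Cax; NonCax baseline for tumour) clustered into eight
  scenario groups by template-initialized, variance-sensitive fuzzy
  c-means, validated with the Xie–Beni index, with ranked members and
  Sankey-ready contribution tables.
- **¹³C-MFA** — an atom-transition network parser, a steady-state EMU
  simulator (compiled hot path), weighted least-squares flux fitting with
  the citrate synthase reference flux pinned at 100, χ² goodness of fit,
  Monte-Carlo 95% confidence intervals and interval-overlap comparisons.
- **Synthetic cohorts** — a first-class generator with recorded ground
  truth (effect templates, outlier cells, true fluxes), so every stage is
  testable without any external download.

## The core model

For a metabolite with C carbons, the mass isotopomer distribution vector
(MDV) is the fractional abundance of mass shifts M+0…M+C. At isotopic
steady state the MDVs of a reaction network are fixed by the fluxes: the
EMU decomposition reduces the balance to per-size linear systems
`A(v) X = B(v, inputs)` whose inputs are substrate marginals and
convolutions of smaller units. Fluxes are estimated by minimizing

    SSR(θ) = Σᵢ ( (simᵢ(θ) − measᵢ) / se )² ,  se = 0.03,

over the free fluxes θ (pyruvate carboxylase V9, unlabelled acetyl-CoA
inflow V11, glutamine entry V16) with all dependent fluxes from
stoichiometric balance and the citrate synthase flux V12 ≡ 100. SSR at the
optimum is compared to χ²(dof), dof = #fitted fractions − #free fluxes,
and confidence intervals come from refitting Monte-Carlo-perturbed data.
Two fluxes differ at P < 0.05 when their 95% intervals are disjoint.

## A worked example

Simulate labelling data from known fluxes on the shipped glycolysis→TCA
network, fit, and ask whether the cachectic shift in pyruvate carboxylase
is detectable:

```r
library(TraceMet)

net <- defaultNetwork()
ctrl_truth <- completeFluxes(net, c(V9 = 25, V11 = 40, V16 = 20))
cax_truth  <- completeFluxes(net, c(V9 = 45, V11 = 24, V16 = 28))

ctrl <- generateLabelling(net, ctrl_truth, mdv_noise_sd = 0.03,
                          n_samples = 4, seed = 1)
cax  <- generateLabelling(net, cax_truth,  mdv_noise_sd = 0.03,
                          n_samples = 4, seed = 2)

fit_ctrl <- fitFluxes(net, groupMeanMDVs(ctrl$mdv_noisy), seed = 3)
fit_ctrl <- monteCarloCI(net, groupMeanMDVs(ctrl$mdv_noisy), fit_ctrl,
                         n_draws = 200, seed = 4)
fit_cax  <- fitFluxes(net, groupMeanMDVs(cax$mdv_noisy), seed = 5)
fit_cax  <- monteCarloCI(net, groupMeanMDVs(cax$mdv_noisy), fit_cax,
                         n_draws = 200, seed = 6)

round(fluxes(fit_ctrl)[c("V9", "V10", "V11", "V12")], 1)
#>    V9   V10   V11   V12
#>  23.5  61.9  38.1 100.0
round(fluxes(fit_cax)[c("V9", "V10", "V11", "V12")], 1)
#>    V9   V10   V11   V12
#>  46.4  75.4  24.6 100.0
subset(compareFluxes(fit_ctrl, fit_cax), reaction %in% c("V9", "V11"))
#>   reaction estimate_a estimate_b significant
#> 2       V9   23.49058   46.39929        TRUE
#> 4      V11   38.13546   24.63688        TRUE
```

The fitted fluxes recover the planted truth (V9 = 25 vs 45, V11 = 40 vs
24) within noise, the reference flux is exactly 100 in both groups, and
the non-overlapping 95% intervals flag the pyruvate-carboxylase increase
and the reduced unlabelled acetyl-CoA inflow as significant — the
flux-level signature of glucose hypermetabolism in cachectic muscle.

The whole pipeline (synthetic cohort → preprocessing → differential +
signature → clustering → labelling summaries → MFA) runs with:

```r
res <- runPipeline(defaultConfig(seed = 1), out_dir = "run1")
res$manifest   # one CSV per result table, stamped with the config hash
```

## Network file format

One reaction per line, atoms as lowercase letters, plus directives:

```
substrate GLC 0 0 0 0 0 0 1     # input MDV (here: pure M+6)
symmetric SUC FUM               # 50:50 orientation scrambling
reference V12                   # reported as 100
free V9 V11 V16                 # fitted fluxes
measured CIT SUC FUM MAL
V10: PYR (abc) -> CO2 (a) + AcCoA (bc)
V19: SUC (abcd) -> FUM (abcd)
```

In EBNF:

```
line      = directive | reaction | comment ;
reaction  = id ":" side ("->" | "<->") side ;
side      = species { "+" species } ;
species   = name "(" atoms ")" ;          (* atoms: [a-z]+, a bijection *)
directive = "substrate" name number+ | "symmetric" name+
          | "reference" id | "free" id+ | "measured" name+ ;
```

See `vignettes/tracer-metabolomics-methods.Rmd` for the models,
assumptions, parameter choices and known limitations.
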