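---
title: "Models and methods behind TraceMet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind TraceMet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TraceMet)
```

TraceMet re-implements, as a tested and reusable pipeline, a multi-tissue
stable-isotope tracer metabolomics analysis of cancer-cachexia
progression: natural-abundance correction of isotopologue intensities,
a fixed preprocessing chain, per-tissue differential analysis with a
cross-tissue signature rule, pseudo-time trajectory clustering, and
steady-state ^13^C metabolic flux analysis (MFA) of a glycolysis–TCA
network. This vignette explains each model, its assumptions, the tunable
parameters, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The study design being emulated

The cohort design is four groups of mice — healthy controls (`Ctrl`),
non-cachectic tumour controls (`NonCax`), pre-cachectic (`PreCax`) and
cachectic (`Cax`) — with n = 4 animals per group, sampled across eight
tissues (plasma, liver, eWAT, iWAT, heart, gastrocnemius, soleus,
tumour). Tumour tissue has no `Ctrl` group, because control animals carry
no tumour; that constraint is enforced by the `MetaboSet` validity
method. Animals receive a uniformly labelled [U-^13^C~6~]glucose tracer,
so glycolytic and TCA intermediates acquire characteristic mass shifts:
pyruvate dehydrogenase (PDH) transfers two labelled carbons (M+2
patterns), pyruvate carboxylase (PC) three (M+3 patterns).

## Synthetic cohorts with recorded ground truth

`generateCohort()` draws lognormal intensities
`exp(baseline + effect[group] + N(0, noise_sd))`. Defaults: 8 tissues ×
4 groups × 4 replicates, 200 metabolites, `noise_sd = 0.4` log units
(a ~40% coefficient of variation, typical of untargeted LC–MS across
biological replicates), baselines `N(11, 1.5)` on the log scale (peak
areas around e^11^ ≈ 6·10^4^ arbitrary units), 5% missing cells
completely at random, 0.5% outlier cells spiked upward by at least
6·`noise_sd`. Where the study itself fixes a value (group count,
replicate count, tissue panel, the 3% MDV standard error) the generator
default *is* that value; the remaining rates are one-time choices of
realistic magnitudes, not tuning knobs.

Eight effect templates mirror the trajectory scenarios (early/late/
gradual × up/down, up-then-down, down-then-up) plus a null template; the
`NonCax` entry is always zero, reflecting the observation that
non-cachexia-inducing tumours leave the metabolome essentially
unaltered. Template assignment is class-linked: one-carbon-annotated
metabolites rise late (`late-up`), most energy metabolites fall late
(`late-down`), the remainder draw from configurable weights with half
the mass on the null template. Assignments, flagged outlier cells and
true group means are returned as ground truth for recovery tests.

Determinism: the generator uses the Mersenne–Twister RNG with inversion
sampling, and each tissue consumes its own stream derived from the
master seed, so adding a tissue never perturbs the values of existing
ones. An optional left-censoring mode makes missingness
intensity-dependent (MS missingness is in truth abundance-linked); it is
off by default so the filters' expected behaviour stays analytic.

What the generator does *not* emulate: chromatographic drift, batch
effects, annotation errors, or correlated metabolite co-regulation
beyond the shared templates. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to those real-data pathologies.

## Natural-abundance and tracer-purity correction

Measured isotopologue intensities convolve the biological labelling
pattern with natural heavy-isotope abundance and tracer impurity. For a
metabolite with formula-derived element counts, column *j* of the
correction matrix is the expected measured mass-shift distribution of a
molecule carrying exactly *j* tracer-derived labels: the convolution of
(a) the natural-abundance mass-shift distribution of all non-tracer
elements, (b) the natural-abundance distribution of the C−j unlabelled
tracer-element positions, and (c) a binomial purity distribution over
the j labelled positions. Mass shifts beyond C are truncated, so columns
sum to at most 1. This is the low-resolution regime — every element
contributes to the measured mass shift — matching Orbitrap MS1
acquisition; resolution-dependent partial correction is out of scope.

Correction solves `raw = M x` by non-negative least squares
(`pracma::lsqnonneg`) and renormalizes, guaranteeing non-negative
fractions and invariance to uniform intensity scaling. The ¹³C natural
abundance default is 0.0107; the full isotope tables live in
`ISOTOPE_ABUNDANCES` so tests can pin them. Tracer purity defaults to 1
because the correction is stated but the purity value is not printed;
it is configurable.

## The preprocessing chain

`runPreprocess()` applies, per tissue and in this order:

1. **Log transform** (natural log by default). Zero or negative observed
   values are a hard error — no silent pseudo-count.
2. **Outlier masking**: per metabolite, over all the tissue's samples,
   cells strictly greater than mean + 4·sd (log scale) become missing.
   One pass, no iteration. A point worth knowing: with n samples no
   single value can deviate more than (n−1)/√n sds from the mean, which
   is 3.75 at n = 16 — so at the default multiplier the mask can only
   trigger on multi-sample anomalies or larger cohorts. The rule is
   implemented exactly as stated; its reach at n = 16 is a property of
   the rule, not of this implementation.
3. **Missingness filter**: a metabolite is removed iff *more than* 25%
   of its values are missing; exactly 25% (4 of 16) is retained.
4. **RSD filter**: per metabolite and condition (experimental group
   within the tissue), RSD = sd/mean over observed *raw-scale* values
   (RSD of log values is not scale-free, so the raw matrix is carried
   alongside as a second assay). The threshold is the 80th percentile of
   each condition's RSD distribution, linear interpolation between order
   statistics (`type = 7`, pinned in one constant shared with the test
   oracle); removal requires strictly exceeding the threshold in at
   least one condition. A (metabolite, condition) cell with fewer than
   two observed values contributes no RSD. Note that a percentile-based
   cut removes ≥ 20% of metabolites by construction — up to 1 − 0.8⁴
   across four conditions when exceedances are weakly correlated — and,
   because RSD of lognormal data is invariant to the group-effect
   templates, removal is blind to biological effect; the calibration
   test asserts exactly this.
5. **knn imputation**: for each missing cell, donors are the k = 5
   nearest metabolite rows by Euclidean distance over mutually observed
   samples, scaled by the number of shared samples, among metabolites
   observed in the target sample; their unweighted mean fills the cell.
   k is not stated by the source workflow; 5 is the package default and
   is recorded in the report. A cell with no eligible donor falls back
   to the metabolite's own mean and is counted separately.

Open interpretation points (config-switchable): whether the outlier rule
operates on log or raw values, and per tissue or globally. The defaults
(log scale, per tissue per metabolite) are the minimal reading of
"log-transformed before further processing".

## Differential analysis and the cross-tissue signature

Per tissue and metabolite, classical one-way fixed-effects ANOVA
followed by Tukey's honestly-significant-difference contrasts over all
six group pairs (Tukey–Kramer for unbalanced groups), via `stats::aov` /
`TukeyHSD`. No across-metabolite multiplicity correction is applied —
Tukey corrects across contrasts only — mirroring the source workflow's
reporting of unadjusted *P* < 0.05 for metabolomics; this is stated in
the output headers. Zero-variance degenerate cells are flagged rather
than silently returning NaN. Fold changes are reported in log2 units.

The cachexia signature: a metabolite is commonly up- (down-)regulated
iff, in at least two of the seven non-tumour target tissues, both the
Cax–Ctrl and Cax–NonCax Tukey contrasts are significant at α = 0.05
*and* both differences share the expected sign in those same tissues.
Whether the original rule demanded direction agreement or only
significance is not spelled out; the stricter reading is the default,
with `require_direction = FALSE` to relax. α is configurable per tissue
because one tissue in the source analysis used *P* < 0.1.

## Trajectory clustering

Pseudo-time profiles are the 3-vectors of group means over
Ctrl → PreCax → Cax (NonCax replaces Ctrl as the tumour baseline),
z-standardized across the three points; constant profiles are dropped
with a warning. Standardization before clustering is itself an
interpretation (the source does not state it); raw-profile mode is
available.

Clustering is fuzzy c-means with c = 8, fuzzifier m = 2, tolerance 1e-6,
maximum 300 iterations, initialized at the eight canonical scenario
shapes (step-early, step-late, linear, rise-fall and their mirrors,
standardized). Template initialization makes the procedure deterministic
and keeps each cluster's scenario label meaningful. "Variance-sensitive"
is implemented as per-cluster distance scaling by the current
membership-weighted within-cluster dispersion, floored at 1e-4 and
normalized to mean 1, so tight clusters pull harder; this mechanism is
an interpretation of the cited method and is config-exposed. A profile
at zero distance from a centroid receives membership 1 there. Cluster
validity is the Xie–Beni index (membership-weighted within-scatter over
n times the minimal squared centroid separation; lower is better);
coincident centroids are reported as degenerate rather than silently
producing an infinite index. Reporting gates hard assignments at a
minimum best-membership of 0.5 (configurable), reflecting that only
profiles with a defined trend are carried forward; ranked member lists
break membership ties lexicographically so output is stable.

## ^13^C metabolic flux analysis

The atom-transition network is plain text, one reaction per line
(`V10: PYR (abc) -> CO2 (a) + AcCoA (bc)`), with directives for
substrate MDVs, symmetric molecules, the reference flux, free fluxes and
measured metabolites. The parser enforces that every atom map is a
carbon-conserving bijection and that the free-flux parameterization
determines the network (square, non-singular dependent system).
Reversible reactions are split into forward and `_rev` halves.

The shipped default network lumps glycolysis (GLC → 2 PYR), takes
pyruvate into the TCA cycle by PC (V9) and PDH (V10), feeds acetyl-CoA
from fat oxidation/ketogenic amino acids as an unlabelled inflow (V11),
and runs citrate synthase (V12, the reference flux), lumped
aconitase/IDH (V13), unlabelled glutamine entry (V16/V17), OGDH (V18),
SDH/FH/MDH (V19–V21, with succinate and fumarate symmetric) and a
cataplerotic OAA efflux closing the balance. CO₂ consumed by PC is
treated as unlabelled (large pool dilution); all reactions are
irreversible by default. This network is an approximation assembled from
the fluxes the source names in its main text — the exact published
network is in supplementary material not shipped here — and any other
network can be swapped in through the file format.

Steady-state MDVs are computed by EMU (elementary metabolite unit)
decomposition: backtracking from the measured metabolites' full-carbon
EMUs through the atom maps yields, per EMU size, a linear balance system
whose inputs are substrate EMUs and convolutions of smaller EMUs;
symmetric molecules are handled by splitting each producing reaction
into two half-flux orientation variants. Substrate EMU marginals treat
positions as exchangeable given a full MDV (exact for the uniformly
labelled tracer). The decomposition is compiled once per (network,
target set) and evaluated in C++; a pool with zero turnover at the
current fluxes contributes nothing downstream and its row is pinned
rather than failing the solve. The test suite verifies the EMU route
against an independent full-isotopomer fixed-point enumerator on both
toy networks and the complete default network.

Fitting minimizes Σ((sim − meas)/se)² over the free fluxes (V9, V11,
V16) with the reference flux pinned at 100 and dependent fluxes from
stoichiometric balance, using Levenberg–Marquardt (`minpack.lm::nls.lm`)
from 10 seeded random feasible multi-starts by default (ties go to the
lowest start index); infeasible parameter points (negative dependent
fluxes) are repelled by a smooth penalty. The per-fraction standard
error defaults to 0.03, the stated 3% MDV standard error, treated as
absolute on each fraction. Degrees of freedom are the number of fitted
fractions minus the number of free fluxes (22 − 3 = 19 for the default
network and measured set of citrate, succinate, fumarate and malate);
goodness of fit is the upper-tail χ² probability of the SSR.

Confidence intervals are Monte-Carlo: perturb the measured MDVs with
truncated Gaussian noise of the same sd, renormalize, refit from the
point estimate, and take percentile intervals (95% by default, 500
draws by default) on the reference-normalized scale; intervals are
flagged unreliable when more than 20% of refits fail. Two fluxes differ
significantly at P < 0.05 iff their 95% intervals are disjoint. Fits
default to per-group-mean MDVs (per-animal mode is a matter of passing
each sample's MDVs separately).

## Isotopologue summaries

Group summaries report means ± s.e.m. of isotopologue percentages
("percentage of total metabolite levels"), the labelled total
(100 − mean M+0), and per-isotopologue comparisons versus the control
group using one-way ANOVA with Dunnett's many-to-one adjustment
(`multcomp`), or Kruskal–Wallis with Dunn's rank comparisons
(Bonferroni-adjusted) as the non-parametric switch — the parametric
route is the default since no normality-test criterion is stated.
Aggregate labelled distributions renormalize the k ≥ 1 fractions of a
metabolite set per group; shifting flux truth toward PC raises the M+3
share, which is the qualitative signature the muscle figures rest on.

## Orchestration and reproducibility

`validateConfig()` reads a YAML configuration, fills documented defaults
(which reproduce every stated constant: 4·sd, 25%, 80th percentile, 8
clusters, 3% SE, 95% CIs, reference = 100), rejects unknown keys
fail-fast and reports all schema violations at once. `runPipeline()`
executes simulate → preprocess → differential/signature → cluster →
labelling → MFA in dependency order, derives per-stage seeds from the
master seed so stages re-run in isolation, stamps outputs with the
configuration hash, and writes one CSV per result table plus a
`key=value` log. Identical configuration and seed give byte-identical
result files.

## Problem sizes used by the tests

The suite runs the acceptance-grade simulations at desk scale chosen for
statistical decisiveness per check: 200 simulated datasets with 200
Monte-Carlo draws each for interval coverage (binomial 99% bounds around
95% are ~91–99% at that size); 2000 null metabolites for type-I-error
calibration; 200 template-generated profiles (25 per scenario) for
template recovery; 30 seeded replicates across PC:PDH ratios
0.1/0.5/1.0 for flux recovery. These sizes are the package's own choices
and are pinned with their seeds in the tests.

## Known limitations

- Steady-state MFA only; the in-vivo bolus protocol is approximated as
  isotopic steady state, as in the source's own software choice.
  Non-stationary MFA, exchange-flux estimation and compartmentation are
  out of scope.
- The default network's reaction numbering outside the named fluxes is
  an interpolation; swap in a complete network file when one is
  available.
- The variance-sensitivity mechanism and the membership gate of the
  clustering are interpretations of a method the source only names.
- Raw LC–MS processing (peak picking, annotation), RNA-seq, pathway
  over-representation and ordination are out of scope by design.
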