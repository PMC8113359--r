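---
title: "Age-dependent selection on gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-dependent selection on gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agesel)
```

## The scientific question

In an age-structured population, the force of natural selection declines
over the lifespan: a mutation whose effects are confined to late life
harms fewer of its carriers' reproductive prospects than one expressed
early. Genes that are predominantly expressed late in life should
therefore evolve under weaker purifying selection — accumulating more
nonsynonymous polymorphism and divergence — and, if degradation by fixed
deleterious mutations eventually causes gene loss, should also have
shorter evolutionary lifespans.

`agesel` implements the quantitative machinery for testing these
predictions on per-gene summary data: an age-of-expression statistic, a
Poisson random field (PRF) model that converts polymorphism and
divergence ratios into per-gene estimates of the scaled selection
strength and the beneficial mutation fraction, a random-walk model of
gene lifespan, and a rank-based association layer. A synthetic cohort
generator plants all of these signals with known truth, so the entire
pipeline can be validated end to end.

## The age-of-expression statistic

For each gene, REA is the ordinary least-squares slope of log expression
on sample age, using every sample as one data point. Working on the log
scale makes the slope a proportional change per unit age, invariant to a
gene's absolute expression level; scaling the age axis by a constant
scales every REA by its inverse, which leaves all rank-based analyses
unchanged. Positive REA marks late-expressed genes, negative REA
early-expressed ones.

Two open choices are fixed as follows and exposed as arguments:

* **Replicates.** All samples enter the regression individually rather
  than as age-group means. In a balanced design the two give the same
  slope; with imbalance the per-sample fit weights information by sample
  count, which is what least squares should do.
* **Log transform.** Natural log with a pseudocount of 1 when raw counts
  are supplied (`read_expression_matrix(raw_counts = TRUE)`). The choice
  of base rescales every REA by the same constant and is irrelevant to
  ranks; the pseudocount matters only for genes near zero counts.

`age_of_max_expression()` provides the alternative summary (the age of
maximal mean expression, ties to the youngest age), and `compute_tau()`
the usual tissue-specificity index `tau = sum(1 - x_i/x_max)/(N - 1)` on
non-negative per-tissue means.

Early and late classes are the lower 10th and upper 90th percentiles of
REA. Percentiles use inverse-ECDF (type 1) quantiles, mirrored for the
upper tail, so with distinct values each extreme class holds exactly
`ceiling(n/10)` genes and ties at a cutoff all join the extreme class —
a fully deterministic rule. The early/late contrast in dN/dS,

\[
\Delta R_{NS} =
\frac{(d_N/d_S)_{\mathrm{late}} - (d_N/d_S)_{\mathrm{early}}}
     {\tfrac12\left[(d_N/d_S)_{\mathrm{late}} + (d_N/d_S)_{\mathrm{early}}\right]},
\]

uses unweighted arithmetic class means and is bounded in \([-2, 2]\).

## The Poisson random field model

Each gene carries `sites_n` nonsynonymous and `sites_s` synonymous
sites. Mutations arrive at total rates \(\mu_N\) and \(\mu_S\); a
fraction \(\alpha_m\) of nonsynonymous mutations is beneficial with
scaled homozygous effect \(+N_e s\), the rest deleterious with
\(-N_e s\), heterozygotes intermediate, synonymous mutations neutral.
Sites evolve independently (no interference), so segregating- and
fixed-site counts are Poisson around diffusion expectations.

For a sample of \(m\) gene copies, the expected segregating synonymous
count is Watterson's \(\theta_S \sum_{k=1}^{m-1} 1/k\); the selected
classes require quadrature over the sojourn density, with the exponent
\(4 N_e s\) in the polymorphism integrand. The divergence expectations
for a species pair separated by \(t_{div}\) (units of \(2 N_e\)
generations) scale the divergence window by the relative fixation rate
\(x/(1 - e^{-x})\) with \(x = N_e s\) and add boundary terms computed by
`g_integral()`. One inconsistency in the printed source formulas is
preserved deliberately: the polymorphism integrand carries the scaled
effect with a factor of 4 while the fixation formulas carry it with a
factor of 1. Both are implemented exactly as printed with a single
internal parameter equal to the printed product in each formula;
reported `ne_s` values follow the fixation-formula scale. Users
comparing against other PRF software should be aware of this convention.

Expected ratios follow as
\(p_N/p_S = (n_B + n_D)/n_S\) and \(d_N/d_S = (F_B + F_D)/F_S\),
both independent of the absolute mutation scale. In the long-divergence
limit,

\[
\frac{d_N}{d_S} \to \frac{\mu_N}{\mu_S}
\left[\alpha_m \frac{x}{1 - e^{-x}}
 + (1 - \alpha_m)\frac{-x}{1 - e^{x}}\right].
\]

**Numerical choices.** Quadrature uses adaptive integration at relative
tolerance `1e-10`, with the removable endpoint singularities of the
integrands replaced by their finite limits, and an algebraically
equivalent overflow-free form of the sojourn factor for strongly
negative effects. Every factor is 0/0 at \(s = 0\), so for
\(|N_e s| < 10^{-6}\) all kernels switch to second-order series
expansions; the neutral limits (`pn_ps` and `dn_ds` both equal to
\(\mu_N/\mu_S\)) then hold to better than \(10^{-8}\). The mirror
symmetry \((\alpha_m, s) \leftrightarrow (1 - \alpha_m, -s)\) and the
harmonic-sum identity for the synonymous integral are enforced by tests.

### A note on the two pN/pS scales

The model ratio is over expected *counts* of segregating sites; the
common observed statistic divides each count by its site total. The two
differ by `sites_s/sites_n`. The inversion works on the count scale,
where the factor cancels against `mu_ratio = sites_n/sites_s`; the
observed, fraction-based statistic (`compute_pnps()`, used in the
association layer and for plotting) equals 1 under neutrality with
equal per-site rates.

## Inverting the model

`estimate_gene()` solves the two-equation system (observed pN/pS and
dN/dS versus their expectations) for \((N_e s, \alpha_m)\), minimising
squared log residuals — the natural scale for positive ratios spanning
decades — over \(N_e s \in [10^{-6}, 100]\),
\(\alpha_m \in [0, 1]\). Three structural facts shape the algorithm:

1. Both expected ratios are **exactly linear in \(\alpha_m\)** at fixed
   \(N_e s\), so \(\alpha_m\) is profiled out of the dN/dS equation in
   closed form and the search reduces to one dimension.
2. The forward map is **not globally injective**: near the
   \(\alpha_m = 0\) boundary two parameter pairs (a few percent apart in
   \(N_e s\)) can reproduce the same ratio pair essentially exactly. The
   profiled objective is therefore scanned on a deterministic grid in
   \(\log N_e s\), *every* local minimum is refined, and the boundary
   branches \(\alpha_m \in \{0, 1\}\) are solved exactly by root
   finding. Ties between exact fits are broken toward the smaller
   \(N_e s\): the weakest selection consistent with the data.
3. Near neutrality the two mutation classes are indistinguishable, so
   \(\alpha_m\) is unidentifiable; estimates with
   \(\hat{N_e s} < 10^{-4}\) are flagged
   `neutral_alpha_unidentifiable`.

A bounded joint polish finishes the fit. Observations of exactly zero
are floored at half the smallest positive observable ratio for the
gene's counts (flag `boundary`), preserving rank information without
infinite logs; observation pairs outside the attainable set return the
minimal-residual fit flagged `no_solution`. With noisy counts a large
fraction of genes is expectedly `no_solution` in this strict sense — the
estimates remain usable for rank-based analyses, which is how they are
consumed. The long-divergence limit is the default divergence
observable, since per-species divergence times are rarely known on the
\(2 N_e\) scale; passing `t_div` switches to the finite-divergence
model. No uncertainty is attached to the per-gene estimates; the
statistical properties of this inversion are unknown, which is why all
downstream claims rest on nonparametric rank statistics across genes.

`estimate_table()` applies the same fit per gene, skipping (with a
recorded reason) genes lacking synonymous polymorphism or divergence,
and shares a spline interpolation of the polymorphism integral across
genes for the scan stage only — refinement always uses exact quadrature.

## The gene-lifespan walk

A gene starts at fitness 1; each fixation moves it by \(\pm s\) (up with
probability \(\alpha\), the fraction of *fixed* substitutions that are
beneficial — distinct from \(\alpha_m\)), and the gene is lost at
\(-k\) net deleterious steps. This is a gambler's ruin: the generating
function of the substitution count at loss is \(V(z)\) (the dummy
variable is named `z` to avoid the selection coefficient), absorption is
certain for \(\alpha < 1/2\), and the expected substitution count
evaluates — exactly, as the tests verify across the whole grid — to
\(k/(1 - 2\alpha)\), with the small-\(\alpha\) form \(k(1 + 2\alpha)\).
Dividing by the total fixation rate \(r_B + r_D\) converts counts to
time; `expected_extinction_time()` returns both the small-\(\alpha\)
approximation \((k/(r_B + r_D))(1 + 2 r_B/(r_B + r_D))\) (default, kept
as the model's canonical form) and the exact composition
\(k/((r_B + r_D)(1 - 2\alpha))\). Weaker purifying selection raises
\(r_D\) and shortens the expected lifespan — the mechanism by which
late-expressed genes are predicted to be young. `simulate_walk()` is the
direct Monte-Carlo counterpart (censoring horizon \(10^7\) steps by
default, because absorption times are heavy-tailed near
\(\alpha = 1/2\)).

## The synthetic cohort generator

The generator is the package's test bed: it plants the statistical
structure the analysis is meant to detect, with retrievable truth.

* True REA per gene is Normal; the empirical REA distribution in real
  cohorts is unknown, so Normal is a configurable placeholder
  (`rea_mean`, `rea_sd`).
* Selection maps: \(N_e s = e^{a_0 + a_1 \cdot REA}\) (log-linear keeps
  it positive) and \(\alpha_m = \mathrm{logis}(c_0 + c_1 \cdot REA)\)
  (logistic keeps it in \([0,1]\)). Defaults \(a_1 = -0.5\),
  \(c_1 = +1\) plant weaker purifying selection and a slightly larger
  beneficial fraction in late genes; \(a_0 = 0.5\) centres \(N_e s\)
  near 1.6, and \(c_0 = -3\) keeps the beneficial fraction small
  (mean ≈ 5%, a realistic order) — which also keeps the implied
  fraction of beneficial *fixations* below 1/2 across the REA range, so
  every gene's lifespan walk is subcritical.
* Expression: per-gene log-normal baseline, per-tissue offsets, plus
  \(REA \times age\) and Gaussian noise, over five adult ages × three
  replicates × three tissues (an insect-style whole-body design).
* Counts are Poisson around the PRF forward expectations — matching the
  inference model exactly, which makes parameter recovery a clean test —
  with `theta_s = 5` (≈ 20 segregating synonymous sites at `m = 40`)
  and `t_div = 50`, large enough that the long-divergence limit used by
  the default inversion is a good approximation of the finite-\(t\)
  expectations used for generation.
* Gene age is an exponential waiting time with mean proportional to the
  lifespan model's expected extinction time at the gene's fixation
  rates (the simplest generative story consistent with that model).

What the generator does **not** emulate: linkage and selective
interference, demographic nonequilibrium, a continuous distribution of
fitness effects, expression measurement artefacts (batch, probe,
circadian effects), or correlated annotation structure. Passing tests
therefore demonstrate that the pipeline recovers what the model family
assumes — not that real data satisfy those assumptions.

## The association layer

`fit_rea_regression()` fits
\(y_i = b_0 + b_1\,REA_i + b_2\,\overline{expr}_i + \dots + e_i\) by
OLS, with tissue-specificity `tau` as an optional covariate and tissue
(where a tissue column exists) as fixed per-tissue intercepts. A
random-effect treatment of tissue would be the textbook choice for many
tissues; fixed intercepts remove tissue means identically at the scale
of these designs without a mixed-model dependency, and this deliberate
simplification is the package's documented convention. Inference about
the REA effect rests on the two-sided Spearman rank correlation,
uncorrected for multiple tests; the OLS coefficients are descriptive.
Missing data are removed listwise with the used sample size reported.

`paralog_contrasts()` regresses within-pair differences of a statistic
on the REA difference (pairs oriented by ascending gene id; results are
invariant to orientation), and `binary_trait_association()` combines a
Spearman test on the 0/1 indicator, a Wilcoxon rank-sum comparison of
REA between classes, and equal-count REA bins (default 10) for
enrichment curves.

## Validation sizes and runtimes

The shipped validation uses cohorts of 2000 genes (20 seeds) for the
end-to-end direction-recovery check, 500 replicates of 60-gene null
cohorts for calibration of the Spearman test, \(10^5\) draws for walk
simulations, and Wright–Fisher runs at population size 100 with 40 000
sampled generations — sizes at which Monte-Carlo error is small relative
to the planted effects while the whole suite remains quick to run. The
Wright–Fisher oracle accumulates sample-level segregation as its exact
conditional expectation given population frequencies (binomial sampling
of `m` copies, as the model assumes), so its error bars reflect the
population process only, with batch-means standard errors over epochs.

## Known limitations

* Per-gene \((N_e s, \alpha_m)\) estimates carry no standard errors and
  can be boundary-attracted at low counts; use them for ranks, not
  magnitudes.
* The two-point \(\pm s\) effect model has no dominance parameter and no
  continuous DFE.
* The exponent-convention discrepancy between the polymorphism and
  fixation formulas (above) means absolute `ne_s` values are
  convention-dependent; comparisons across genes within this package are
  unaffected.
* The lifespan model treats fixation rates as constants per gene; no
  feedback from accumulated substitutions on \(\alpha\) or \(s\).
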