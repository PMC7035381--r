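---
title: "Methods: two-parameter characterization of intermittent transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-parameter characterization of intermittent transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scintermit)
```

## The statistical model

Single-cell RNA-seq counts for a given gene are highly variable across
cells: many zeros alongside occasional counts of hundreds. `scintermit`
summarizes each gene in each tissue by two parameters that are agnostic
about the mechanism behind that variability. If a gene is "on" with
probability $p$ and an on-cell carries $\alpha$ transcripts (off-cells
carry none), the count mean and variance are $\mu = \alpha p$ and
$\sigma^2 = p(1-p)\alpha^2$. Inverting these moment relations motivates
the plug-in estimators

$$\hat p = \frac{\mu^2}{\sigma^2}, \qquad \hat\alpha = \frac{\sigma^2}{\mu},$$

which return $p/(1-p)$ and $\alpha(1-p)$ under the two-point model —
i.e. $p$ and $\alpha$ themselves up to relative error of order $p$ when
activation is rare. Because both parameters span decades across a
transcriptome, analysis is done in logarithmic variables: the
*activity* $A = \ln\alpha$ and the *intermittency* $I = -\ln p \ge 0$.

Assumptions worth keeping in view:

- The moments are *population* moments ($1/N$ variance), taken literally
  from the defining formulas; a $1/(N-1)$ option exists
  (`var_method = "sample"`) but changes nothing at single-cell sample
  sizes.
- No distributional form is assumed within the on-state. On real data
  $\hat\alpha$ is best read as "typical count when expressed", not as a
  rate constant.
- The estimators are deliberately simple: no shrinkage, no uncertainty
  intervals. They are comparison devices across genes within one
  dataset, not calibrated absolute measurements.

## Degenerate inputs and clipping

Three situations pin the estimators rather than inform them, and are
flagged `degenerate`:

- $\mu = 0$ (gene absent): $p$ is set to 0 and the (gene, tissue) entry
  is excluded from summaries — assigning $I = \infty$ would poison every
  average downstream.
- $\sigma^2 = 0$ (constant nonzero gene): $p = 1$, $\alpha = \mu$,
  $I = 0$. This is the ideal spike-in limit.
- $\mu^2 > \sigma^2$ (sub-Poissonian): the raw ratio exceeds 1 and is
  clipped to $p = 1$ so that $I$ stays non-negative.

On all non-degenerate entries the identity
$\hat p\,\hat\alpha = \mu$ holds exactly; the test suite asserts it to
$10^{-12}$.

## Discriminating rare cell types from intermittency

For a gene pair in one tissue, with population moments,

$$C = \frac{\langle M_i M_{i'}\rangle - \mu_i\mu_{i'}}{\sigma_i\sigma_{i'}},
\qquad K = C\,\frac{\sigma_i\sigma_{i'}}{\mu_i\mu_{i'}}.$$

If two genes are never expressed in the same cell, the cross moment
vanishes and $K = -1$ *exactly*, independently of expression levels —
this is an algebraic identity, not an asymptotic one, and
`gen_differentiated_counts()` reproduces it to machine precision. If
instead low-$p$ genes are temporally intermittent, co-regulated genes
switch on together and the larger correlation coefficients are
predominantly positive. `run_analysis()` turns the two summaries into a
verdict: a substantial mass of pairs within `epsilon` of $K = -1$
(default 0.05) flags differentiation-consistency; a positive fraction
of at least 0.75 among pairs with $|C| >$ `c_threshold` (default 0.1)
with almost no exclusive pairs flags intermittency-consistency. Both
thresholds are exposed because no principled universal value exists:
the $|C|$ cutoff separates "meaningful" from noise-level coefficients
(at $N$ cells, null correlations have standard error $\approx
1/\sqrt{N}$, so 0.1 is $\sim 4.5\sigma$ at $N = 2000$), and `epsilon`
absorbs floating noise around the exact $-1$.

A finite-sample caveat the package makes visible rather than hides:
for two *independent* rare genes ($p_1 p_2 N \ll 1$) the expected
number of co-occurrences is below one, so $K = -1$ arises by chance
absence of co-expression. The exclusivity test is informative only
when the surveyed genes and cell numbers satisfy $p_i p_j N \gtrsim 1$;
with very sparse data the verdict degrades to "indeterminate" rather
than asserting differentiation.

## Spike-in diagnostics and normalization

Spike-ins are present in every cell at known concentration, so
fluctuations of $\ln M$ across cells measure the technical fractional
error. Dividing by the cell total ($M' = M/\sum_i M$) would help only
if the totals' variation were technical; if it is biological, the
division *injects* that variation into the constant-concentration
sequences and $\mathrm{Var}(\ln M')$ exceeds $\mathrm{Var}(\ln M)$.
`spikein_log_variability()` reports both variances per spike-in and
their aggregate ratio, optionally after excluding cells in the lower
quartile of total count (whose small denominators dominate the
effect). Numerical choices: logs are taken over strictly positive
counts only ($\ln 0$ is undefined and a zero read carries no
fractional-error information), and spike-ins are excluded from the
normalization denominator by default (the total is meant to proxy the
cell's endogenous transcriptome; a flag restores the inclusive
convention).

`equalize_tissue_activity()` additively shifts each tissue's $A$
values to a common mean — multiplicative on $\alpha$ — to remove
tissue-level differences in overall mRNA content before comparing
activity distributions; being a pure shift, it preserves within-tissue
variances exactly.

## Cross-tissue persistence

Per gene, $A$ and $I$ are averaged across tissues with a simple
unweighted mean (cell numbers per tissue vary by an order of
magnitude and would otherwise dominate the average), and deviations
$\Delta A_{ik} = A_{ik} - \bar A_i$, $\Delta I_{ik}$ are pooled over
all (gene, tissue) points. The headline statistic is the pair of
population variances $\mathrm{Var}(\Delta A)$, $\mathrm{Var}(\Delta I)$
and their ratio, accompanied by a $20\times20$ occupancy histogram of
$(\Delta I, \Delta A)$. A ratio well below 1 is the persistence
signature: peak activity is an intrinsic gene property while tissues
modulate expression probability.

## Tail fits

The upper tail of the tissue-averaged activity $\bar A$ is modelled as
$\exp(-\lambda \bar A)$; by the change of variables
$\alpha = e^{A}$ this is equivalent to a power law
$P(\alpha) \sim \alpha^{-(\lambda+1)}$, and the package reports both
the exponential rate and the implied power-law exponent
($= \lambda + 1$ exactly). Estimation is by maximum likelihood on the
exceedances above a cutoff — the exponential-rate MLE
$\hat\lambda = 1/\overline{(\bar A - c)}$, identical to the Hill
estimator on $\alpha$ — because slopes drawn through log-binned
histograms depend on binning and are better treated as visual guides.
A `method = "regression"` mode (log-density regression on uniform
bins) is provided for figure-style replication and agrees with the MLE
on clean data. The cutoff is manual by default for reproducibility;
the fit refuses to run on fewer than 50 exceedances, where the
estimator's standard error $\lambda/\sqrt{n}$ exceeds any tolerance of
interest.

## Telegraph-model theory

The two-state model (promoter switching on at rate $k_{on}$, off at
$k_{off}$, transcribing at $k_{tr}$ while on, transcripts degrading at
$k_{deg}$) has stationary mean $p_0 M_0$ and variance

$$p_0 M_0 + p_0(1-p_0) M_0^2 \frac{k_{deg}}{k_{on}+k_{off}+k_{deg}},
\qquad p_0 = \frac{k_{on}}{k_{on}+k_{off}},\; M_0 = \frac{k_{tr}}{k_{deg}}.$$

`gen_telegraph_counts()` samples the exact stationary law via its
Poisson–Beta representation — a Poisson whose rate is $M_0$ times a
$\mathrm{Beta}(k_{on}/k_{deg},\, k_{off}/k_{deg})$ occupancy variable —
chosen over Gillespie simulation with burn-in because it is exact,
burn-in-free and $O(n)$. Substituting the closed-form moments into the
estimators gives, for $M_0 \gg 1$,

$$p \sim \frac{p_0}{1-p_0}\frac{k_{deg}+k_{on}+k_{off}}{k_{deg}},
\qquad \alpha \sim M_0(1-p_0)\frac{k_{deg}}{k_{deg}+k_{on}+k_{off}},$$

whose product telescopes to the mean $p_0 M_0$ exactly. When
$p_0 \ll 1$ and degradation is fast relative to switching
($k_{deg} \gg k_{on}+k_{off}$), $p$ and $\alpha$ identify $p_0$ and
$M_0$. `verify_identification()` checks this by simulation; it uses
the *raw* moment ratios without the $p \le 1$ clipping, since outside
the identification regime the ratio legitimately exceeds 1 and the
point of the report is to quantify exactly that deviation. The
documented tolerance — relative error below 10% for $p_0 \le 0.05$ and
$k_{deg} \ge 20(k_{on}+k_{off})$ — is near-sharp: at the boundary the
asymptotic bias alone is $\approx(1+p_0)(1+1/20) \approx 1.10$, so
validation grids sit comfortably inside the region (switching ratios
of 50–100) rather than on its edge. No likelihood fitting of the
telegraph model is attempted: the moment approach exists precisely
because such fits are ill-conditioned in parts of parameter space.

## Quality filters

Two protocol-specific filters, with deliberately literal boundary
semantics:

- *FACS* (`filter_facs()`): per-cell counts strictly below 10 are
  zeroed first, then genes whose total is not strictly greater
  than 500 are dropped ("more than 500" read as strict; a total of
  exactly 500 is dropped, 501 kept). Zeroing precedes the total
  because neglected counts should not help a gene pass. Spike-ins are
  exempt from the drop so diagnostics retain them. The gene criterion
  is applied per tissue by default — every downstream statistic is
  per-tissue, so a gene weakly present in one tissue should not ride
  in on another tissue's counts — with a global mode available
  (`per_tissue = FALSE`).
- *Droplet* (`filter_droplet()`): cells need at least 1000 reads and
  at least 500 detected genes, both inclusive; spike-ins count toward
  neither. Surviving cells are untouched.

Both filters are idempotent, which the suite asserts.

## What the synthetic generators emulate

The generators are first-class, tested components; every downstream
claim is validated against their ground truth.

- `gen_intermittent_counts()` — case B: Bernoulli($p$) activation per
  cell (optionally shared within co-regulation programs), active
  counts either exactly $\mathrm{round}(\alpha)$ (`"fixed"`, the
  two-point model under which the estimator identities are exact) or
  Poisson($\alpha$) (`"poisson"`, the default; real counts fluctuate
  within the on-state, and the estimators then return
  $1 + (1-p)\alpha$ for $\hat\alpha$ — the suite uses `"fixed"` when
  testing exact moment identities). Both modes are offered because the
  within-active-state distribution is not identifiable from the
  two-moment summary itself. A lognormal per-cell size factor (sdlog
  `cell_size_dispersion`) emulates the roughly two-decade spread of
  real per-cell totals.
- `gen_differentiated_counts()` — case A: disjoint cell types drawn at
  stated frequencies, each gene expressed continuously in exactly one
  type. Cross-type gene pairs have exactly zero cross moment.
- `gen_telegraph_counts()` — exact stationary Poisson–Beta sampling as
  above.
- `gen_spikein_counts()` — every sequence in every cell at
  concentration × capture efficiency, multiplied by per-entry
  lognormal technical noise and a per-cell technical scale factor,
  then *rounded deterministically*, so a noise-free panel yields
  literally identical counts (variance exactly 0, $I$ exactly 0) —
  the contract the intermittency cutoff is calibrated against.
  Optional biological filler genes carry an additional per-cell
  biological size factor that spike-ins do not share; this is the
  configuration in which normalization inflates spike-in log variance.
- `gen_multi_tissue_counts()` — the persistence study condition:
  α per gene drawn once from a Pareto tail with exponent 2.35 above 20
  (matching the power-law character and droplet-protocol exponent of
  activity distributions in real transcriptomes) and held fixed across
  8 tissues of 400 cells, while $p$ is redrawn log-uniformly on
  [0.02, 0.5] per (gene, tissue) — two decades of expression
  probability, the regime where intermittency varies strongly but
  activity persists. These defaults are the study conditions, chosen
  once; validation at these sizes completes in seconds.

What the generators do *not* emulate — and hence what passing tests do
not establish about real data: amplification cascades and
protocol-dependent count distortions, doublets and ambient RNA,
correlated gene programs beyond simple shared switching, cell-cycle
and continuous (non-switching) regulation, and UMI saturation.
Agreement on synthetic data shows the estimators and statistics do
what their algebra promises, not that any particular biological
dataset satisfies the model.

## Interfaces and reproducibility

Counts travel as Matrix Market files with TSV sidecars
(`write_counts()`/`read_counts()`, lossless round trip, spike-ins
recognized by the `ERCC-` prefix by default); all analysis outputs are
plain TSV via `write_report()`, so reruns can be diffed numerically.
The orchestration layer is the function surface itself —
`analysis_config()` plus `run_analysis()` — which is the natural
command interface for an R analysis package; every generator and
`run_analysis()` take an explicit integer seed, and reruns with the
same seed are bitwise identical (asserted in the suite).
`scripts/acceptance.R` recomputes the validation quantities end to end
from a single `--seed`: estimator recovery on a
$p \in \{0.01, 0.05, 0.1\} \times \alpha \in \{20, 100, 500\}$ grid at
$10^5$ cells, telegraph moments on a 12-point grid at $10^5$ draws,
the identification grid at $2\times10^5$, discrimination on 24-gene
case A/B datasets at 4000 and 2000 cells, tail recovery at $10^5$
draws, and the multi-tissue persistence ratio at the generator
defaults.

## Known limitations

- $\hat p$ estimates $p/(1-p)$, not $p$; above $p \approx 0.2$ the
  distinction is material and the intermittency call (calibrated at
  $p = 0.2$) should be read accordingly.
- Degenerate-entry exclusion means genes detected in a single cell of
  a tissue contribute to that tissue's statistics but with very noisy
  $\hat\alpha$; at droplet-like sparsity these single-count genes pile
  up at the low-activity end and can dominate dispersion summaries.
- The exclusivity test loses power on sparse data (see the caveat
  above); the verdict logic prefers "indeterminate" over a forced call.
- All-pairs correlation surveys scale quadratically in genes;
  `max_pairs` subsamples pairs with a fixed seed, preserving sign-split
  distributions but not the identity of individual extreme pairs.
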