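# scintermit

Characterization of intermittent gene transcription from single-cell
RNA-seq count matrices, for computational biologists studying
transcriptional bursting and for method developers who need a
mechanism-agnostic alternative to fitting stochastic burst models.

## The model

Many genes appear in only a small fraction of cells. Two explanations
compete: the gene is expressed continuously but only in a rare,
specialized cell type (case A), or it is expressed intermittently in
most cells, switching on and off over time (case B). `scintermit`
implements a two-parameter characterization that addresses this without
assuming any particular stochastic mechanism.

For gene *i* in tissue *k*, from the per-cell counts *M<sub>ijk</sub>*
over the *N<sub>k</sub>* cells of the tissue:

- moments (population convention):
  μ<sub>ik</sub> = (1/N<sub>k</sub>) Σ<sub>j</sub> M<sub>ijk</sub>,
  σ²<sub>ik</sub> = (1/N<sub>k</sub>) Σ<sub>j</sub> M²<sub>ijk</sub> − μ²<sub>ik</sub>
- activation probability: p<sub>ik</sub> = μ²<sub>ik</sub> / σ²<sub>ik</sub>
- peak activity: α<sub>ik</sub> = σ²<sub>ik</sub> / μ<sub>ik</sub>
- log variables: activity A<sub>ik</sub> = ln α<sub>ik</sub>,
  intermittency I<sub>ik</sub> = −ln p<sub>ik</sub>

Under a two-point on/off model (count α with probability p, else 0),
μ = αp and σ² = p(1−p)α², so the ratio estimators return p/(1−p) and
α(1−p) — i.e. p and α themselves when p ≪ 1. A gene is called
*intermittent* when I > ln 5 (active with probability below 0.2), a
cutoff calibrated on ERCC spike-ins, which are present in every cell
and ideally have I = 0.

The case A/B discrimination uses gene-pair statistics: the correlation
C<sub>ii′,k</sub> = (⟨M<sub>i</sub>M<sub>i′</sub>⟩ − μ<sub>i</sub>μ<sub>i′</sub>) / (σ<sub>i</sub>σ<sub>i′</sub>)
and its rescaling K<sub>ii′,k</sub> = C σ<sub>i</sub>σ<sub>i′</sub> / (μ<sub>i</sub>μ<sub>i′</sub>).
K equals −1 exactly whenever two genes are never observed in the same
cell — the fingerprint of disjoint rare cell types — whereas temporal
co-activation produces predominantly positive C.

The package also provides cross-tissue persistence statistics
(Var(ΔA) vs Var(ΔI) of per-tissue deviations from each gene's tissue
average), spike-in log-variance diagnostics for total-count
normalization, exponential/power-law tail fits of the activity
distribution, and the stationary theory of the two-state telegraph
model (Poisson–Beta sampling, closed-form moments, and the limit in
which p and α identify the promoter parameters p₀ = k_on/(k_on+k_off)
and M₀ = k_tr/k_deg).

## Worked example

Simulate two tissues in which thirty genes keep a shared peak activity
(α = 80) but differ in activation probability, with co-regulated
five-gene programs, then run the full pipeline:

```r
library(scintermit)

genes <- intermittent_genes(paste0("gene", 1:30), p = 0.2, alpha = 80,
                            program = rep(paste0("prog", 1:6), each = 5))
cm <- gen_intermittent_counts(
  genes, c(liver = 2000, heart = 2000),
  p_overrides = data.frame(gene_id = paste0("gene", 1:30),
                           tissue = "heart", p = rep(c(0.05, 0.4), 15)),
  seed = 7)

cfg <- analysis_config(protocol = "facs", min_gene_total = 100,
                       min_cell_count = 1, seed = 7)
run_analysis(cm, cfg)
#> analysis_bundle
#>   Var(dA) = 0.01374, Var(dI) = 0.4295 (ratio 0.032)
#>   exclusive-pair fraction = 0, positive fraction = 1
#>   C(A_bar, I_bar) = 0.998
#>   verdict: intermittency-consistent
```

`Var(dA) ≪ Var(dI)` says activity barely moves between tissues while
intermittency does (the persistence signature built into the
generator); every significantly correlated gene pair is positive and
none sits at K = −1, so the data are flagged intermittency-consistent.
The per-(gene, tissue) table shows the estimators at work — for liver
(true p = 0.2, α = 80) the two-point model predicts
p̂ = p/(1−p) = 0.25 and α̂ = α(1−p)+1 ≈ 65:

```r
head(run_analysis(cm, cfg)$stats[, c("gene_id", "tissue", "mu", "p",
                                     "alpha", "A", "I", "intermittent")], 4)
#>   gene_id tissue   mu     p alpha    A    I intermittent
#> 1   gene1  liver 16.3 0.253  64.4 4.16 1.38        FALSE
#> 2   gene2  liver 16.5 0.253  65.2 4.18 1.38        FALSE
#> 3   gene3  liver 16.3 0.252  64.7 4.17 1.38        FALSE
#> 4   gene4  liver 16.5 0.252  65.3 4.18 1.38        FALSE
```

The same pipeline on rare-cell-type data
(`gen_differentiated_counts()`, eight disjoint types) returns
`verdict: differentiation-consistent` with an exclusive-pair fraction
of 0.913.

Telegraph-model theory in three calls:

```r
tp <- telegraph_params(k_on = 0.01, k_off = 0.09, k_tr = 100, k_deg = 1)
stationary_moments(tp)
#>     mean variance
#>  10.0000 828.1818
predict_p_alpha(tp)
#>          p      alpha
#>  0.1222222 81.8181818
```

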