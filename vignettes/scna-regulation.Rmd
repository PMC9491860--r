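---
title: "Quantifying RNA- and protein-level gene regulation from somatic copy-number alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA- and protein-level gene regulation from somatic copy-number alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`scnareg` treats somatic copy-number alterations (SCNAs) as natural
perturbation experiments: when a tumor gains or loses a chromosome arm,
every gene on that arm receives a dosage change, and the degree to which
its RNA and protein abundances follow that change reveals where the cell
regulates the gene. This vignette explains the models the package
implements, the parameters that matter, what the bundled synthetic
generator does and does not emulate, and the numerical decisions taken
where the methodology left room.

```{r setup, message = FALSE}
library(scnareg)
library(dplyr)
```

## The fold-change reference and the compensation score

All fold changes are taken relative to a *neutral group*: for each gene
(within each tumor type), the samples whose DNA log2 copy-number ratio
lies within `[-0.2, 0.2]`. The medians of that group on each layer's
native scale define the neutral DNA, RNA and protein levels; a sample's
log2 fold change (log2FC) is `log2(value / neutral median)` for
linear-scale layers and `value − neutral median` for log2-scale layers.
Two contracts matter here:

- **Scales are declared, never guessed.** RNA matrices are accepted on
  the linear (FPKM-like) or log2 scale, protein isobaric-label ratios are
  log2; the reader requires the declaration because the transform cannot
  be inferred reliably from the values.
- **The DNA fold change is re-referenced** to the neutral group's median
  DNA ratio rather than assumed zero, so a globally shifted ratio
  baseline (a common artifact of ratio normalization) cancels out.

The DNA log2FC places each gene–sample pair in one of five SCNA groups.
The published group definitions leave the boundary points unassigned, so
the package fixes a convention: deep loss `x < −0.65`; loss
`−0.65 ≤ x < −0.2`; neutral `−0.2 ≤ x ≤ 0.2`; gain `0.2 < x ≤ 0.65`;
high gain `x > 0.65`. The neutral bin is closed on both sides to agree
with the neutral-group window; the partition covers the real line, so
every finite fold change gets exactly one label.

For non-neutral observations the compensation score is

$$
\mathrm{CS} =
\begin{cases}
d - e & d > 0\\
e - d & d < 0
\end{cases}
$$

with \(d\) the DNA and \(e\) the expression log2FC. CS is positive when
the expression moved less than the DNA, i.e. when the cell buffered the
dosage change, and it is undefined at \(d = 0\); that case cannot arise
for a non-neutral observation, but the function guards it with an error
rather than returning a silent zero.

## Bootstrap inference

Group-level claims ("the median CS of this cell is positive", "complex
genes have a higher median CS than non-complex genes") use resampling
rather than parametric theory, because CS distributions are heavy-tailed
mixtures:

- **Median test.** `n_boot` resamples with replacement, observed median
  \(m\), basic 95% CI \((2m - q_{0.975},\; 2m - q_{0.025})\) over the
  bootstrap medians, and one-tailed
  \(p = (1 + \#\{m^*_b \le 0\})/(B + 1)\). The \(+1\) keeps Monte-Carlo
  p-values away from zero.
- **Difference test.** Both groups are resampled independently; the
  two-tailed p-value recenters the bootstrap distribution at zero
  (\(\delta_b = \theta^*_b - \hat\theta\),
  \(p = 2\min\{P^*(\delta \ge \hat\theta), P^*(\delta \le \hat\theta)\}\),
  each tail with the \(+1/(B+1)\) correction). The published analyses
  name the test but not the tail construction; this recentered form is
  the standard choice that is exact under a sharp null and calibrates
  well in simulation (the test suite checks a 1000-replicate type-I rate
  against the `[0.03, 0.08]` band at nominal 0.05).

P-values are Benjamini–Hochberg adjusted. The family boundary is a
decision: all cells of one layer (every SCNA group and tumor type of the
RNA panel, say) are adjusted together, mirroring one figure-equivalent
panel; median tests and difference tests form separate families. Cells
with fewer than `min_cell_size = 20` observations are reported as
missing rather than tested — bootstrap medians over tiny cells are
unstable. Both choices are configurable. A related open choice is the
resampling unit: the default resamples gene × sample observations within
a cell; `collapse_genes = TRUE` first collapses each gene to its median
score, for readers who consider genes the exchangeable unit.

## Regulation profiles and their associations

Per gene and tumor type, `dr_rho` is the Spearman correlation between
DNA ratio and RNA abundance and `rp_rho` between RNA and protein. The
inferential logic runs in reverse: high correlation = the downstream
layer tracks the upstream one = *weak* regulation at that step. The rank
correlation is implemented in-repo (average ranks for ties, Pearson on
the ranks) so tie behavior is an explicit, tested contract rather than a
library default; a hand-ranked oracle and the reference implementation
both back it in the tests. Correlations need at least `min_pairs = 10`
complete pairs — below that a rank correlation is mostly noise — and two
gene filters precede profiling:

- **Low expression:** within each tumor type the bottom 10% of genes by
  median RNA are removed; exactly `floor(0.10 · n)` genes, ties broken
  by gene identifier so the filter is deterministic.
- **Low DNA variance:** genes whose ratio sits strictly inside
  `(−0.02, 0.02)` in strictly more than 70% of samples are removed;
  correlations over a near-constant regressor are uninformative. The
  strict inequality follows the stated rule to the letter (7 of 10
  samples inside: kept; 8 of 10: removed).

The pan-cancer profile of a gene is the unweighted mean of its per-type
rho values over the types where it passed the filters (a
sample-size-weighted mean is available but off by default, since the
canonical aggregate is unweighted).

The gene-level association between `dr_rho` and `rp_rho` is estimated
from the ridge of their joint density rather than a regression over
genes, because the cloud is heteroscedastic with dense shoulders: a
Gaussian kernel density (normal-reference bandwidth, 100 × 100 grid) is
evaluated, the `dr` range is split into 40 windows, the `rp` of the
maximum-density cell represents each window with data support, and the
OLS slope plus Spearman rho over those representative points summarize
the trend. Numerical decisions: windows without data points are skipped;
a cloud with zero `rp` spread short-circuits to the constant (slope 0)
since a bandwidth of zero would be degenerate; fewer than 200 input
points or an all-identical cloud is an error. On noiseless lines the
ridge recovers the generating slope to within one grid cell — the test
suite checks slopes −1, −0.33, 0 and 0.5 — and on independent clouds it
averages to zero over seeds.

Opposing regulation classes use opposite-tail 35% quantiles (type-7
interpolation; genes tied at a cutoff are included): group 1 = high
`dr_rho` and low `rp_rho` (protein-level regulation), group 2 = the
mirror (RNA-level regulation). Realized cutoffs are data-dependent and
reported alongside membership. Pathway-level scores are the median rho
over member genes (at least 5 genes with profiles), and the table-level
association between the two pathway vectors is reported as Spearman and
Pearson coefficients with p-values. Gene-class contrasts (complex vs
non-complex, conservation tertiles, one subcellular location vs the
rest) reuse the bootstrap difference test; over-representation of a gene
group in annotated sets uses the upper-tail hypergeometric with BH
adjustment.

## Aneuploidy scores and expression models

Segments (0-based, half-open) are projected onto 100 kb windows within
chromosome arms; each window takes the length-weighted mean of
overlapping segments, which also resolves overlapping segments from one
sample. An arm with at least half its windows covered gets the mean of
its covered windows as arm ratio and a call: gain above +0.2, loss below
−0.2, both strict. The aneuploidy score of a sample is the count of
non-neutral arms; missing arms contribute zero. The arm-call step is a
deliberate simplification — the stated rule (window averaging, ±0.2) is
implemented directly rather than re-estimating segment boundaries, which
is upstream work out of scope here.

Gene-wise association with aneuploidy is ordinary least squares of
expression (or log2FC) on the aneuploidy score plus covariates — purity,
cell-cycle score (mean log2 RNA over a configured marker list; the list
is an input, not a hard-coded constant), tumor type expanded to
indicator contrasts. Missing values drop listwise; a fit with
numerically zero residual variance is flagged degenerate and excluded
from ranking. The t-value of the aneuploidy coefficient (residual df
\(n - p\)) ranks genes, descending, ties broken by identifier. Gene
masks (e.g. mitochondrial genes) are applied before ranking.

Preranked enrichment is the weighted Kolmogorov–Smirnov walk: hits
advance by \(|s|^w\) normalized over the set (\(w = 1\) default; a set
whose hit weights are all zero falls back to equal steps), misses
retreat by \(1/(N - N_h)\), and the ES is the signed extreme of the
running sum, the earliest such position under ties (ties only occur in
tiny constructed lists, but the rule makes the statistic well defined).
Null distributions come from same-size random gene sets — equivalent to
permuting gene labels — with the nominal p the same-sign tail fraction,
NES the ES over the mean same-sign null magnitude, and FDR the standard
positive/negative-separated comparison of observed against pooled null
NES. Sets that cover none or all of the list are skipped with a message.

## The synthetic generator

`simulate_proteogenomics()` emulates the statistical structure the
analyses assume, with every parameter recoverable:

- **Copy number.** A 39-arm genome (22 autosomes, acrocentric p arms
  excluded); each sample alters each arm independently with probability
  `scna_event_rate = 0.25` (matching the ~10 altered arms per tumor that
  aneuploid cancers typically show), gains at `log2(3/2)` and losses at
  `log2(1/2)` — one copy in a diploid. Emitted arm ratios (segments and
  DNA matrix alike) carry Gaussian measurement jitter
  `scna_noise_sd = 0.05`, the order of array- or sequencing-derived
  ratio noise; without it, unaltered arms would be exactly zero and the
  low-DNA-variance filter would implausibly remove most of the genome.
  The true aneuploidy score is defined on the emitted ratio, so the
  window → arm-call → count path recovers it exactly.
- **Expression.** In log2 fold-change space,
  `rna = (1 − c_rna)·dna + ε` and `prot = (1 − c_prot)·rna + η`. The
  compensation fractions are per-gene Beta draws around class means —
  complex genes `c_prot = 0.6`, `c_rna = 0.05`; non-complex
  `c_prot = 0.15`, `c_rna = 0.2` — encoding strong protein-level
  buffering of complex subunits and mild RNA-level regulation elsewhere;
  complex genes also get tighter RNA noise (multiplier 0.6). Noise is
  Gaussian in log2 space, the simplest model consistent with log-ratio
  data that keeps every expectation closed-form. RNA is emitted on the
  linear scale around a log-normal baseline (log2 mean 3, s.d. 1.5) so
  the bottom-decile expression filter has real work to do; protein is
  emitted as zero-centered log2 ratios, the native scale of
  isobaric-label proteomics.
- **Pathway coupling.** Genes belong to one of `n_pathways = 50`
  pathways. The RNA-noise scale spans `sigma_rna_range` across pathways,
  and the *relative* protein-noise scale (protein noise expressed per
  unit of RNA-signal standard deviation, so the two axes are comparable)
  follows a Gaussian copula with rank correlation `pathway_coupling`
  against it. Coupling −1 forces pathways with high DNA–RNA correlation
  to have low RNA–protein correlation and yields a strongly negative
  pathway-level association; +1 the reverse. The default −0.75 produces
  the negative coupling characteristic of tumor proteogenomic cohorts.
  Because the coupling is carried by pathway noise and not by complex
  membership, restricting the pathway analysis to either gene class
  preserves its sign — a robustness property the tests assert.

Default problem sizes in the tests and the acceptance script (hundreds
of genes, 80–100 samples, tens of pathways) keep full runs in seconds to
minutes while leaving every group and pathway well populated; sample
counts match the 80–110 per cohort typical of this data type, gene
counts are scaled down from the 7–12k of real cohorts.

What the generator does **not** emulate: isobaric-label ratio
compression, batch effects, purity mixtures (purity is only a covariate
column), focal sub-arm events, and single-cell variability. Passing
recovery tests therefore demonstrate that the estimators are correct
under the stated generative model — not that real-data values will match
any particular magnitude. Real cohorts also need genome-doubled samples
removed (`drop_genome_doubled()`), multi-isoform protein tables
collapsed to gene level beforehand (the package assumes gene-level
inputs), and attention to the fact that reported correlation cutoffs are
data-dependent.

## Known limitations

- The arm-call rule is a weighted window mean, not a segmentation
  consensus; heavily fragmented genomes may call arms differently than a
  re-segmentation would.
- The hypergeometric over-representation test operates on flat gene
  sets; no ontology-graph redundancy handling.
- Bootstrap p-values are Monte-Carlo and bounded below by
  \(1/(B + 1)\); claims at very small FDR need `n_boot` sized
  accordingly.
- Pan-cancer aggregation weights tumor types equally regardless of
  cohort size by design; switch `weighted = TRUE` to change that.
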