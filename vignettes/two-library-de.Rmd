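---
title: "Two-library differential expression: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-library differential expression: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twolibDE)
```

## The problem

Early transcriptome studies in non-model species often sequenced **one
pooled library per condition**: RNA from several animals mixed, one lane
each. With no replicates there is no within-condition variance estimate, so
differential expression is assessed by an exact test on the two observed
counts, treating sequencing as the only noise source. twolibDE implements
this analysis — RPKM quantification, the Audic–Claverie (AC) exact test
with BH-FDR thresholding, library-specific gene detection, hypergeometric
term enrichment and 2^−ΔΔCt qPCR validation — together with a synthetic
data generator that makes every stage testable against known ground truth.

## The model

### Quantification

`compute_rpkm()` implements `RPKM = 10^9 C/(N L)`. The library total `N`
defaults to the column sum of the count table, which equals "reads uniquely
aligned to all genes" whenever the table covers all detected genes; TSV
metadata lines (`#lib_total_a=`) allow overriding with externally known
totals. Note that RPKM uses the *library* total, not per-gene sums, so the
algebraic identity `sum(RPKM * L)/1e9 * N = sum(C)` holds exactly and is
tested.

### Fold change and the zero floor

The reported ratio is `log2(RPKM_pregnant / RPKM_nonpregnant)`. For genes
expressed in only one library this is infinite; published analyses of this
design nevertheless report large finite ratios (up to ~10), implying some
floor. How the original computation handled zeros is not stated anywhere we
could find, so the package makes the choice explicit: `zero_floor`, default
the RPKM a **single read** would produce for that gene in the smaller
library — the smallest observable nonzero expression, and the most
conservative finite stand-in. Genes where the floor was active are flagged
in the output (`floored`), so downstream consumers can distinguish measured
from floored ratios.

### The Audic–Claverie test

For counts `x` (depth `N1`) and `y` (depth `N2`),

$$p(y|x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

the posterior predictive probability of `y` given `x` under a flat prior on
the per-gene Poisson rate. Over `y` this is negative-binomial with size
`x+1` and success probability `N1/(N1+N2)` — which gives an independent
route (`pnbinom`) used in the test suite to cross-check the
implementation, and guarantees normalization. The two-sided p-value doubles
the smaller cumulative tail: `2S` with `S = Σ_{i≤y} p(i|x)` when `S ≤ 0.5`
(the boundary `S = 0.5` deliberately falls on this branch, so
`ac_pvalue(0, 0, N, N)` is exactly 1), else `2(1−S)`.

Two numerical points matter:

* all point probabilities are evaluated in log-space via `lgamma`, so
  counts of any magnitude are safe;
* on the `2(1−S)` branch the complement is **never formed by
  subtraction** — when `S ≈ 1` the expression `1 − S` loses up to eight
  significant digits in double precision. Instead the upper tail
  `Σ_{i>y} p(i|x)` is summed directly, in chunks of 64 terms until the
  running chunk falls below 1e-17 of the accumulated tail (terms decay at
  least geometrically beyond the mode, at asymptotic rate
  `r/(1+r)`). Both branches therefore keep full relative precision.
  Sums rely on R's extended-precision (long double) accumulator, which
  serves the same purpose as explicit compensated summation.

The test's factorials require integer counts; the package applies the test
to **raw counts**, with the library totals carrying the depth
normalization, as the statistic's derivation assumes. Genes with zero
counts in both libraries carry no information and are excluded from testing
(reported via the `n_untested` attribute).

### Multiple testing and calls

`bh_adjust()` is Benjamini–Hochberg step-up with an explicit family size
`m_total`, which matters in two places: the genome-wide scan (family = all
genes with at least one read) and pathway Q-values, where only the top
rows of a table may be available but the family is all pathways with an
annotated DEG (e.g. 242). It delegates to `stats::p.adjust(..., n =
m_total)`; the test suite verifies the step-up arithmetic independently.
Calls use the conventional thresholds FDR ≤ 0.001 and |log2 ratio| ≥ 1
(both boundaries inclusive); `detect_specific()` flags genes with at least
`min_count` reads in one library and none in the other. The minimum count
defining "expressed" for specificity is not standardized in this design;
it is exposed as a parameter (default 1).

### Enrichment

`hypergeom_upper_p()` computes `P(X ≥ m)` for
`X ~ Hypergeom(N, M, n)` by summing the upper tail directly in log-space
(`lchoose`). Since the upper tail *is* the quantity reported, no
`1 − CDF` cancellation can occur and extreme p-values (1e-15 and below)
retain full relative precision — necessary to reproduce published tables at
printed precision. `enrich()` recomputes `N` (universe = genes with any
annotation) and `n` (DEGs inside the universe) from the annotation set
rather than trusting caller-supplied totals; `report_table3()` provides the
complementary mode where printed `(N, n, M, m)` ingredients are taken at
face value to rebuild a published table. Terms with `m = 0` are not tested
and do not count toward the Bonferroni factor; the BH family size for
pathways is an explicit argument because published totals typically count
every pathway with ≥ 1 annotated DEG, listed or not. GO categories
(BP/CC/MF) are tested jointly by default, matching how classified-group
counts are usually reported; per-category analyses can be run by
subsetting the annotation set.

### qPCR

`ddct_ratio()` computes replicate-level ΔCt (target − reference, paired by
replicate index, assuming target and reference are measured in the same
runs), condition ΔCt as the replicate mean, ΔΔCt as pregnant −
nonpregnant, and the ratio `2^−ΔΔCt`. Because the reference is subtracted
within each condition, any constant Ct shift in one condition (plate or
efficiency offset) cancels exactly — a property tested explicitly. The
replicate ΔCt values feed a two-sample t-test; Student's equal-variance
version is the default (Welch by `var_equal = FALSE`). Noise-free panels
have zero within-group variance, where the t statistic degenerates; the
p-value is then defined as 0 for any mean difference and 1 for none. No
amplification-efficiency correction (Pfaffl) or standard-curve fitting is
attempted.

## The synthetic-data generator

`generate_counts()` emulates the study design this package targets, and its
defaults are fixed at that design: 20,651 genes; library sizes 13,549,560
(nonpregnant) and 13,676,394 (pregnant); 8.3% true-DE genes of which 60%
are up in the pregnant library (matching the observed 1033:691 up:down
split); 7.1% / 9.7% of genes expressed in only one library; true
|log2 fold changes| drawn N(2, 0.5) truncated at 0; gene lengths uniform on
200–10,000 bp. Relative abundances are log-normal (`sdlog` 1.2), giving the
heavy right tail typical of RNA-seq; expected counts are scaled per library
so each library's expected total equals its configured size; counts are
negative binomial with a single dispersion knob (default 0.1, standing in
for the biological variance that pooling three animals leaves in the
library; 0 gives pure Poisson — the AC test's own sampling model, which is
what calibration studies use). Library-specific genes are drawn
zero-truncated (inverse-CDF: `u ~ U(P(0), 1)`, then the Poisson/NB
quantile), so the "≥ 1 read in the expressed library, 0 in the other"
invariant holds exactly, not just in expectation. One integer seed drives
every draw, so identical configs reproduce identical tables bit for bit.

Two deliberate simplifications, and what they imply for the tests:

* **No read-level simulation.** Counts are drawn directly; alignment
  ambiguity, positional bias and adaptor artifacts are absent. Passing
  calibration tests therefore validates the *statistics*, not the upstream
  mapping.
* **Composition effects are real but mild.** Scaling each library's
  expected counts to its total means that when DE is sign-imbalanced, null
  genes acquire a small opposite shift in relative abundance (as in real
  sequencing, where library size is fixed by the instrument). With 10% DE
  at |lfc| = 2 the shift is ≈ 0.2 on the log2 scale — well inside the
  |log2 ratio| ≥ 1 gate, so false calls are not inflated, but deep-library
  AC p-values of null genes are visibly sub-uniform in that regime. Null
  *calibration* claims are therefore always evaluated at `frac_de = 0`.

`generate_annotations()` plants `enriched_terms` terms whose membership is
drawn from true-DE genes at rate `enrichment_strength` (1 = term built
solely from DEGs), remaining members and all other terms uniform.
`generate_qpcr_panel()` builds Ct values whose expected 2^−ΔΔCt equals the
requested ratio, with Gaussian per-measurement noise; with noise the
recovered ratio is slightly convex-biased (Jensen), ≈ 0.3% at sd 0.1 with
triplicates — far inside the tolerances used.

## Calibration results the suite verifies

The test suite and `scripts/acceptance.R` recompute (never hard-code) the
following, at the problem sizes given:

* Null Poisson simulations (10,000 genes, 10^7-read libraries,
  `frac_de = 0`): AC rejection rates at α = 0.05 and 0.01 within three
  binomial standard errors of α, and essentially zero DEG calls at
  FDR ≤ 0.001 with the fold-change gate.
* Planted simulations (10% DE, |lfc| = 2, 10^7-read libraries, 10 seeds):
  sensitivity above 95% in practice (≥ 80% asserted) with a false-discovery
  proportion far below the 5% bound asserted.
* A term planted purely from true DEGs ranks first by raw p in 10/10 seeds
  (≥ 9/10 asserted) end-to-end (simulate → test → enrich, 2,000 genes,
  10^6-read libraries — sizes chosen to keep the full suite fast while
  leaving power near 1).
* Log-space AC p-values match direct factorial arithmetic and the
  negative-binomial CDF identity to < 1e-10 relative error over
  `x, y ≤ 30` and depth ratios {1, 2, 10}; the hypergeometric tail matches
  exact binomial-coefficient enumeration to < 1e-12 on an `N ≤ 60` grid.
* The shipped pathway-table ingredients (`inst/extdata/`) reproduce their
  published p and Q columns to printed precision (e.g. 2.05e-15 for the
  complement/coagulation row; BH over the 242-pathway family).

## Known limitations

* The AC test models sequencing (Poisson) noise only. With biological
  overdispersion (NB `dispersion > 0`) it is anti-conservative — the
  historical weakness of unreplicated designs; the generator's dispersion
  knob exists precisely so users can see this. The package deliberately
  does not implement replicate-aware NB GLMs; use edgeR/DESeq2 when
  replicates exist.
* Enrichment treats annotations as flat gene→term sets: no GO-graph
  ancestor propagation, no between-term correlation correction.
* qPCR analysis assumes equal amplification efficiency between target and
  reference.
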