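---
title: "Models and methods behind ribote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribote)
```

ribote analyses paired RNA-seq and ribosome-profiling (Ribo-seq) count data
from two-condition microbial experiments — the motivating setting is
oxidative stress in the halophilic archaeon *Haloferax volcanii* — and asks
three questions: which genes change in transcript abundance, ribosome
occupancy, or translation efficiency; which ribosome-associated small RNAs
(sRNAs) look like they are genuinely translated; and whether the predicted
mRNA targets of candidate regulatory sRNAs are enriched for translational
change.  This vignette records the models, the tunable parameters, and the
design decisions, in enough detail that a reader can audit every number the
package produces.

## The count model

Counts for gene $g$ in library $j$ are modelled as negative binomial (NB),

$$ y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
   \mathrm{Var}(y_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2, $$

with the dispersion parameterized as $\alpha$ so that $\sqrt{\alpha}$ is the
biological coefficient of variation and $\alpha = 0$ degenerates to Poisson.
This parameterization is stated explicitly to avoid the recurring ambiguity
with the `size` ($r = 1/\alpha$) convention.

Library depths are normalized by **median-of-ratios size factors**: $s_j$ is
the median over genes of $y_{gj}$ divided by the gene's geometric mean
across libraries, computed over genes with all-positive counts.  This
estimator assumes most genes are unchanged between conditions; a simulation
in which every gene carries an effect violates it and will show a global
shift (the test suite constructs its effect-recovery experiments with a
null majority for exactly this reason).

**Dispersions** are estimated per gene by the method of moments on
size-factor-normalized counts: within each condition,
$\hat\alpha_c = (s_c^2 - \bar k_c)/\bar k_c^2$, pooled across conditions
with weights $n_c - 1$, truncated at zero and floored at $10^{-8}$ (so
degenerate genes — constant replicates — behave as near-Poisson rather than
producing negative variances).  No information is shared across genes: the
estimator is transparent and testable, at the cost of more per-gene noise
than the empirical-Bayes machinery of the established differential-
expression tools.

## Wald tests and the t reference

Each contrast is fitted per gene by iteratively reweighted least squares
for the NB log-linear model with offsets $\log s_j$; the marginal
(per-assay) model is

$$ \log \mu_{gj} = \beta_0 + \beta_1 \,[\text{condition}_j = \text{stress}]
   + \log s_j, $$

and `log2fc` is $\hat\beta_1 / \ln 2$.  The Wald statistic is
$\hat\beta_1 / \widehat{SE}(\hat\beta_1)$ with the SE taken from the Fisher
information at the fitted values.

Because $\alpha_g$ is *estimated* from only
$\nu = \sum_c (n_c - 1)$ residual degrees of freedom (6, at four replicates
per condition) and then plugged in as known, referring the Wald statistic
to a standard normal is anti-conservative: in our null simulations at
$\alpha = 0.05$ dispersion and 4 + 4 replicates the raw type-I rate is
roughly twice nominal.  ribote therefore refers the statistic to a **t
distribution with $\nu$ degrees of freedom** by default — the same device
quasi-likelihood frameworks use to account for an estimated variance — which
restores near-nominal calibration (measured $\approx 0.05$ in the acceptance
suite) without introducing any cross-gene shrinkage.  `p_reference =
"normal"` recovers the plain normal reference for the situations where it
is appropriate (dispersions known, or many replicates).

## Translation efficiency as an interaction

Translation efficiency (TE) is the ratio of the Ribo-seq fold change to the
RNA-seq fold change; on the log2 scale, their difference.  ribote estimates
it as the interaction coefficient of the joint model over all
$2 \times 2 \times n$ libraries,

$$ \log \mu = \beta_0 + \beta_a A + \beta_c C + \beta_{ac}\, A C + \log s_j, $$

with $A$ indicating Ribo-seq and $C$ stress.  Three choices make this
estimate exactly interpretable:

* **No fold-change shrinkage.**  Unshrunk estimates preserve the additive
  identity $\widehat{TE} = \widehat{lfc}_{ribo} - \widehat{lfc}_{rna}$
  (when the marginal fits reuse the joint fit's size factors and
  dispersions), which the test suite verifies to $10^{-6}$.  A shrunk
  estimate would be better ranked but would break this audit.
* **Size factors estimated per library on the combined RNA+Ribo matrix**,
  treating every library symmetrically rather than normalizing the assays
  separately.
* **One dispersion per gene shared across the four assay-condition
  groups** (method-of-moments within group, pooled over
  $\nu = \sum_g (n_g - 1) = 12$ df at four replicates), which is also the
  t-reference df for the TE test.

## Thresholds

| parameter | default | meaning |
|---|---|---|
| `tpm_min` | 10 | detection: mean TPM across a condition's replicates must *exceed* 10 |
| `alpha` | 0.05 | adjusted-p cutoff, strict (`padj < 0.05`) |
| `lfc_min` | 1 | absolute log2FC cutoff, strict (`|lfc| > 1`) |
| `min_reads` | 65 | footprint-profile classification floor, total reads summed over a condition's replicates |
| `orf_min_len` | 30 nt | minimum smORF length, start through stop inclusive |
| `target_p_max` | 0.01 | high-confidence cutoff on target-interaction p-values, strict |

All comparisons are strict.  Where a source prints both "cutoff of 10 TPM"
and "TPM > 10", the strict form is adopted consistently, so a gene with
mean TPM exactly 10, a fold change of exactly 1, or an adjusted p of
exactly 0.05 does not qualify; a p-value printed as "0.00" does.
TPM itself is the direct formula
$10^6 (c_g/\ell_g) / \sum_h (c_h/\ell_h)$ on annotated gene lengths — no
effective-length correction, so values can differ slightly from
assembly-tool output computed on effective lengths.

Genes are partitioned into regulatory classes from the three significance
calls.  TE-significant genes with a substantial transcript-level change
(`|lfc(rna)| > 1`) are `te_and_transcriptional`, or `opposing` when the RNA
and TE fold changes point in opposite directions (both exceeding 1 in
magnitude) — the signature of a transcriptionally induced but
translationally repressed gene; TE-significant genes without such a change
are `te_only`; the rest fall into `both` / `rna_only` / `ribo_only` /
`none`.  The transcript-level side of this partition deliberately uses the
fold-change magnitude, not the adjusted p, because "changed at both levels"
is a statement about effect size.

## Footprint-length coding classification

Elongating ribosomes protect a characteristic ~27-nt footprint, so genuinely
translated transcripts show length histograms sharply enriched at 24–27 nt,
while rRNA fragments, tRNAs and other structural RNAs protected by
secondary structure show distinct, broader or shifted distributions.  The
classifier:

1. sums per-gene length histograms across all biological replicates of one
   condition and converts to percentages; profiles under `min_reads` total
   reads are excluded (low-count profiles are multinomially noisy and
   cluster erratically — the calibration routine reproduces how the
   read-count floor is chosen so that misleading low-coverage positives
   fall below it);
2. always appends a pooled "all CDS" profile (counts summed over all coding
   genes *before* percentage conversion, so deep genes carry more weight);
3. clusters all included profiles with Euclidean distance and complete
   linkage — the defaults of the clustered-heatmap tools this analysis
   mirrors — and cuts the tree at $k = 2, 3, \dots$ until no cluster
   contains both an rRNA reference and a coding reference.  Only rRNA
   participates in the separation criterion; tRNAs are allowed to co-cluster
   with either side.  Identical coding and rRNA profiles (distance zero) are
   flagged as unseparable rather than split arbitrarily;
4. calls an sRNA `coding_like` iff its cluster contains at least one coding
   reference ("any", not "majority", because the pooled CDS profile anchors
   the coding cluster), `not_coding_like` otherwise, and
   `insufficient_reads` when excluded — the Yes/No/NA triple of a
   per-condition coding-cluster column.  Conditions are classified
   independently.

## smORF scanning

`find_orfs()` scans the sense strand (sRNA annotations are stranded; a
both-strands flag exists) for ORFs beginning at ATG, GTG, TTG or CTG —
archaeal smORFs demonstrably initiate at CTG, so alternative starts must be
allowed — and extending to the first in-frame stop.  Length is counted
start through stop inclusive (the convention of the common web scanner is
ambiguous; inclusive is chosen and documented), nested starts sharing a
stop are all reported, and when no stop falls inside the scanned region the
scan can continue into supplied flanking sequence, flagging
`stop_within_region = FALSE`.  `stop_codon_check()` reports per reading
frame whether any in-frame stop lies wholly inside a region — an all-FALSE
verdict is the signature of sequence-only ORF predictions that overrun the
annotated transcript.

## Target overlap and enrichment

"Differentially translated" for the overlap statistic means significant in
the Ribo-seq *or* the TE contrast at the same strict thresholds; the
published target sets include TE-only cases, so the disjunction is the
faithful reading.  Predictions are filtered at `interaction_pvalue < 0.01`;
targets missing from the differential results count as not differential
rather than shrinking the denominator (the published denominators are all
high-confidence predictions, not all tested genes).  Category enrichment
uses the "total hits" convention of homology-based GO mappers (only genes
with at least one category assignment count toward $n$ and $N$), a
two-sided Fisher exact test by summation of tables no more probable than
the observed one, and BH correction across categories.

## The synthetic-data generator

The generator emulates the statistical structure of the motivating study:
4 biological replicates × 2 conditions × 2 assays; NB counts with a
transcriptional effect (`txn_log2fc`, both assays) and a translation-only
effect (`tln_log2fc`, Ribo-seq only); class-specific footprint-length
profiles over 15–45 nt (`coding_peak` places ≥ 70% of its mass on 24–27 nt
with the mode at 27; `rrna_like` is broad and long; `trna_like` narrow near
31 nt); annotation and sequences on a synthetic replicon, with smORFs
embedded (or scrubbed) on demand.  Defaults were fixed once, before any
validation was run, at values a practitioner would call realistic for
deeply sequenced, tightly controlled microbial cultures: dispersion 0.01
(10% CV), baseline means spanning roughly $10^2$–$2\times10^3$ expected
counts, unit library size factors (depth heterogeneity is opt-in).
Per-library sequencing depths are not published for the motivating data
set, so these remain configurable.

One root seed drives documented per-stage substreams (sequence, RNA-seq
counts, Ribo-seq counts, footprint lengths, predictions), so identical
seeds give byte-identical FASTA/GFF3/BED/TSV output and each stage is
individually reproducible.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: positional coverage and three-nucleotide
periodicity; rRNA contamination and multimapping artifacts; correlated
biological replicates; mean-dependent dispersion trends; UTR structure
(most *H. volcanii* transcripts are leaderless); and any relationship
between a gene's sequence and its expression.

## Numerical choices and degenerate inputs

* IRLS: log-link, convergence at $10^{-12}$ on the coefficient change,
  at most 100 iterations, linear predictor clamped to $\pm 30$.
  Genes with all-zero counts are reported with `NA` statistics and excluded
  from the BH correction; a gene with one all-zero condition diverges, is
  clamped, and is flagged `converged = FALSE` rather than crashing.
* Read-to-gene assignment is by alignment start within the gene interval on
  the matching strand; a start inside two overlapping genes goes to the
  gene with the nearer 5′ end, ties broken by annotation order.  Read
  lengths outside the configured range land in a reported overflow bin.
* `NA`/`NaN` p-values propagate through `bh_adjust()` unchanged and are
  excluded from the number of tests.
* The validation suite sizes its simulations for speed at desk scale:
  2,000 genes for the null-calibration check, 500 planted queries for the
  classifier recovery check, 1,500 genes (300 with effects) for the TE
  recovery check, brute-force oracles on all 2×2 tables with $N \le 30$ and
  sequences up to 300 nt.

## Known limitations

Per-gene method-of-moments dispersions are noisy at small replicate
numbers; rankings near the significance boundary are correspondingly
unstable, and the t reference corrects the level, not the ranking.  The
classifier assumes the reference coding and rRNA genes are correctly
labelled and deeply covered.  Genome-scale gene counts from the motivating
study (hundreds of differential genes, detection percentages) depend on the
deposited sequencing data and are deliberately outside the validation
surface; the packaged reference tables cover the printed worked examples
instead.
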