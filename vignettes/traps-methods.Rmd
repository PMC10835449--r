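---
title: "Measuring purifying selection on synonymous variants with synsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring purifying selection on synonymous variants with synsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synsel)
```

## The problem

Synonymous single-nucleotide variants leave the protein sequence unchanged,
yet they can perturb mRNA stability, translation speed and splicing. A
population-level signal of their deleteriousness is the enrichment of
*singletons* — variants seen exactly once in a large cohort — because
negative selection keeps deleterious alleles at the bottom of the allele
frequency spectrum. `synsel` implements this singleton-based framework:
the mutability-adjusted proportion of singletons (MAPS) and its
square-root-recalibrated variant (TRAPS), the codon-optimality annotations
that define the variant classes of interest, the downstream class
contrasts, and a LASSO decomposition of the scores into codon-level
predictors. A deterministic synthetic-data generator supplies
gnomAD-like input tables with known planted selection so that every stage
is testable without external downloads.

## The selection score

For a variant class $S$, the score is the scaled excess of singletons over
a mutability-calibrated expectation:

$$ \mathrm{score}(S) \;=\; \frac{\sum_{c \in S} s_c \;-\;
   \sum_{c \in S} n_c\, \hat p_c}{\sum_{c \in S} n_c}, \qquad
   \hat p_c = \mathrm{clamp}\!\left(\alpha + \beta\, t(\mu_c),\, 0,\, 1\right), $$

where $c$ indexes mutational contexts (trinucleotide, alternate allele,
methylation bin), $n_c$ and $s_c$ are variant and singleton counts, and
$\mu_c$ is the context's relative mutation rate. The calibration
$(\alpha, \beta)$ is a weighted least-squares fit of the per-context
singleton proportion on $t(\mu_c)$, weighted by $n_c$, over a variant
class treated as neutral (synonymous variants in the intended
application). With $t(\mu) = \mu$ this is MAPS; with $t(\mu) = \sqrt\mu$
it is TRAPS.

The square root matters because large cohorts are saturated for mutable
contexts: recurrent mutation makes the singleton proportion fall off
nonlinearly with mutability, and a straight line in $\mu$ — anchored by the
extreme CpG-transition contexts, roughly two orders of magnitude more
mutable than transversions — systematically under-predicts the singleton
proportion of the least mutable contexts. The result is a spurious positive
score for transversions. The package exposes this directly:
`mutability_quartile_diagnostic()` scores the four variant-weighted
mutability quartiles of the calibration universe, and the test suite checks
that the identity-transform fit shows a significantly positive lowest
quartile on saturation-shaped data while the sqrt-transform quartiles all
cover zero.

Because the fit has an intercept, the weighted residuals over the
calibration set sum to zero exactly, so the score of the full calibration
set is zero to numerical precision — an identity the tests assert at
1e-10.

### Uncertainty

Confidence intervals are Wilson score intervals for the observed singleton
proportion, shifted by the expected proportion, which is treated as fixed.
For calibration sets of tens of thousands of variants the coefficient
uncertainty is second-order relative to the binomial noise of the scored
subset; the suite verifies 94–96% empirical coverage of the Wilson
interval at $n = 1000$, $p = 0.1$, and ≥90% coverage of planted offsets
end to end. Group comparisons use a Welch (unequal-variance) two-sample
$t$ test on per-context residual proportions, restricted to contexts with
at least `min_n = 20` variants in the group, with Bonferroni adjustment
over the comparisons reported together. The observation unit for this test
is a design choice — the underlying studies do not state theirs — and
per-context residuals are the natural unit given the calibration; with
groups of only a few hundred variants spread over ~100 context keys, few
contexts clear `min_n` and the test is underpowered, so ordering
statements in the package's checks rely on scores, not p values.

## Codon optimality annotations

* **CSC** (codon stability coefficient): the Pearson correlation, across
  transcripts, between a codon's per-thousand frequency in the transcript
  and the transcript's half-life (hours). Computed by `compute_csc()`
  from a frequency matrix and half-life vector; codons with zero frequency
  variance are flagged missing. Correlations use raw (untransformed)
  half-lives.
* **tAI** (tRNA adaptation index): per-codon availability of decoding
  tRNAs approximated from tRNA gene copy numbers,
  $W_i = \sum_j (1 - s_j)\,\mathrm{copies}_j$ over the anticodons able to
  decode codon $i$, normalized by the maximum. `compute_tai()` ships the
  literature-standard eukaryote wobble penalties
  ($s_{G:U} = 0.41$, $s_{I:C} = 0.28$, $s_{I:A} = 0.9999$,
  $s_{U:G} = 0.68$, Watson–Crick $0$), configurable via the `s` argument;
  methionine's ATG is decoded only Watson–Crick. Codons with zero direct
  availability receive the geometric mean of the nonzero values and are
  flagged.
* **ΔCSC, ΔtAI, ΔGC**: per-substitution deltas, always alternate minus
  reference, so every metric is antisymmetric under reversal. A change
  with ΔCSC < 0 is *optimality-reducing*, ΔCSC > 0 *optimality-increasing*;
  the sign convention (rather than an optimal/non-optimal dichotomy) keeps
  amino acids classifiable even when all their codons have negative CSC,
  as happens for histidine in human data. ΔtAI and ΔCSC enter the
  predictor model as signed deltas — "gain" readings are the positive part
  of the same quantity and can be obtained by the caller.
* **Codon usage bias** per amino acid is summarized as the excess of the
  most-used codon's within-amino-acid fraction over the uniform $1/k$,
  rescaled to $[0, 1]$ by $1 - 1/k$. This operationalizes "average codon
  usage bias" — which has no standard formula — as a quantity that is 0
  for uniform usage and 1 for complete skew, comparable across
  degeneracies.

## Variant ingestion

Variant tables arrive as flat TSV or as VCF with annotations in INFO keys
(`read_variant_table()`). Records must carry allele count and number, a
VEP-style most-severe consequence, the coding-strand trinucleotide
context, a methylation bin, and the reference/alternate codons. Analysis
keeps only records whose most severe consequence is exactly
`synonymous_variant`, which removes missense, predicted loss-of-function
and canonical-splice-disrupting SNVs; under the shipped severity ordering
it also removes synonymous records that additionally carry a splice-region
annotation. Both behaviors are available by supplying a custom severity
ordering.

Context keys are strand-normalized so the middle base is a pyrimidine
(mutability is reverse-complement symmetric); codon fields stay on the
coding strand. Every (context, alternate) pair falls in exactly one of
three classes — CpG transition, non-CpG transition, transversion — and the
classification is total over all 192 possible keys. Methylation bins
(0–2) apply to CpG contexts only; other keys use bin 0.

## The synthetic-data generator

`simulate_dataset()` draws a coding universe (default 200 genes × 300
codons, giving roughly 5×10⁴ observed synonymous variants at the default
sampling rate of 0.4), plants per-codon CSC/tAI tables, and emits every
possible synonymous change with probability equal to the sampling rate.
Singleton status is Bernoulli with

$$ p = \mathrm{clamp}\left(a_0 + a_1 \sqrt{\mu} + \delta\right), \qquad
   \delta = w_\mathrm{tai}(-\Delta \mathrm{tAI}) +
            w_\mathrm{csc}(-\Delta \mathrm{CSC}) +
            w_\mathrm{gc}(-\Delta \mathrm{GC}) + \text{class offsets}, $$

with defaults $a_0 = 0.60$, $a_1 = -0.22$, $w_\mathrm{tai} = 0.05$,
$w_\mathrm{csc} = 0.08$, $w_\mathrm{gc} = 0.03$. Class offsets cover
high-SpliceAI splice-loss (+0.10) and splice-gain (+0.05) variants,
ClinVar-style labels (pathogenic-like +0.06, VUS +0.02), variants in the
30% most constrained (lowest-LOEUF) genes (+0.03), and an optional
randomly *tagged* class with a configurable offset used for recovery
experiments. Mutability is drawn log-uniformly per class — transversions
0.004–0.012, non-CpG transitions 0.015–0.06, CpG transitions 1.0–3.0
(about 100-fold the non-CpG center) with methylation-bin multipliers
0.5/1/1.5 — which reproduces the realistic separation of the three
mutational classes.

Deliberate modeling choices:

* The neutral curve is affine in $\sqrt\mu$, so the TRAPS calibration is
  correctly specified and the MAPS calibration is misspecified. This is
  what lets the suite reproduce the mutability-bias pattern; it encodes
  the saturation/recurrence explanation of that bias rather than
  simulating recurrence mechanistically.
* Planted CSC values are evenly spaced within each amino acid (spacing
  0.15 around a random center, jittered), so synonymous codons are
  meaningfully separated, as in empirical CSC tables; independent uniform
  draws can make two codons effectively tied, leaving the
  reducing/increasing dichotomy undefined for that amino acid.
* The transcript frequency matrix for the CSC assay is constructed with
  noise orthogonalized against the half-life axis, so the planted
  correlations are recovered to within ~0.01 at the default 500
  transcripts; the acceptance bound is ±0.05.
* Non-singleton allele counts follow a truncated geometric; their shape is
  irrelevant to every statistic in the package (only the singleton
  indicator enters).
* Observation sampling is uniform across contexts. Real cohorts observe
  mutable contexts at higher rates (another face of saturation), so the
  generator does not emulate differential discovery — saturation enters
  only through the singleton probability. Saturation-by-amino-acid
  baselines are therefore exercised structurally, not calibrated to
  cohort-level discovery rates.
* Everything is a deterministic function of the config seed (R's default
  generator, fixed offsets per stage), so equal seeds give byte-identical
  tables.

## The predictor decomposition

`build_design_matrix()` aggregates variants into substitution classes —
distinct (reference codon, alternate codon) pairs, optionally stratified
by mutational class — because the selection score is a group statistic and
has no variant-level analogue. Each class with at least `min_n = 50`
variants contributes its score as response, its deltas, degeneracy and
mean transformed mutability as predictors, and its variant count as
weight. `fit_lasso()` standardizes predictors to zero weighted mean and
unit weighted variance (making selection invariant to affine predictor
rescaling), fits a weighted L1-penalized path with `glmnet`, and chooses
the penalty by 10-fold cross-validation with a fixed, logged seed:
`lambda.min` for coefficient estimates and R², `lambda.min + 1SE` for
selection statements. Both are reported; the underlying studies state a
selected set but no rule, so the parsimonious 1SE rule backs the
selected/dropped statements.

One structural caveat the synthetic experiments expose: when selection
acts on ΔGC, it is *not* independent of mutability, because every C→T
change removes one G/C — CpG-transition contexts therefore carry a
systematically positive selection offset, and the calibration projects
part of that selection onto $\sqrt\mu$. Mean class mutability then carries
a real (if ~10× smaller) signal and is not a pure decoy. The
predictor-recovery experiment therefore follows the cleaner design of
adding the linear predictor signal to a neutral pipeline's response
(whose noise has exactly the calibration/binomial structure), where
degeneracy and mutability are genuine decoys and are dropped in ≥90% of
seeded runs, while the full-pipeline variant asserts that the three true
predictors are always selected.

## Downstream analyses

All comparative analyses are pure functions of the annotated variant table
and the calibration model: per-amino-acid reducing-vs-increasing
contrasts; one-sided Mann–Whitney–Wilcoxon tests of GERP distributions
(alternative: reducing > increasing, Bonferroni over amino acids tested,
restricted by default to two-codon amino acids where the dichotomy is
sharpest); saturation of optimality-reducing variants against a
mutability-weighted opportunity baseline over all possible synonymous
changes in the sequence universe (the "expected level" has no stated
construction in the source analyses; opportunity share is the package's
reading); constrained-gene subsets (lowest-LOEUF ⌈30%⌉ of genes);
SpliceAI classes split at delta score ≥ 0.5 for each of donor/acceptor ×
loss/gain independently, unannotated variants excluded; external-predictor
quartiles (stable rank tie-breaking, left-inclusive boundaries); and
ClinVar-style groups with likely/confident labels merged and differences
reported against the benign-like reference.

## Simulation sizes

The test suite fixes its problem sizes as follows: the Fig-1-style
quartile-bias pattern runs 50 seeds at the default ~5×10⁴-variant scale;
offset recovery runs 200 seeds per offset at a 60-gene scale (the Wilson
interval's validity, not power, is under test); predictor recovery runs
50 seeds at a 400-gene scale chosen so the class-level binomial standard
error (~0.012) sits well below the smallest predictor contribution; the
amino-acid contrast uses a single strong-CSC-selection scenario
($w_\mathrm{csc} = 0.25$, 500 genes) sized so the rarest two-codon amino
acid has a comfortable margin; the conservation contrast subsamples 500
variants per side per amino acid from a 1000-gene universe.

## Known limitations

* The generator targets the singleton indicator, not full allele-frequency
  trajectories; no forward or coalescent simulation is involved.
* Passing the synthetic checks shows the statistics behave correctly under
  the stated generative law, not that real-data effect sizes will match:
  real mutability tables, methylation effects, coverage heterogeneity and
  discovery saturation are all richer than the emulation.
* tAI uses gene copy number as a proxy for tRNA abundance with fixed
  wobble penalties; tissue-specific tRNA expression is out of scope.
* The calibration is the linear fit described above; no regularized or
  site-frequency-spectrum models are provided.
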