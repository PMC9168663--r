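---
title: "Detecting bicycle-like gene families from gene structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bicycle-like gene families from gene structure}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicyclr)
```

## The problem

Bicycle genes — a large, rapidly evolving family of putative plant-gall
effectors in aphids — diverge so fast at the sequence level that
BLAST-style homology searches miss most family members in related
species. What the family conserves instead is its *gene structure*: an
unusually large number of unusually short internal coding exons
("micro-exons", typically tens of bases), almost all of which begin in
reading-frame phase 2. `bicyclr` turns that structural signature into a
detector: it scores every annotated transcript in a genome from
coordinates alone, with no use of the encoded protein sequence, and
then corroborates candidate homology through the positional concordance
of introns across a protein alignment.

## The structural feature space

Each transcript is reduced to eight predictors computed purely from its
CDS coordinates:

| predictor | meaning (units: bases or counts) |
|---|---|
| `gene_span_len` | genomic span from the first to the last coding base, introns included |
| `cds_total_len` | summed length of all coding exons |
| `first_exon_len`, `last_exon_len` | lengths of the terminal coding exons (translation order) |
| `internal_exon_mean_len` | mean length of the non-terminal coding exons |
| `n_phase0`, `n_phase1`, `n_phase2` | counts of internal exons starting in each phase |

**Phase convention.** We use the GFF3 phase-column convention
throughout: the phase of an exon is the number of bases that must be
skipped at its start to reach the next codon boundary,
`(3 - (upstream coding length mod 3)) mod 3`, so the first exon always
has phase 0. This is self-consistent, writable to (and checkable
against) the standard phase column, and is implemented in exactly one
function (`exon_phases()`) so that a different nomenclature — e.g. the
intron-phase convention, which labels the *donor* side — could be
swapped in at one place. Phases are always recomputed from coordinates
rather than trusted from the file, because fragmented annotations
commonly carry wrong phase columns; `read_gff3(strict_phase = TRUE)`
turns any disagreement into a hard error.

**Eligibility.** Transcripts with fewer than four coding exons have
fewer than two internal exons, so their internal-exon mean and phase
counts are not meaningfully estimable; they are excluded from training
and scoring and reported in a side table with reasons. The boundary is
sharp: four exons are eligible, three are not. One consequence worth
stating plainly: the classifier is structurally blind to any family
member annotated with three or fewer exons.

Transcripts that fail validation (coding length not a multiple of 3,
overlapping segments) are likewise excluded but carried in the report —
fragmented assemblies produce many such models, and silently dropping
them would hide real candidates from the user.

**Isoforms.** Each transcript is scored independently by default; an
optional `longest_cds_per_gene()` collapse is provided for annotations
with heavy isoform redundancy. Scoring per transcript is the more
conservative default because candidate lists are de-duplicated
downstream anyway, and collapsing first can discard the one isoform
whose structure carries the signal.

## The classifier

A binomial logit-link linear model is fitted to labeled transcripts
(`family` = 1, `non_family` = 0; unlabeled rows are never used in
training, because an unlabeled gene may be an undetected family
member). The fit is iteratively reweighted least squares — Newton
steps with step halving on the log-likelihood — run on internally
standardized predictors for numerical conditioning, with coefficients
reported on the raw scale. Convergence is declared when the largest
absolute coefficient change drops below `tol` (default 1e-10, iteration
cap 100).

**Separation.** A family this structurally stereotyped can be linearly
separable from the background, in which case the maximum-likelihood
coefficients diverge. The fit never fails silently: saturated fitted
probabilities or a hit iteration cap set a `separation` flag in
`training_meta` and raise a warning, and the iteration-capped estimate
is returned (its predicted probabilities, which are all the downstream
steps use, are stable even when the coefficients are not). An optional
ridge penalty on the standardized slopes (`ridge` argument, recorded in
`training_meta`) keeps the coefficients themselves finite when they are
of interest.

**Cutoff selection.** The decision threshold is chosen on a fixed grid,
0 to 0.98 in steps of 0.02, as the point where precision
(TP/(TP+FP)) and recall (TP/(TP+FN)) are closest to equal — the
threshold minimizing |precision/recall − 1|. Rows are predicted
positive at probability ≥ t (closed at the threshold). Grid points at
which no row is predicted positive have undefined precision and are
excluded rather than imputed, which avoids selecting vacuous cutoffs.
Ties are broken deterministically: larger precision + recall, then the
lower threshold. On perfectly separated training data every threshold
above the gap gives precision = recall = 1 and the rule returns the
lowest such threshold; any single value in the tying range is equally
defensible, and the low end errs toward recall on later, noisier data.

**Cross-validation** (`cross_validate()`) repeats the procedure on
random unstratified 70/30 splits (training fraction and replicate count
are arguments; 0.7 and 100 are the defaults), reporting the mean and
standard deviation of the per-replicate cutoffs. Replicates whose train
or test half contains a single class are skipped and counted.
Unstratified splits are deliberate: stratification would understate the
cutoff variability a user will see on a new genome.

**Ablation** (`ablate_predictors()`) retrains with each predictor
dropped one at a time and with each predictor alone, evaluating every
configuration at the *full* model's cutoff. Using the full cutoff for
the single-predictor fits as well (rather than re-selecting per
configuration) keeps all 17 rows comparable on one scale; since a
single-predictor model is a diagnostic, not a deployable classifier, we
accept that its recall at a foreign cutoff can be pessimistic. On
simulations in which the phase-2 exon count carries the dominant
generating weight, dropping it degrades recall far more than dropping
any other predictor — the behavior expected when phase-2 micro-exon
count is the family hallmark — while dropping a predictor with zero
generating weight moves precision and recall by less than the
simulation noise.

## Intron-position concordance

Structural homology of a *candidate set* is corroborated by comparing
intron positions across a gapped protein alignment (produced
externally, e.g. by a gene-structure-aware aligner; `bicyclr` consumes
the alignment plus a per-sequence intron table of residue index and
phase). Each intron is assigned to the alignment column of the residue
immediately preceding it; gap columns never receive introns. Introns
annotated before residue 1 cannot be assigned a residue column — they
are counted separately (`boundary_introns`) and excluded. Per-column
counts of sequences carrying an intron form the bin-size-1 intron
histogram (`project_introns()`, plotted by `plot_intron_profile()` as
fractions).

Concordance between two families is the Pearson correlation of their
per-column *counts* (counts, not fractions, so that family size keeps
its weight; fractions are for plotting). Pearson rather than a rank
correlation is the default reading of an "R" statistic on these
histograms, and the choice is isolated in `concordance_R()`. A constant
profile makes the correlation undefined and is a hard error, not an NA.

Significance comes from a resampling null (`null_distribution()`):

* `permute_columns` (default, self-contained): the column assignment of
  the second profile is permuted, preserving both families' intron
  counts while destroying positional correspondence;
* `unrelated_families`: the observed statistic is compared with
  concordances between the first family and bootstrap row-resamples of
  user-supplied unrelated families over the same joint alignment, which
  mirrors the original analysis when such families are available.

The one-sided empirical p-value uses the add-one rule,
p = (1 + #{null ≥ R_obs}) / (1 + n), so p is never 0 and is exact under
exchangeability. With the default 200 resamples the smallest attainable
p is 1/201 ≈ 0.005; users wanting finer resolution should raise
`n_resamples`.

## What the simulator emulates — and what it does not

`simulate_genome_annotation()` generates the two-class study
conditions: a minority family class with many short internal exons
predominantly of phase 2, and a conventional background. Defaults, with
their reasoning:

* **family exon counts**: 5 + NB(mu = 12, size = 3) — floor 5 and mean
  ≈ 17 exons, matching the family's reported range;
* **family internal exon lengths**: lognormal, median 45 bp
  (sdlog 0.35, floor 9) — micro-exons of tens of bases;
* **family internal-exon phases**: 0/1/2 with probabilities
  0.05/0.05/0.90 — phase-2 dominance with realistic leakage;
* **background exon counts**: 1 + NB(mu = 5.5, size = 1.3) — mean ≈ 6.5
  with a long tail, so some background genes have many exons;
* **background internal exon lengths**: lognormal, median 120 bp,
  sdlog 0.75 — broad, overlapping the micro-exon range in its lower
  tail;
* **background phases**: 0.48/0.30/0.22, approximate genome-wide
  phase frequencies;
* **intron lengths**: lognormal, median 90 bp, floor 40 — compact
  insect-genome introns;
* **sizes**: 500 family / 5000 background transcripts.

Phase targets are sampled *first* and exon lengths then stretched by
0–2 bases so the realized cumulative-length phase equals the target
(with the final exon padding the total to a multiple of 3). The phase
histogram is the classifier's key signal, so it must be controllable
rather than emergent; the 0–2 base adjustment perturbs the length
distributions negligibly. Every generated transcript validates, and a
truth table of all eight features is recorded at generation time — the
feature extractor is tested against it for *exact* equality, not
tolerance.

The simulator deliberately does not emulate: nucleotide sequence (no
codon usage, no splice-site motifs), UTRs, alternative isoforms,
overlapping or nested genes, annotation errors, or fragmented gene
models. Passing tests on these fixtures therefore demonstrates the
correctness and statistical behavior of the *method* — not that any
particular real genome's background is as well-behaved. On real
annotations the labeled background is noisier (mislabeled or broken
models), which widens the cutoff distribution; the cross-validation
summary is the diagnostic to watch.

`simulate_aligned_families()` plays the same role for the concordance
test: a truth set of shared intron columns, a per-sequence carry
probability, Poisson noise introns and per-column gaps. Its alignment
is random letters — alignment *quality* is outside the model, as the
aligner is external.

## Numerical choices and edge cases

* Cutoff grid fixed at 0–0.98 step 0.02 (50 points); the CLI exposes
  `--grid-max`/`--grid-step`.
* Predicted-positive is p ≥ t (closed); documented because boundary
  rows exist whenever predicted probabilities saturate.
* IRLS: tol 1e-10 on the max absolute standardized-coefficient change,
  cap 100 iterations, step halving (up to 2^-30) guarantees monotone
  log-likelihood; weights floored at 1e-12.
* Standard errors come from the unpenalized observed information on the
  raw scale at the final fit; under separation or ridge they are
  approximations and flagged as such by the metadata.
* KS comparison of exon counts uses the asymptotic p-value: counts are
  heavily tied and the exact method is unavailable with ties.
* Degenerate inputs fail loudly and specifically: start > end names the
  file line; conflicting strands name the transcript; an out-of-range
  intron names the sequence; a constant intron profile is an
  "undefined correlation" error.

## Problem sizes

The test suite runs the full pipeline at the default study size
(500 family / 5000 background transcripts), parameter recovery at
n = 2000 over 100 replicates, cutoff-scan equivalence over 100 random
curves, and concordance power/calibration over 100 related and 200
unrelated seeded family pairs with 200 resamples each — sizes at which
the statistical properties of interest (coefficient recovery within
3 SE, near-nominal 5% false-positive rate, power at share probability
0.5) are measurable with binomial noise a few percent wide.

## Known limitations

* The classifier sees structure only; a gene family that is
  stereotyped in sequence but not structure is invisible to it, and a
  background gene that mimics the structure (many short phase-2 exons)
  is a false positive by construction.
* Transcripts with < 4 coding exons are never scored.
* The concordance test assumes column exchangeability under the null;
  strong regional structure in intron density (e.g. domain boundaries)
  makes the permutation null anti-conservative, which is when the
  `unrelated_families` mode is worth the extra inputs.
* The intron-to-column rule (column of the preceding residue) is one
  deterministic convention; alignments that place homologous introns
  one residue apart count them as discordant. Shared-column recovery is
  therefore conservative.
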