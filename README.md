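# bicyclr

Gene-structure-based detection of bicycle-like gene families.

## What problem this solves, and for whom

Bicycle genes are a large aphid gene family encoding putative plant-gall
effectors. They evolve so rapidly in sequence that BLAST/HMM searches
recover only a fraction of the family in related species — but their
*gene structure* is strikingly conserved: many short internal coding
exons ("micro-exons", tens of bases), almost all starting in
reading-frame phase 2, with at least ~5 and on average ~17 exons per
gene. `bicyclr` is for comparative genomicists who have genome
annotations (GFF3) for insect species and want to find candidate
members of such structurally stereotyped families when sequence
homology search has run out of signal.

The package provides:

1. **Structural feature extraction** — eight predictors per transcript,
   from CDS coordinates alone: genomic span (start to stop codon,
   introns included), total coding length, first/last coding exon
   length, mean internal exon length, and counts of internal exons
   starting in phase 0, 1 and 2 (GFF3 phase convention,
   `(3 − L mod 3) mod 3` for upstream coding length `L`).
2. **A binomial logit-link classifier** over those features, fitted by
   iteratively reweighted least squares, with the decision cutoff
   chosen on a 0–0.98 grid (step 0.02) where precision = TP/(TP+FP)
   and recall = TP/(TP+FN) are closest to equal; plus 70/30
   cross-validation of the cutoff and drop-one / single-predictor
   ablation.
3. **Intron-position concordance** — introns are projected through a
   gapped protein alignment to the column of the residue preceding
   them; two families' per-column intron counts are compared by
   Pearson correlation R, with significance from a resampling null
   (column permutation, or bootstrap over unrelated families).
4. **A synthetic-data generator** for annotations and aligned families
   with recorded ground truth, so the entire pipeline is testable
   end to end.

## Worked example

```r
library(bicyclr)

# a small synthetic genome: 60 family genes among 400 background genes
params <- genome_sim_params(n_family = 60, n_background = 400, seed = 42)
sim <- simulate_genome_annotation(params, out_dir = "demo")

tx <- read_gff3(sim$paths$gff3, label_table = sim$paths$labels)
ft <- feature_table(tx)
# 312 transcripts are eligible (>= 4 coding exons and valid);
# 148 are excluded with reasons (mostly background genes with < 4 exons)

model <- train_classifier(ft$features)
#> Warning: possible (quasi-)separation: fitted probabilities saturate or
#> IRLS hit the iteration cap; coefficients may be unstable
print(model)
#> <bicycle_classifier>
#>   intercept: 42.3838   cutoff: 0.02
#>          gene_span_len          cds_total_len         first_exon_len
#>             0.01009939             0.02366792            -0.09494037
#>          last_exon_len internal_exon_mean_len               n_phase0
#>            -0.09244257            -0.86538391            -8.21688915
#>               n_phase1               n_phase2
#>            -9.95384343             9.56624163
#>   trained on 60 family / 252 non_family rows; converged=FALSE [separation flagged]

report <- classify_candidates(model, ft$features)
sum(report$candidate)                              # 60 candidates
sum(report$candidate & report$label == "family")   # 60 true family members
```

What the numbers mean: the family and background classes in this small
simulation are linearly separable, so the fit flags quasi-separation
(the warning is informational — predicted probabilities are stable even
though raw coefficients are not), every threshold on the grid achieves
precision = recall = 1 and the tie-break selects the lowest (0.02). The
coefficient signs tell the structural story: many phase-2 internal
exons push a transcript toward the family, phase-0/1 exons and long
internal exons push it away. All 60 flagged candidates are true family
members.

Corroborating a candidate set through intron positions:

```r
pair <- simulate_aligned_families(alignment_sim_params(seed = 42),
                                  related = TRUE)
intron_concordance_test(pair$family_a, pair$family_b,
                        n_resamples = 200, seed = 1)
#> <concordance_result> R = 0.9649, empirical p = 0.004975
#>   (permute_columns, 200 resamples, mean null R = 0.0022)
```

The two families place introns at a shared set of alignment columns, so
the observed concordance (R = 0.96) exceeds every one of the 200
column-permutation resamples (p = 1/201 ≈ 0.005, the smallest value
200 resamples can produce), while the null is centred at 0.

A command-line wrapper (installed to `exec/bicyclr`) exposes the same
pipeline as subcommands: `simulate`, `features`, `train`, `crossval`,
`ablate`, `classify`, `concordance`; every run is seeded and writes a
JSON log of its parameters and input checksums.

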