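# shoctscan

Profile-HMM discovery pipeline for short, C-terminally biased protein
domains, with a fully ground-truthed synthetic benchmark.

## The problem

Very short domains (~30 residues) that sit at a fixed position on their host
proteins — the motivating case is SHOCT, the *SHOrt C-Terminal domain*
family found within 50 residues of the C-terminus of thousands of bacterial
proteins — are systematically missed by generic similarity searches and are
hard to validate once found: at that size, how do you know your model is not
matching noise? `shoctscan` implements the complete discovery-and-validation
route as a tested, reusable R package:

1. **Iterative single-query expansion** (`iterate_search()`,
   jackhmmer-style): round 0 builds a single-sequence profile with
   BLOSUM62-conditional emissions; each round searches, re-aligns the
   included sequences by Viterbi, rebuilds, and stops at a fixed point.
2. **Profile HMM construction and search** (`build_hmm()`, `hmm_search()`):
   a local multihit profile HMM scored in bits,
   `log2 P(seq | model) / P(seq | null)`, with *dual inclusion thresholds* —
   24.0 bits per sequence, 15.4 bits per domain envelope — so repeated
   domain copies on one protein are detected.
3. **Reversed-alignment decoy control** (`run_decoy_control()`): a second
   HMM built from the column-reversed seed alignment, identical in length,
   information content and null model, searched over the same database. A
   sound threshold leaves *zero* decoy sequences at or above it while the
   true model shows the family plus an excess of sub-threshold relatives.
4. **Annotation censuses**: C-terminal positional bias (`terminal_bias()`),
   distinct-species taxonomy (`taxon_breakdown()`), N→C domain
   architectures (`architecture_census()`) and per-protein copy number
   (`copy_number_census()`).
5. **Synthetic proteomes with ground truth** (`generate_proteome()`): a
   planted two-helix motif family (invariant Gly/Glu, conserved
   charged/hydrophobic positions, no indels inside the helices), weakened
   sub-threshold homologs, decoy domain families in realistic
   architectures, taxonomy labels — so sensitivity, precision and
   calibration are *measurable* (`evaluate_recovery()`).

The forward/Viterbi dynamic programming is exact compiled code, validated
against an exhaustive path-enumeration reference
(`path_enumeration_score()`) to 1e-9 relative. See the methods vignette
(`vignettes/domain-discovery.Rmd`) for the model, the estimation choices and
the generator's design.

## Worked example

Discover a planted family from one member, then validate and census it:

```r
library(shoctscan)

sim <- generate_proteome(n_family = 50, n_background = 2000, n_weak = 0,
                         rng_seed = 42)

it <- iterate_search(sim$db[sim$db$id == "FAM_0001", ], sim$db)
glance(it)
#>   rounds converged n_included model_m seq_bits dom_bits
#> 1      3 TRUE              50      30       24     15.4

evaluate_recovery(it$final_hits, sim)
#>   n_planted n_recovered sensitivity n_hit_domains n_true_domains precision
#> 1        50          50           1            50             50         1

ann <- hits_to_annotations(it$final_hits, sim$db)
terminal_bias(ann)
#>   window n_proteins n_within fraction
#> 1     50         50       46     0.92
```

Starting from a single sequence, three rounds reach a fixed point: all 50
planted family members are included, the model has collapsed onto the
30-column planted motif (`model_m = 30` from a ~300-residue query), every
planted region is recovered (sensitivity 1) with no false envelope
(precision 1), and 92% of the recovered proteins carry the domain entirely
within the last 50 residues — the planted C-terminal bias. The decoy
control on the full-scale universe (`run_decoy_control()`, 10,260 proteins)
yields zero reversed-model sequences at the 24-bit threshold, and
`autoplot()` draws the two-series score histogram with the threshold line.

A thin command-line wrapper over the same functions is included
(`inst/scripts/shoctscan.R`), writing each stage's artifacts into a
reproducible run directory.

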