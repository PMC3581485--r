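---
title: "Discovering short C-terminal domains with profile HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering short C-terminal domains with profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoctscan)
```

## The problem

Short protein domains are easy to miss. A ~30-residue motif carries little
total information, sits below the radar of generic similarity searches, and —
when it is positionally constrained, say to the last 50 residues of a protein
— is easily dismissed as a spurious C-terminal tail. SHOCT ("SHOrt C-Terminal
domain") is the canonical example: a predicted two-helix domain of about 30
residues, found almost exclusively within 50 residues of the C-terminus of
thousands of bacterial proteins, with one strongly conserved glycine, one
strongly conserved glutamate, two further conserved charged positions and
five conserved hydrophobic positions, and no tolerated indels inside either
helix or the connecting loop.

`shoctscan` implements the complete computational route by which such a
family is discovered and validated, as a reusable, tested pipeline:

1. **Iterative expansion** from a single query sequence
   (`iterate_search()`, jackhmmer-style);
2. **Seed alignment → profile HMM** (`build_hmm()`) and **thresholded
   search** (`hmm_search()`) with a *sequence* inclusion threshold of 24.0
   bits and a *domain* inclusion threshold of 15.4 bits;
3. a **reversed-alignment decoy control** (`run_decoy_control()`) that
   empirically validates the threshold;
4. **censuses** of the resulting annotation: C-terminal positional bias
   (`terminal_bias()`), taxonomy (`taxon_breakdown()`), domain architectures
   (`architecture_census()`) and per-protein copy number
   (`copy_number_census()`).

Because the reference numbers of the original analysis are tied to specific
database releases, the package ships a synthetic-proteome generator
(`generate_proteome()`) that plants a SHOCT-like family with full ground
truth, so that every stage can be exercised and *scored* — sensitivity,
precision, calibration — without any external download.

## The probabilistic model

### Architecture

`build_hmm()` constructs a classic profile HMM: one match state per
sufficiently occupied alignment column (non-gap occupancy ≥ 0.5 by default),
with insert and delete states between them. Search uses a *local, multihit*
architecture:

* entry is uniform over match states (probability 1/M);
* each non-terminal match state exits to the end state with probability
  `p_exit` (default 0.05), the last one with probability 1;
* after a completed pass the model re-enters with probability `re_entry`
  (default 0.5), so several domain copies per sequence are found — required
  for repeat-bearing proteins (`multihit = FALSE` gives a uni-hit model);
* flanking and inter-domain residues are emitted by background states whose
  self-loop probability is configured from the target length L as L/(L+2),
  mirroring the standard length model.

The null model emits L background residues with a geometric length term
L/(L+1). A **bit score** is `log2 P(seq | model) / P(seq | null)`, computed
by the forward algorithm over the full path ensemble (`forward_bitscore()`)
or maximized over paths (`viterbi_decode()`, which also reports one envelope
and per-pass score per model pass). All dynamic programming is in log space,
in compiled code; an exhaustive path-enumeration reference
(`path_enumeration_score()`) written in plain probability space validates
both algorithms exactly on small instances (the test suite checks relative
agreement to 1e-9 on all models with M ≤ 3 and sequences up to length 6).

### Estimation choices

* **Match emissions**: observed counts with a uniform add-k pseudocount,
  default k = 0.2 per residue. The smaller-than-classical default matters:
  iterative search rebuilds models from very small alignments, and add-1
  smoothing flattens a 5-sequence model so much that a 30-residue domain
  cannot reach 24 bits. k = 0.2 keeps small models informative while still
  regularizing; with seed alignments of tens of rows the difference is
  negligible.
* **Single-sequence models** (round 0 of the iterative search) use BLOSUM62
  conditional probabilities p(b | a) — exactly the device jackhmmer uses.
  A count-based single-sequence model scores an identity at ~0.7 bits per
  column, which makes single-query discovery of a 30-residue domain
  impossible at a 24-bit threshold; substitution-informed emissions give
  2–3 bits per conserved identity and are the field's standard solution.
* **Transitions**: counts regularized towards a canonical prior favouring
  match→match (means 0.90/0.05/0.05 at concentration 3). A uniform prior
  would give t(M→M) = 0.5 on a single-row alignment — a one-bit-per-column
  traversal tax that destroys long models.
* **Insert emissions** are fixed to the background frequencies (so inserts
  are score-neutral), the standard practice.
* **Null frequencies**: a standard database amino-acid composition table;
  `null = "uniform"` is available. Non-standard residue codes (B, Z, X, U,
  O) are collapsed to a wildcard that scores zero bits everywhere.
* **Ties** in Viterbi are broken match > delete > insert, making envelopes
  deterministic.

Bit scores from these choices *approximate* rather than reproduce HMMER's
(which uses Dirichlet mixture priors, sequence weighting and effective
sequence number estimation); the dual thresholds 24.0/15.4 are retained as
the reference operating point and behave equivalently on the synthetic
families (see the decoy control below).

## Iterative search

`iterate_search()` starts from one query, builds the single-sequence model,
then repeats: search the database; include every sequence meeting both
thresholds (the query is always retained); re-align the included set to the
current model by Viterbi; rebuild; stop when the included set is unchanged
between consecutive rounds (`max_iter`, default 5, is a guard — inclusion
sets may shrink when scores drift, so a fixed point is not guaranteed).

One design point deserves emphasis. When a sequence has several Viterbi
passes, **all** of them contribute to its alignment row (the
highest-scoring pass wins contested columns). If instead only the best pass
per sequence is kept, the profile can drift wholesale onto a *different*,
better-conserved domain that co-occurs with the target on multi-domain
proteins — we observed exactly this failure against the synthetic decoy
families. Merging passes leaves the column-occupancy rule, not pass
selection, to decide which columns survive; columns belonging to co-occurring
domains present in a minority of members fall below 50% occupancy and are
pruned, and the model converges onto the region shared by *all* members.

`subsample_validation()` implements the closure check: sample n member
sequences, re-search from each, and report the mean fraction of identified
sequences absent from the membership list. "Identified" counts sequences
(not domain regions) in the final round of each search — the natural reading
when membership is a per-sequence property; both conventions exist, and the
per-round alternative is recoverable from the returned history.

## The reversed-alignment decoy control

`run_decoy_control()` builds a second HMM from the column-reversed seed
alignment (`reverse_alignment()`; row order, ids and residue composition are
untouched) and scores the same database under both. The reversed model has
the same length, the same per-column information content and the same null
model — it differs *only* in column order — so it is a matched negative
control for the score distribution. A sound inclusion threshold leaves no
decoy sequence at or above it, while the true model shows both the
supra-threshold family and an excess of sub-threshold scores (distant true
relatives). `bitscore_histogram()` and `autoplot()` reproduce the classic
two-series histogram with the threshold line; the default histogram floor is
0 bits and the default bin width 2 bits.

A numerical caveat: because background scores centre just below 0 bits, a
count of retained scores with a floor of 0 sits on the steep shoulder of the
background distribution, where sub-bit model asymmetries (the reversed model
differs in the placement of its rare boundary deletions) can shift hundreds
of sequences across the floor. The sub-threshold *excess* is therefore most
meaningfully quantified between the domain and sequence thresholds
(15.4–24 bits), a band the background distribution essentially never
reaches — the acceptance script and tests measure it there, while the
histogram keeps its full 0-bit support.

## The synthetic proteome

`generate_proteome()` emulates the search universe at desk scale. Its
defaults are the package's reference study conditions and were chosen once,
from the motif description and from a calibration of realized bit scores
against the 24.0-bit threshold, before the test suite was frozen:

* **Motif** (`motif_model()`): 30 columns; helix blocks at 3–14 and 19–30
  with a 4-residue loop; invariant Gly (column 16, in the loop) and Glu
  (column 8); two charged-preferring and five hydrophobic-preferring columns,
  each conserving a fixed representative residue of its class at
  `p_cons = 0.8`; the remaining 21 framework columns carry a fixed preferred
  residue at weight 0.8. Indels occur only at the two leading boundary
  columns (deletion rate 0.02). The model carries ~76 bits of information,
  so sampled instances score ~65 bits (1st percentile ~35) under a
  seed-built model — comfortably above the 24-bit threshold, as a domain
  curated at that threshold must be. Making the framework literally
  background-like would leave ~15 realized bits and a family invisible at
  its own threshold.
* **Weak homologs**: the motif mixed with background at dilution 0.5 and
  planted in 200 proteins (remote relatives below the detection threshold
  outnumber detectable members). Calibration places ~96% of them below 24
  bits, centred in the just-sub-threshold band — they create the excess the
  decoy control measures.
* **Proteins**: log-normal lengths (median 300, clipped to [60, 2000],
  a typical bacterial proteome shape); background residues i.i.d. from the
  same composition table as the HMM null, so background scores centre near
  0 bits.
* **Placement**: the C-terminal-most instance starts within the final 50
  residues with probability 0.9 (echoing, not reproducing, the reference
  regime); otherwise it is placed well outside the window.
* **Architectures**: five defaults — SHOCT alone (60%) and SHOCT preceded
  by one or two of three decoy domain families (DUF_A/B/C, 40-column
  conserved motifs with mutually dissimilar, aperiodic consensus sequences).
  The decoys exercise the architecture census and, importantly, stress-test
  profile drift in the iterative search.
* **Taxonomy**: species pools (~1 species per 1.6 domain proteins) assigned
  to phyla at the proportions reported for the reference family
  (Firmicutes 29.6%, Proteobacteria 25.3%, Actinobacteria 19.1%,
  Bacteroidetes 5.2%, Cyanobacteria 4.1%, remainder other).

Everything is reproducible bit-for-bit from `rng_seed`, and the truth ledger
(planted coordinates, family labels, architectures, taxa) supports
`evaluate_recovery()` — region-level sensitivity and precision at a 50%
overlap rule.

**What the generator does not emulate**: phylogenetic correlation between
family members (instances are i.i.d. draws from the motif), compositional
heterogeneity of real proteomes (low-complexity regions, signal peptides),
and real secondary structure. Passing tests therefore demonstrate the
pipeline's correctness and calibration under idealized conditions, not its
performance on real UniProtKB data; in particular, real families are easier
in one way (near-identical strains provide stepping stones for iterative
search) and harder in another (biased composition inflates null scores).

## Censuses

All censuses consume the plain annotation table (one row per envelope:
protein, length, domain, 1-based inclusive coordinates, bit score).

* `terminal_bias()` counts a protein as C-terminal iff **every** envelope of
  the target domain starts within the final `window` (default 50) residues —
  i.e. the *entire* domain lies within the window, using envelope
  coordinates. The denominator is proteins, not regions.
* `taxon_breakdown()` counts **distinct species** (the terminal clade-path
  label; strain labels are not collapsed) per clade at the chosen rank,
  with percentages over classified species.
* `architecture_census()` forms each protein's N→C domain tuple (ordered by
  `env_start`, `env_end` as tie-break; repeats kept) and counts proteins per
  distinct tuple. Overlapping envelopes trigger a warning but are ordered
  deterministically.
* `copy_number_census()` tabulates proteins by copy number and conserves
  `sum(copies × proteins) = regions`.

## Problem sizes and numerical notes

The reference study conditions used throughout the tests and the acceptance
script are: 10,000 background + 60 family + 200 weak proteins for the decoy
control (seed 1); a planted family of 50 among 2,000 background for the
iterative search (seed 42); 500 family proteins for the positional census
(seed 11). These sizes give stable statistics (binomial standard errors of a
few percent or less) while a complete run of every analysis stays within a
few minutes on one core. The dynamic programming is exact (no acceleration
filters, no E-value calibration — both are out of scope); log-space
arithmetic makes rescaling unnecessary at any of these sizes.

Known limitations: bit scores are not HMMER-compatible; domain envelopes are
Viterbi pass boundaries, without posterior envelope widening, so envelope
ends can be a residue or two tighter than posterior-based tools would
report; and the novelty statistic depends on the closure of the supplied
membership list, exactly as in the original procedure.

## A worked example

```{r example, eval = FALSE}
library(shoctscan)

sim <- generate_proteome(n_family = 50, n_background = 2000, n_weak = 0,
                         rng_seed = 42)

# discover the family from a single member
it <- iterate_search(sim$db[sim$db$id == "FAM_0001", ], sim$db)
glance(it)
evaluate_recovery(it$final_hits, sim)

# validate the threshold with the reversed-seed decoy
rep <- run_decoy_control(sim$seed_alignment, sim$db)
glance(rep)
autoplot(rep)

# census the recovered annotation
ann <- hits_to_annotations(hmm_search(build_hmm(sim$seed_alignment), sim$db),
                           sim$db)
terminal_bias(ann)
```
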