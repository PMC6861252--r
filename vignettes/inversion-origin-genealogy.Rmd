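---
title: "Breakpoint-flanking genealogies and the origin of overlapping inversions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint-flanking genealogies and the origin of overlapping inversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invorigin)
```

## The scientific problem

Series of overlapping chromosomal inversions — as on the E chromosome
(Muller C) of *Drosophila subobscura* — accumulate sequentially, so their
cytological phylogeny is fixed: each new arrangement derives from the one it
overlaps.  When several inversions share a breakpoint at the molecular
level, the sequence window flanking that breakpoint is inherited through the
same chain of unique origin events, and its molecular genealogy should
branch in the same order as the cytology.  Each inversion that arises by
non-homologous end joining (NHEJ) passes through an extreme bottleneck — a
single founding haplotype — so variation inside a derived arrangement
accrues only by new mutation (plus, marginally, gene conversion), making
breakpoint-flanking windows faithful markers of arrangement history.

A discordance between the two genealogies is therefore informative.  If the
sequences of the youngest arrangements cluster with the *oldest*
arrangement rather than with their cytological parent, the simplest
explanation is that the inversion arose in a **heterokaryotype** and
captured breakpoint-proximal material from the other homolog.  This package
implements that whole argument as a reproducible pipeline:

1. arrangements as ordered, oriented, provenance-tagged fragments;
2. six origin mechanisms and their testable predictions;
3. a coalescent-style simulator of breakpoint-flanking alignments under
   each mechanism's lineage history;
4. a self-contained statistics and genealogy stack (π, *S*, singletons,
   haplotypes, Jukes–Cantor distances, Hudson's *F*~ST~ with permutation
   tests, neighbor joining with bootstrap);
5. a concordance verdict that classifies the inferred genealogy.

## Arrangements and breakpoint anatomy

Fragments are atomic: breaks occur only at fragment boundaries, mirroring
how breakpoint anatomy is described ("between sections A~p~ and A~d~").
The five canonical arrangements are one fixed fragment order satisfying the
documented adjacency constraints; neutral `W` fillers space the named
fragments and nothing downstream depends on their order.

```{r}
arrs <- canonical_arrangements()
arrs[["E_1+2+9"]]
region_names(arrs[["E_1+2+9"]])
```

One deliberate design choice: the standard and doubly inverted arrangements
share an identical fragment tail distal to the `K|L` junction (the inverted
B block and `F` sit *inside* the central segment that the third inversion
excises).  The distal flank of that inversion is untouched by the two
earlier inversions, which is what lets all three heterokaryotype mechanisms
produce byte-identical derived fragment orders while differing in break
count, pathway, provenance and side products.  A related wrinkle in the
source material is that `B_p` sits in the standard arrangement's B part "at
a different position" in some descriptions; the canonical map here follows
the mechanism figures and places `B_p` immediately distal to `A_d`.

## Origin mechanisms

Two single-chromatid mechanisms (isochromatid, chromatid) duplicate the
stretch between staggered breaks but draw *all* material from the carrying
chromosome.  The three heterokaryotype mechanisms draw the proximal
A-window copy from the standard homolog:

| model | breaks | pathways | proximal A~d~/B~p~ | A~p~ | side products |
|---|---|---|---|---|---|
| NHEJ-4 | 4 (both homologs) | NHEJ | captured from standard | standard | reciprocal joint, non-surviving |
| NHEJ-3 | 3 | NHEJ | captured from standard | standard | standard chromosome lacking A~d~, B~p~ |
| BIR-NHEJ | 2 (one chromatid) | BIR + NHEJ | BIR copies of standard | doubly inverted | standard homolog intact |

```{r}
het <- karyotype(arrs[["E_st"]], arrs[["E_1+2"]])
apply_bir_nhej(het)
```

Because the sequenced window lies in A~d~, all three heterokaryotype models
predict the same genealogical signature — AK and AH2 sequences sister to
AB, GAL sister to AG — even though BIR-NHEJ leaves A~p~ with the doubly
inverted lineage.  Single-chromosome models predict everything with AG.
`predict_clade_constraints()` encodes exactly this.  Side products are
retained and flagged rather than discarded so that fragment conservation is
testable; the grey-box "unsuccessful" products are emitted as raw fragment
lists with no viability semantics.

## The synthetic-data generator

`simulate_alignment()` draws, for each region class (AB 18, AG 6, GAL 10,
AK 11, AH2 5 samples — the study's sample sizes), a standard neutral
Kingman coalescent tree grafted at the arrangement's origin, attaches the
founder lineages according to the chosen model's history
(`build_history()`), evolves a uniform-random root sequence down the tree
with Poisson mutation counts per branch and Jukes–Cantor substitution, and
labels the resulting ~2-kb alignment (plus one outgroup sequence).

Design choices worth knowing:

* **Clean splits, no incomplete lineage sorting.**  Each pool's MRCA is
  constrained below its origin time (the coalescent draw is rescaled into
  0.9× the available stem in the rare event it exceeds it), and founders
  attach exactly at the event times.  This keeps every region monophyletic
  in the true genealogy — matching the observed pattern, where each
  breakpoint region forms its own clade — at the cost of not modelling
  deep coalescence across the bottlenecks.
* **Time and rate units are arbitrary**; only products time × rate are
  observable.  Defaults (`mu = 0.015` per site per unit; origin times
  outgroup 3, doubly inverted 2, third inversion 1.2, fourth 0.6; pool
  coalescent scale `Ne = 0.25`, one knob, equal across arrangements) were
  chosen once so that per-region diversity lands in the observed
  0.006–0.015 band (expected 2 `Ne` `mu` ≈ 0.0075) and outgroup divergence
  near 0.09 (expected 2 × 3 × 0.015).  They are calibrated to the
  magnitudes of the real data, not fitted to them.
* **Gene conversion** (default off) is a post-hoc simplification: each
  sample receives a Poisson number of tract copies (100–500 nt, uniform
  start) from a random sequence of another region, rather than events
  placed on lineages.  It emulates the homogenising effect qualitatively.
* The simulator produces gap-free alignments; the deletion filters are
  exercised on constructed fixtures and on real-mode inputs, which may
  carry gaps and ambiguity codes.

What passing simulation-based tests shows — and does not.  The generator
reproduces the bottleneck structure, sample sizes and divergence scales of
the study design, so a ≥90% verdict-recovery rate demonstrates that the
inference stack reliably separates the two model classes *under those
conditions*.  It does not model alignment error, SGM-element insertions,
long T runs, or recombination away from breakpoints, so it cannot certify
behaviour on arbitrarily messy real alignments.

## Statistics

All statistics are computed from first principles and cross-checked in the
test suite against naive brute-force reimplementations (and, for distances
and trees, against an independent library implementation):

* **Complete deletion** keeps columns with no gap/ambiguity in any retained
  sequence; per-region summaries apply it per region, so each region uses
  its own site count.  Divergence *K* additionally requires the outgroup to
  be unambiguous, which is why its site set is smaller.  A pairwise-deletion
  variant sits behind `deletion = "pairwise"`.
* **Singletons** are counted as sites whose minor variant occurs in exactly
  one sequence; **multiple-hit sites** have more than two observed states.
* ***F*~ST~** is the Hudson-style `1 - pi_w / pi_b` with `pi_w` the
  unweighted mean of the two within-group diversities.  The permutation
  *P* is the fraction of label permutations with *F*~ST~ at least the
  observed value, with no +1 correction (so a never-reached value reports
  0.0000).  With tiny groups the observed partition recurs among random
  relabelings (probability 1/3 for 2+2), a property the tests verify
  exhaustively.
* **Neighbor joining** is the Saitou–Nei agglomeration with the standard
  Q-criterion; exact Q ties are broken by the lexicographically smallest
  pair of cluster labels and negative branch lengths are clamped to zero
  with a warning, so output is deterministic.  **Bootstrap** resamples
  masked columns with replacement under one fixed mask (whether the
  original analysis re-masked per replicate is unknowable; fixing the mask
  keeps replicates comparable), capping saturated resampled pairs at
  `p = 0.7499` instead of failing.
* The **verdict** roots on the outgroup, drops GAL leaves (their predicted
  affinity is AG under every model, so they carry no discriminating
  signal), requires the AK ∪ AH2 leaves to be monophyletic, and reads the
  sister clade: AB without AG ⇒ `discordant` (the heterokaryotype
  signature), AG without AB ⇒ `concordant`, anything else `unresolved`.

## The pipeline

```{r, eval = FALSE}
cfg <- pipeline_config(sim = sim_params(model = "nhej3"), seed = 1)
res <- run_pipeline(cfg)
summary(res)
```

At the default problem size (51 sequences × 2000 sites, 10000 permutations
per *F*~ST~ pair, 1000 bootstrap replicates) a full synthetic run takes
about 80 s on one CPU; the replicate studies in the tests and the
acceptance script use the same sequence scale with 100 seeded replicates
per model class.  Before pooling arrangements that share the focal
breakpoints, the pipeline tests their differentiation within the AK and
GAL regions (mirroring the original pooling decision); with the default
generator those *F*~ST~ values hover near zero with large *P*.

Real alignments enter through `read_fasta()` (labels in headers or a
sidecar TSV) and `pipeline_config(mode = "real", ...)`; sequences are
upper-cased, `U` normalised to `T`, and ragged or corrupt input fails
loudly.  A run manifest (seeds, parameters, versions) is written alongside
the outputs so a run can be reproduced bit-identically.

## Known limitations

* Breaks only at fragment boundaries; no nucleotide-level breakpoint
  coordinates or cytological band mapping.
* No likelihood or model choice across mechanisms — the data at hand
  cannot discriminate among the three heterokaryotype models, only between
  the heterokaryotype and single-chromosome classes.
* No demographic history (growth, migration), no recombination away from
  breakpoints, no substitution-model selection beyond Jukes–Cantor.
* The 29-individual karyotype table shipped for the dosage computation is a
  synthetic stand-in consistent with every published constraint (29
  heterokaryotypic individuals, arrangement copy numbers 1/1/2/2/2, 80
  expected A fragments); the per-individual assignments are not the
  original ones.
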