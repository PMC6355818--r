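---
title: "Inferring how a gene family expanded: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring how a gene family expanded: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant genomes frequently carry large, young gene families — clusters of
near-identical paralogs whose copy number differs sharply between close
relatives. A classic example is a secondary-metabolite enzyme family that
expanded in one species (giving it a trait such as a floral scent) while
staying small in its sister species. Reconstructing *how* such a family
expanded means attributing each member to a duplication mechanism:

* **tandem duplication** — unequal crossing-over leaves adjacent copies on
  one chromosome (a tandem array);
* **segmental duplication** — a genomic block is copied to a distant,
  typically inter-chromosomal locus;
* **retroduplication** — a spliced mRNA is reverse-transcribed and
  reinserted, leaving an intronless copy, often with a poly(A)-derived tail
  and short flanking direct repeats (target-site duplications, TSDs).

`famdup` implements this attribution as a reproducible pipeline and pairs
it with a forward simulator that plants each mechanism with known ground
truth, so that every inference stage can be measured rather than argued.

## The inference chain

1. **Harvest.** Candidate members are collected by aligning every annotated
   protein against a query with an affine-gap Smith–Waterman aligner
   (BLOSUM62, gap open −11 / extend −1) and keeping hits with
   Karlin–Altschul expectation `E = K·m·n·exp(−λS)` below 1e-10. The
   constants default to published gapped values (BLOSUM62 11/1: λ = 0.267,
   K = 0.041; DNA +1/−2 with gaps 5/2: λ = 0.625, K = 0.41) and are
   configurable; they approximate, not reproduce, BLAST's statistics.
2. **Tree.** Pairwise protein p-distances (complete deletion of gapped
   columns) are Poisson-corrected, `d = −ln(1 − p)`, and a neighbor-joining
   tree is built by the Saitou–Nei Q-criterion with lexicographic
   tie-breaking, then midpoint-rooted. Negative NJ branch lengths are
   clamped to zero (raw values retained in an attribute).
3. **Retro inference.** Intron presence is collapsed to a binary character
   (1 = has ≥ 1 intron) and reconstructed under Dollo parsimony: introns
   are ancestral, losses irreversible. The root is fixed to state 1; when
   every leaf is intronless the single loss is reported on the root's stem.
   Each loss edge is one candidate retroduplication event and every leaf
   below it carries the retro signature. Poly(A) scans (first 300 bp of the
   3' flank; a 15 bp window at ≥ 80% A, or a run of ≥ 8 As) and TSD scans
   (terminal/initial 100 bp windows; maximal shared substrings ≥ 8 bp with
   ≤ 1 mismatch) provide corroborating, per-gene evidence and cleanly
   report absence — eroded insertions are expected to lose these marks
   long before they regain introns.
4. **Tandem arrays.** Family genes on one chromosome are chained while
   consecutive members are within 250 kb and separated by ≤ 5 non-family
   genes. A cluster is labelled *tandem-origin* when at least half its
   members have a cluster-mate in their sibling subtree. Sisterhood is
   evaluated on the tree pruned of retro-flagged non-members: a retrocopy
   sired by an array member is its donor's closest relative and would
   otherwise displace the true sister, stripping a genuine array of its
   label while telling us nothing about its physical origin.
5. **Segmental pairs.** All-vs-all local DNA alignment of family CDSs;
   pairs with identity > 80% (gap columns in the denominator, BLAST-style)
   and E < 1e-10 are kept, excluding pairs inside one tandem-origin
   cluster. Reciprocal-best pairs (each the other's highest-identity
   partner) mark the strongest event candidates.
6. **Calls.** Per-gene evidence flags are combined with the precedence
   retro > tandem > segmental > unclassified: the retro signature reflects
   an older event that later tandem expansion builds upon.

## The simulator defines the study conditions

`sim_config()` starts one ancestor gene (3 exons of 300/150/300 bp, two
200 bp introns, so intron presence is a clean binary signal) on an
8 × 1.5 Mb genome and applies 12 duplication events, four per mechanism in
shuffled order, mutating every gene at 1% per site per step (≈ 0.12
substitutions/site on the oldest lineages — young-family territory where
identity thresholds begin to bite, which is exactly the regime worth
testing). Six unrelated intronless genes act as harvest decoys, and
promoters seeded with dictionary elements ride along for the scanner.

Deliberate design choices, made once:

* **Retro donors must carry introns.** A retrocopy of an intronless gene
  leaves no reconstructable signal under an intron-presence character, so
  planting such events would make ground truth unknowable by construction.
* **Dispersed insertions land at well-separated fixed sites** (≥ ~400 kb
  apart). In a real multi-hundred-Mb genome a random insertion essentially
  never lands inside an unrelated array; a toy genome needs the separation
  made explicit to preserve that property.
* **Tandem copies keep the donor's promoter and flank marks; retro copies
  get fresh promoter background**, mirroring the loss of regulatory
  sequence during retroduplication.
* **No indels, no partial duplications.** Copies are instantaneous and
  complete; divergence is substitution-only (uniform over the three
  alternative bases). Frameshifted pseudogenes and eroding gaps in real
  data are therefore *not* exercised; the aligner supports gaps but the
  simulated benchmark never stresses gap placement.

What passing the simulated benchmark does **not** show: robustness to
annotation error, alternative splicing, incomplete assemblies, transposon-
mediated duplication, or selection-driven rate variation. It shows that on
cleanly annotated input whose history actually consists of the three
modelled mechanisms, the chain of decisions recovers that history.

## Scoring against ground truth

`compare_to_truth()` scores *events*, not gene labels, because the
precedence rule makes per-gene labels ambiguous by design: a tandem copy
of a retrogene is intronless and sits inside a Dollo loss clade, so it is
flagged retro although the event that created it was tandem. The event
view keeps both statements true. Concretely:

* a **tandem** event is recovered when donor and copy share a
  tandem-origin cluster; a predicted cluster is correct when its member
  set equals one connected component of the truth's tandem edges;
* a **segmental** event is recovered when its pair passes the identity/E
  screen; predicted segmental events are reciprocal-best pairs among
  non-retro-flagged genes, and such a pair is correct when the unique
  genealogy path between the genes crosses a segmental event and no retro
  event (two genes on segmentally duplicated blocks are segmental
  relatives even if one of them is also a tandem copy);
* a **retro** event is recovered when some loss edge subtends exactly the
  planted retrocopy and its later copy-descendants.

Under the default conditions (replicate sweeps over 20 seeds) the pooled
per-mode recall and precision stay at or above 0.9; single replicates can
miss an event when two copies separated by a single simulation step leave
an internal tree edge too short for NJ to resolve, or when an early
segmental pair decays to the 80% identity boundary. Those failure modes
are inherent to the statistics, not to the implementation, and the test
suite asserts the pooled rates rather than pretending individual runs are
deterministic successes.

## Numerical and interface choices

* Coordinates are GFF3 1-based inclusive everywhere; BED export would be
  0-based half-open (documented at the writer).
* Flanks are gene-strand oriented: the 3' flank begins immediately after
  the stop codon in transcription direction, so poly(A) tails always read
  as `A`s.
* Genes lacking `exon` features fall back to `CDS` features, then to the
  gene span, tolerating database dialects; `N` bases translate to `X`
  rather than erroring, tolerating draft assemblies.
* Alignment traceback ties break diagonal > up > left; NJ Q-ties break
  lexicographically on the smallest contained leaf label; both make every
  downstream artifact byte-reproducible for a fixed seed, which the test
  suite verifies with checksums.
* The exhaustive alignment enumerator, the brute-force Dollo search, the
  naive promoter matcher and the least-squares topology search live beside
  the tests as independent oracles; they share no code with the
  implementations they check.

## Problem sizes

The shipped benchmarks use a 13-gene family on a 12 Mb toy genome, 200
simulated retro insertions for the scanner recalls, 50 additive trees of
5–12 leaves (with exhaustive least-squares checks at ≤ 6 leaves), 100
random trees for the Dollo oracle, and 1000 random 2 kb promoters for the
scanner oracle — sizes chosen so the whole suite, including 21 full
pipeline replicates, completes in minutes on one core while still hitting
every decision boundary (the 80% identity threshold, the 0.5 sisterhood
threshold, the poly(A) fraction threshold) with realistic divergence.

## Known limitations

* Whole-genome synteny (collinearity chains) is out of scope; segmental
  detection rests on pairwise CDS similarity, as is appropriate for a
  single family but weaker than block-level evidence.
* No Ks-based dating; event order is inferred only qualitatively from tree
  topology.
* Dollo reconstruction assumes intron gain never recreates lost introns —
  reasonable at these timescales but violated by genuine intron gain.
* E-values are Karlin–Altschul approximations with fixed constants, fit
  for thresholding, not for reporting as calibrated probabilities.
* One transcript per gene is assumed; alternative splicing would blur the
  intron-presence character.
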