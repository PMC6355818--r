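# famdup — duplication-mode inference for expanded gene families

`famdup` reconstructs *how* a gene family expanded within a genome. Given a
genome (FASTA), gene models (GFF3) and a query protein, it:

1. harvests family members by affine-gap similarity search
   (Karlin–Altschul `E = K·m·n·e^{−λS}` screen, default `E < 10⁻¹⁰`);
2. builds a neighbor-joining tree from Poisson-corrected protein distances
   (`d = −ln(1 − p)`) and midpoint-roots it;
3. reconstructs intron presence on the tree under Dollo parsimony (introns
   ancestral, losses irreversible) — each loss edge is a candidate
   **retroduplication**, corroborated by poly(A)-tail and
   target-site-duplication scans of the 1 kb flanks;
4. chains **tandem arrays** from gene order (≤ 250 kb gaps, ≤ 5 intervening
   genes) and labels them tandem-origin when tree sisterhood ≥ 0.5;
5. calls **segmental** duplicate pairs from all-vs-all CDS alignment
   (identity > 80%, `E < 10⁻¹⁰`, reciprocal-best flagging);
6. combines the evidence into per-gene calls with precedence
   retro > tandem > segmental > unclassified.

Because real genomes come without ground truth, the package ships a forward
simulator (`simulate_family()`) that plants tandem, segmental and
retroduplication events with per-site divergence, intronless retrocopies
bearing poly(A) tails and TSDs, and promoters seeded with a built-in
dictionary of light/temperature-responsive cis-elements — so the whole
chain is benchmarked against known truth.

It is aimed at comparative genomicists studying young, locally expanded
families (secondary-metabolite enzymes, resistance genes, receptor
clusters) who need mechanism attribution that is reproducible and
measurable rather than curated by eye.

## Worked example

```r
library(famdup)

cfg <- pipeline_config(simulate = sim_config(seed = 42))
report <- run_pipeline(cfg)

length(report$family)
#> [1] 13

for (cl in report$clusters)
  cat(cl$chrom, paste(cl$members, collapse = ","),
      cl$sisterhood_fraction, cl$tandem_origin, "\n")
#> chr3 fam001,fam004,fam013,fam002 1 TRUE
#> chr3 fam003,fam010 1 TRUE

table(report$calls$primary_mode)
#>
#>     retro segmental    tandem
#>         7         2         4

metrics <- compare_to_truth(report, report$truth)
metrics$per_mode
#>        mode n_truth n_pred recall precision
#> 1    tandem       4      2      1         1
#> 2 segmental       4      1      1         1
#> 3     retro       4      4      1         1
```

Reading the output: the harvest recovered all 13 planted family genes (and
none of the decoys); two chromosome-3 arrays are labelled tandem-origin;
seven genes carry the retro signature (four planted retrocopies plus three
later copies *of* retrocopies, which inherit intronlessness — the
event-level metrics below the table are the meaningful score, and all
twelve planted events are recovered with nothing spurious). `report`
also carries the Newick tree, the BLAST-style hit table, the segmental
pair list, the per-gene retro report (poly(A) offsets, best TSD) and
per-promoter cis-element counts; with `out_dir` set, all of it is
persisted as TSV/Newick/JSON, byte-identically across reruns of the same
seed.

A thin command-line wrapper is installed at `inst/cli/famdup.R`
(`famdup.R simulate|run --seed N --out DIR`).

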