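# tierbin

Two-tier unsupervised binning of assembled contigs from a **single**
metagenomic sample, for microbial ecologists and bioinformaticians who
need high-purity genome bins without reference databases or marker
genes — including from samples that contain multiple closely related
strains.

## Method

Per contig the package computes GC content, mean read coverage and the
canonical tetranucleotide frequency profile (136 strand-invariant
4-mer frequencies). Binning then proceeds in two tiers:

1. **Primary binning** — contigs are clustered in the standardized
   GC–log(coverage) plane with DBSCAN. Density clustering infers the
   number of groups from the data, assumes no cluster shape, and marks
   low-density contigs as noise. The radius ε is chosen automatically
   from the knee of the k-distance curve unless supplied.
2. **Refinement** — each primary bin is re-clustered in
   tetranucleotide space: length-variance-stabilized profiles are
   reduced by PCA and fitted with a Dirichlet-process Gaussian mixture
   (collapsed Gibbs sampling), which infers the number of components.
   Refinement only splits bins; sub-bins smaller than `min_bin_size`
   contigs are dissolved to the unclassified pool.

The rationale: strains share composition but usually differ in
abundance, so coverage is used as the *primary* signal and composition
as the refinement signal. Binnings are scored with the standard
measures — with R<sub>ij</sub> the number of contigs of genome *j* in
bin *i* and *U* the unclassified count:

- precision (%) = 100 · Σ<sub>i</sub> max<sub>j</sub> R<sub>ij</sub> / Σ<sub>ij</sub> R<sub>ij</sub>
- recall (%) = 100 · Σ<sub>j</sub> max<sub>i</sub> R<sub>ij</sub> / (Σ<sub>ij</sub> R<sub>ij</sub> + U)
- F1 = 2·P·R / (P + R)
- genome *S* is **discovered** by bin *C* when >50% of the contigs in
  *C* are from *S* and >50% of *S*'s contigs are in *C*.

A synthetic-community generator (Markov-chain genomes with controlled
GC and strain structure, fragmented into contigs with configurable
coverage distributions) makes the whole workflow testable end to end
without downloads. See `vignettes/tierbin-methods.Rmd` for the models,
priors and design decisions.

## Worked example

Simulate a 3-species community (coverages 5/50/300), run the pipeline,
and score it:

```r
library(tierbin)

spec <- community_spec(n_genomes = 3, n_coverage_distributions = 3,
                       coverage_centers = c(5, 50, 300),
                       genome_length = 200000L, seed = 42)
com <- simulate_community(spec)
dir <- tempfile(); write_community(com, dir)

res <- run_pipeline(file.path(dir, "contigs.fasta"),
                    file.path(dir, "coverage.tsv"),
                    "out", run_config(seed = 7))
str(res$counts)
#> List of 7
#>  $ input        : int 63
#>  $ short        : int 0
#>  $ zero_coverage: int 0
#>  $ noise        : int 5
#>  $ small_bin    : int 0
#>  $ binned       : int 58
#>  $ n_bins       : int 3

truth <- setNames(com$truth$genome, com$truth$id)
ev <- evaluate_binning(as_assignment(res), truth)
sprintf("precision %.1f recall %.1f f1 %.1f species %d",
        ev$precision, ev$recall, ev$f1, ev$n_species)
#> "precision 100.0 recall 92.1 f1 95.9 species 3"
```

All 63 contigs are accounted for: 5 were flagged as density outliers
(noise) in the primary tier and written to `unclassified.fasta`, the
other 58 landed in three bins (`bin_000.fasta` …) that each hold one
genome — 100% precision, with the unclassified contigs costing ~8
points of recall. `out/summary.json` itemizes every exclusion and the
parameters used; `out/assignments.tsv` maps each contig to its bin.

A thin command-line front-end wraps the same functions:

```sh
exec/tierbin simulate --n-genomes 30 --n-coverage-distributions 5 --seed 7 --out sim/
exec/tierbin bin --contigs sim/contigs.fasta --coverage sim/coverage.tsv --out out/ --seed 1
exec/tierbin evaluate --assignments out/assignments.tsv --truth sim/truth.tsv
```

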