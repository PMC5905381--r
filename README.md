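# nanobar

Field DNA barcoding from noisy long-read amplicons: demultiplexing,
filtering, de novo and reference-guided consensus, homopolymer-aware
polishing, primer trimming, and accuracy evaluation — with a deterministic
read simulator so the whole pipeline is testable end to end without any
sequencing data.

## The problem

Portable nanopore-class sequencers can produce DNA barcodes (500–900 bp
mitochondrial markers such as 16S, CytB, ND4) in the field, but individual
reads carry ~10–15% error dominated by indels, with systematic
undercounting of homopolymer runs. Species identification therefore rests
on building an accurate *consensus* from tens of reads per sample. That
involves: assigning pooled reads back to their sample barcodes, discarding
failed-ligation reads that are pure adapter, filtering on the
error-probability-scale mean quality (Q > 13) and length (> 200 bp),
clustering reads by overlap (span ≥ 50 bp, identity ≥ 0.7), calling a
column-majority consensus, and polishing it by iterative remapping with
explicit run-length voting for homopolymers and short tandem repeats —
the error classes plain majority voting systematically gets wrong.

The accuracy statistic is the alignment-based percent identity against a
Sanger-grade truth sequence: an optimal affine-gap alignment, global over
the truth with free query ends, with identity = matches / alignment
columns (each gap base one column), so a single 1 bp deletion against a
500 bp truth reads 99.8%.

## Worked example

Simulate a 120-read run of one 500 bp locus with 10% adapter-only junk,
then run the full pipeline against the known truth:

```r
library(nanobar)
library(tibble)

truth <- random_locus(500, seed = 7)
run <- simulate_run(
  tibble(locus = "16S", seq = truth, barcode_id = "BC01", n_reads = 120L),
  adapter_only_fraction = 0.1, seed = 42)
run
#> <simulated run> 133 reads, 1 loci, seed 42
#>   category         n
#> 1 adapter_only    13
#> 2 locus          120

report <- run_pipeline(list(
  reads = run, barcodes = run$barcodes, primers = run$primers,
  truth = tibble(id = "16S", seq = truth)))
report[1, c("barcode", "reads_in", "kept", "contig_support",
            "consensus_length", "identity_denovo")]
#>   barcode reads_in kept contig_support consensus_length identity_denovo
#> 1    BC01      119   35             35              500             100
```

119 of 133 reads demultiplex to BC01 (the rest are adapter-only
concatemers landing on other barcodes, or unassigned); the strict Q > 13
filter keeps 35, which cluster into one contig, and the polished,
primer-trimmed consensus matches the truth exactly:

```r
contig <- attr(report, "contigs")[["BC01"]]
acc <- classify_errors(global_identity(contig, truth), truth)
acc
#> <accuracy> 100.0% identity (500/500 columns): 0 sub, 0 ins, 0 del
#>            (0 homopolymer indel columns)
```

Coverage–accuracy curves follow the same pattern as real runs — accuracy
is already ≥ 99.4% at 30 reads and saturates by 100:

```r
tab <- subsample_experiment(run$reads, truth, sizes = c(30, 100),
                            replicates = 3, seed = 1,
                            primers = run$primers)
autoplot(tab)
```

Per-stage functions (`demultiplex()`, `filter_reads()`,
`cluster_reads()`, `build_consensus()`, `polish_consensus()`,
`trim_consensus()`, `refguided_pipeline()`, `rescue_unassigned()`,
`compare_strategies()`) expose every intermediate step; a thin CLI lives
at `inst/cli/nanobar.R`. The methods vignette
(`vignettes/consensus-methods.Rmd`) documents the algorithms, parameters
and their defaults, and the simulator's scope.

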