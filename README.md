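# tsrnakit

Identification, quantification and interactome analysis of
**5'-tRNA-derived small RNAs (5'-tsRNAs)** from small RNA sequencing data,
for people studying small-RNA dynamics in stem-cell differentiation and
similar systems.

A 5'-tsRNA is a 30-35 nt fragment of a mature tRNA that starts within the
first four nucleotides and ends just before the anticodon loop. Only a
handful of tRNA species produce them, their abundance tracks cell state,
and individual tsRNAs bind specific mRNAs and proteins. `tsrnakit` turns
that definition into a reproducible pipeline, together with the downstream
statistics used to characterize what a tsRNA binds:

* **Reference clustering** — tRNA loci sharing an identical first 50 nt
  are collapsed into clusters, so a 5' fragment that cannot distinguish
  near-identical loci has one well-defined home (multi-mapping remedy).
* **Read cleanup** — 3' adapter trimming (`TGGAATTCTCGGGTGCCAAGG`, minimum
  overlap 5, minimum length 6), rRNA removal, 18-35 nt selection.
* **Alignment & calling** — exhaustive ungapped alignment with at most 2
  mismatches, all best-stratum placements reported with fractional weights
  1/n; tsRNA = 30-35 nt read with a tRNA alignment; 5'-tsRNA = start at
  cluster position ≤ 4. Per-base coverage of cluster position *b* is
  `cov(b) = (weighted reads spanning b) / (total weighted tRNA-mapped reads)`
  with a sample-wide denominator, and the tRNA fraction of genome-mapped
  reads is reported per read length.
* **Differential abundance** — median-of-ratios size factors and an exact
  conditional negative-binomial test (method-of-moments dispersions shrunk
  to a gamma-family mean-dispersion trend), BH-adjusted.
* **Pulldown enrichment** — normalized-count > 200 expression filter,
  ts/scramble fold-change > 2, two-sided Fisher exact test per condition,
  Bonferroni-adjusted p < 0.05; significant transcripts allocated to
  RA-enriched / LIF-enriched / ubiquitous by a twofold RA/LIF ratio and
  classified against a reference RA-response table.
* **Interactome** — emPAI cleaning (non-detects → lowest detected value,
  bead subtraction, bead-dominant discard), twofold enrichment flags,
  gene-set Fisher/FDR over-representation, and one-site equilibrium
  binding fits `y = Bmax·C/(Kd + C)` by multi-start Levenberg-Marquardt.
* **Synthetic data** — generators for every input above with ground-truth
  manifests, so each stage is validated by planted recovery.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects have
`tidy()` / `glance()` / `augment()` methods and `autoplot()` /
`plot_*()` graphics.

## Worked example

Simulate a differentiating-cell-like library in which 80% of the
30-35 nt genome-mapped reads are 5'-tsRNAs, then run the calling pipeline:

```r
library(tsrnakit)
library(dplyr)

ref      <- simulate_trna_reference(n_genes = 60, n_anticodons = 12, seed = 1)
clusters <- cluster_trnas(ref$genes)          # 60 genes -> 30 clusters
decoys   <- simulate_contigs(3, 1200, "decoy", seed = 2)
rrna     <- simulate_contigs(2, 1500, "rRNA",  seed = 3)

lib <- simulate_small_rna_library(
  library_config(n_reads = 20000, tsrna_fraction = 0.8,
                 mirna_fraction = 0, rrna_fraction = 0,
                 error_rate = 0, seed = 7),
  clusters, decoys, rrna)

clean <- preprocess_reads(lib$reads, rrna)
aln   <- align_reads(clean$reads, align_targets(clusters, decoys))
calls <- call_tsrnas(filter(aln, is_trna), clusters)

fr   <- trna_fraction_by_length(filter(aln, !is_trna), filter(aln, is_trna))
pool <- fr[fr$length >= 30, ]
sum(pool$n_trna) / sum(pool$n_genome)
#> [1] 0.801
```

The pipeline recovers 16,024 5'-tsRNA reads and a pooled 30-35 nt tRNA
fraction of 0.801 against the planted 0.8 — the statistic that, on real
libraries, distinguishes differentiating (high) from pluripotent (low)
states. A binding assay analysis looks like:

```r
series <- simulate_binding_series(kd_nM = 33, cv = 0.02, seed = 11)
fit <- fit_kd(series)
fit
#> One-site binding fit
#>   Kd   = 34.75 nM
#>   Bmax = 1.062
#>   RSS  = 0.001363
#>   converged: TRUE
autoplot(fit)
```

`run_pipeline(pipeline_config(seed = 42), "out/")` executes the whole
chain — simulate, preprocess, call, quantify, differential, pulldown,
interactome — writing every stage artifact as TSV (with a version +
config-hash header) plus the resolved configuration as YAML; reruns are
byte-identical.

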