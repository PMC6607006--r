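---
title: "Calling 5'-tsRNAs and analysing their interactomes with tsrnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling 5'-tsRNAs and analysing their interactomes with tsrnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrnakit)
library(dplyr)
```

## The biological problem

Mature tRNAs are processed into discrete small-RNA fragments. In
differentiating mouse embryonic stem cells a prominent class is the
**5'-tsRNA**: a 30-35 nt fragment that starts within the first four
nucleotides of a mature tRNA and ends one to three nucleotides before the
anticodon, i.e. just short of the anticodon loop. Only a small subset of
tRNA species is processed this way, the pool grows as cells leave the
pluripotent state, and individual tsRNAs engage specific mRNAs and
RNA-binding proteins. `tsrnakit` implements the complete quantitative
workflow around this biology:

1. **Reference preparation** -- cluster near-identical tRNA loci by their
   5' sequence so multi-mapping reads have a well-defined home.
2. **Read cleanup** -- 3' adapter trimming, rRNA removal, 18-35 nt
   selection.
3. **Alignment and calling** -- mismatch-bounded ungapped alignment,
   tsRNA classification, per-base coverage, and the tRNA-fraction-by-length
   statistic.
4. **Differential abundance** -- median-of-ratios normalization and an
   exact negative-binomial test on tsRNA counts.
5. **Pulldown enrichment** -- which transcripts associate with a
   biotinylated tsRNA bait versus a scrambled control, and in which cell
   state.
6. **Interactome analysis** -- emPAI-based protein enrichment, gene-set
   over-representation, and one-site equilibrium binding (Kd) fits.
7. **Synthetic data** -- a generator for every input above with a
   ground-truth manifest, so each stage can be validated by planted
   recovery rather than by eye.

## Reference clustering

tRNA isodecoders are encoded by many near-identical loci. A 30-35 nt
5' fragment cannot distinguish loci that agree over its span, so genes are
collapsed by **exact identity of their first 50 nt** (`cluster_trnas()`).
Identity, rather than a similarity threshold, is the only parameter-free
reading of "5' sequence similarity" and collapses precisely the loci a
5' fragment cannot separate. Genes shorter than the prefix use their full
sequence as the key.

Each cluster's representative is its **longest** member (ties broken by the
lexicographically smallest gene id). A pure prefix key has no 3' end; the
longest member keeps 3'-fragment classification meaningful. The
consequence, documented rather than hidden: `3prime` species labels are
relative to the representative and are approximate for clusters whose
members differ in 3' length. 5' calls -- the object of study -- are
unaffected.

The anticodon is located by searching for the annotated triplet with start
positions restricted to the canonical window \[30, 40\] (anticodon loops of
cytosolic tRNAs sit at positions ~34-36); if the triplet does not occur
there, the first occurrence anywhere is used so degenerate references do
not hard-fail.

## Read cleanup

`trim_adapter()` implements 3'-ligated small-RNA semantics: remove from the
leftmost exact occurrence of the full adapter
(`TGGAATTCTCGGGTGCCAAGG` by default), otherwise remove the longest adapter
*prefix* (>= 5 nt) that ends the read; discard reads shorter than 6 nt
afterwards. Matching is exact -- the libraries this models carry exact
adapters, and an error-tolerant match would only add a free parameter. One
honest caveat: a biological insert that genuinely ends in >= 5 nt of
adapter sequence is indistinguishable from a partial adapter, so trimming
is idempotent only up to such inserts (about 1 read in 10^3 at random
composition).

`filter_rrna()` drops any read with an ungapped placement within 2
mismatches on either strand of the rRNA reference -- the same mismatch
constant used for every alignment in the package. `select_length()` keeps
18-35 nt, the window in which small-RNA species are analysed; reads of
30-35 nt are tsRNA candidates, while 18-24 nt reads are never called
tsRNAs.

## Alignment, calling, and coverage

`align_reads()` is an exhaustive ungapped (Hamming) scanner written in
C++: every placement at each read's minimal mismatch count (best stratum)
within the 2-mismatch bound is reported, tRNA clusters on the forward
strand only, genomic decoys on both strands. No indels are considered,
matching the mismatch-only contract of classic `-v`-mode short-read
aligners. At the reference sizes this problem has (a few hundred tRNA
clusters plus decoy contigs, well under 100 kb) an exhaustive scan is
faster in practice than maintaining a seed index, and it makes the
brute-force-equivalence property of the aligner true by construction; the
test suite still cross-checks it against an independent implementation.

Residual multi-mapping -- a read matching several clusters equally well --
is resolved by fractional weights `1/n` over the reported placements, so
read totals are conserved exactly. Whether such reads should instead count
once per cluster is genuinely underdetermined; fractional assignment is the
choice that keeps every downstream sum interpretable as "number of reads".

A read is a **tsRNA** iff it is 30-35 nt and has at least one tRNA-cluster
alignment; it is a **5'-tsRNA** when its alignment starts at cluster
position <= 4. Reads with additional genomic placements still count: tRNA
loci are themselves genomic, and clustering -- not placement exclusivity --
is the multi-mapping remedy.

Per-base coverage of cluster position $b$ is

$$\mathrm{cov}(b) = \frac{\sum_{\text{reads spanning } b} w_r}
{\sum_{\text{tRNA-mapped reads}} w_r},$$

with the denominator shared across all clusters of a sample, so profiles
are comparable within a sample and total coverage times the denominator
equals the total weighted aligned read-bases -- an exact conservation law
the tests assert to machine precision.

The composition statistic `trna_fraction_by_length()` reports, for each
read length 18-35, the fraction of genome-mapped reads with a tRNA
alignment. Reads whose only placements are on tRNA clusters count as
genome-mapped (tRNA genes are part of the genome); lengths with no
genome-mapped reads report `NA`.

## Differential abundance

Raw per-cluster 5' tsRNA counts (weighted sums rounded half-up) are
normalized by **median-of-ratios** size factors: the median across
features, with positive geometric mean, of the ratio of a sample's count to
the feature's geometric mean, rescaled to unit geometric mean across
samples. `nb_test()` then runs a classic count-model test:

* **Dispersion** per feature by method of moments on normalized counts
  (`(pooled within-group variance - mean) / mean^2`), with variance
  parameterized as `mean + dispersion * mean^2`.
* **Trend** by a gamma-family identity-link regression of the (floored)
  raw dispersions on 1/mean, the standard two-parameter mean-dispersion
  model `a0 + a1 / mu`.
* **Shrinkage** of each raw value toward the trend with residual-df versus
  prior-df weighting; the prior df is 10, chosen so that 2v2 designs
  (residual df 2) lean heavily on the trend while larger designs keep
  feature-specific signal. The floor is 1e-8.
* **Test**: when both groups have <= 5 samples, an exact conditional NB
  test -- counts rescaled to the common (geometric-mean) library size and
  rounded, group sums conditioned on their total, and the two-sided p-value
  formed by summing all splits whose point probability is at most the
  observed one (1e-7 relative slack). Otherwise a Wald test on the log
  link with delta-method variances. Benjamini-Hochberg adjustment across
  features.

The exact test's Poisson limit is a conditional binomial, which the tests
use as a closed-form oracle, and a seeded 2v2 null simulation at dispersion
0.1 verifies the attained size stays within \[0.03, 0.07\] at nominal 0.05.

## Pulldown enrichment

Transcript counts from tsRNA-bait versus scrambled-control pulldowns in two
cell states (LIF = pluripotent, RA = differentiating) are analysed as:

1. normalize all four samples (median-of-ratios);
2. keep transcripts with normalized count strictly > 200 in at least one
   sample;
3. per condition, fold change ts/scr (0.5 pseudo-count on zeros) and a
   **two-sided Fisher exact test** on the 2x2 table
   (transcript, rest-of-library) x (ts, scr) built from rounded normalized
   counts -- the standard construction for count enrichment against a
   control library, isolated behind `fisher_exact_p()` so alternatives are
   pluggable;
4. Bonferroni correction with m = number of transcripts surviving the
   expression filter, per condition; significant = fold change > 2 *and*
   adjusted p < 0.05 in at least one condition;
5. state allocation by the RA/LIF pulldown ratio r: `RA_enriched` when
   r > 2, `LIF_enriched` when r < 1/2, `ubiquitous` when the fold-change
   gate passes in both conditions and r sits within the band;
6. optional classification against a reference RA-response table:
   reference fold change > 2 is differentiation-responsive, < 0.5 is
   pluripotency-associated.

A known statistical limitation, stated rather than patched: the Fisher
test treats counts as conditionally multinomial. Under biological
overdispersion it is anticonservative, which is why the planted-recovery
validation runs the generator in the Poisson regime the test assumes, and
why real-data use relies on the conservative Bonferroni + fold-change
double gate.

## emPAI interactome and binding fits

`clean_empai()` replaces the -1 non-detect sentinel with the lowest
detected value in the table, subtracts the bead-control emPAI from each
condition, and discards records whose bead signal exceeds **every**
condition (a strict per-condition variant is a one-line filter on the
returned columns). Fold-change flags use adjusted values floored at the
table's detection floor, which makes cleaning and flagging exactly
equivariant under rescaling the whole table -- the natural requirement for
a relative abundance index. `geneset_enrichment()` reuses the shared
Fisher implementation over GMT gene sets with BH correction.

`fit_kd()` fits the one-site model $y = B_\max C / (K_d + C)$ to binding
signal normalized to the highest-concentration point, by multi-start
Levenberg-Marquardt least squares (starts at the minimum, median and
maximum concentration; positivity bounds; best residual sum of squares
wins). $B_\max$ stays free because normalization at the top concentration
does not imply saturation there. Ordinary (unweighted) least squares is
used; with multiplicative noise at the few-percent level the weighting
choice is immaterial, and no error model is available to justify more. A
fit whose $K_d$ collapses onto the lower boundary (flat series) is
reported with `converged = FALSE`.

## What the synthetic data emulate -- and what they do not

The generator writes every input the pipeline reads, plus a manifest
labelling each record with its ground truth.

* **Reference**: 72-90 nt genes, anticodon planted at 34-36, several genes
  per cluster sharing an identical first 50 nt and differing only in the
  3' tail (roughly two loci per unique 5' sequence, the ratio seen in
  real tRNA references).
* **Libraries**: 5'-tsRNA reads start at nt 1-4 and end 1-3 nt before the
  anticodon (length clipped to 30-35); miRNA-like reads are 21-23 nt decoy
  substrings; rRNA reads 28-35 nt; the remaining fraction is a genomic
  background drawn, by default, at 30-35 nt -- it models the non-tRNA part
  of the 30-35 nt peak, so the configured `tsrna_fraction` is in
  expectation exactly the tRNA fraction among 30-35 nt genome-mapped
  reads, the quantity the composition statistic measures. Inserts get the
  3' adapter, truncation to a 50 nt machine read, uniform per-base
  substitution errors, and constant "I" qualities (the pipeline never uses
  quality values). Not modelled: ligation bias, PCR duplicates, 3' end
  chemistry, realistic quality profiles. Passing tests therefore show
  correctness of the computational contract, not robustness to every
  real-library artefact.
* **Pulldown counts**: negative binomial with
  `variance = mean + dispersion * mean^2` around a lognormal baseline
  (sdlog 0.5, mean preserved at `baseline_mean` = 200, giving ~1e6 reads
  per 5000-transcript library). The sdlog was set from a power analysis:
  the > 200 expression filter must not silently remove planted transcripts
  at this depth.
* **emPAI tables**: planted fourfold RA- or LIF-shifted proteins,
  bead-dominant rows, non-detects, and a pinned 0.01 minimum detected
  value; optional lognormal noise.
* **Binding series**: the one-site law at concentrations
  20/40/80/200/400 nM with mean-one lognormal noise, normalized to the
  400 nM point.

All generators are deterministic given their seed; the orchestrated
pipeline derives per-stage seeds from one top-level seed and reruns
byte-identically.

## Numerical choices and problem sizes

Tie-breaks and floors that matter: half-up rounding for weighted counts
(so two half-weight reads count once); 0.5 pseudo-counts only where a zero
would otherwise destroy a ratio, never inside a test statistic; dispersion
floor 1e-8; Fisher two-sidedness by point-probability summation with 1e-7
relative slack; Kd multi-start with `ftol`/`ptol` 1e-12.

The validation suite runs at desk scale: 300-gene clustering against an
O(n^2) oracle, 2000 reads against an independent exhaustive scan, a
20,000-read composition study, 2000-feature null and power simulations,
a 5000-transcript pulldown with 100 planted targets, 100 noisy binding
series. These sizes give each stochastic check at least ~3-sigma
resolution while keeping the whole suite in a few minutes.

## Worked example

```{r example, eval = FALSE}
ref <- simulate_trna_reference(n_genes = 60, n_anticodons = 12, seed = 1)
clusters <- cluster_trnas(ref$genes)
decoys <- simulate_contigs(3, 1200, "decoy", seed = 2)
rrna <- simulate_contigs(2, 1500, "rRNA", seed = 3)

lib <- simulate_small_rna_library(
  library_config(n_reads = 20000, tsrna_fraction = 0.8,
                 mirna_fraction = 0, rrna_fraction = 0,
                 error_rate = 0, seed = 7),
  clusters, decoys, rrna)

clean <- preprocess_reads(lib$reads, rrna)
aln <- align_reads(clean$reads, align_targets(clusters, decoys))
calls <- call_tsrnas(dplyr::filter(aln, is_trna), clusters)
cov <- per_base_coverage(dplyr::filter(calls, is_tsrna), clusters)
autoplot(cov, clusters = clusters)
```

The coverage plot shows the 5' plateau ending just before the dashed
anticodon line -- the signature that distinguishes genuine 5'-tsRNAs from
degradation.
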