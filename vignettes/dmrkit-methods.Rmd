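---
title: "dmrkit: models, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dmrkit: models, defaults, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dmrkit` analyses two-condition whole-genome bisulfite sequencing (WGBS)
count data of the kind produced in peripheral-nerve injury studies, where
an "uncut" control nerve is compared with a "cut" nerve whose Schwann
cells have converted to the repair phenotype. This vignette is the
package's own account of its statistical choices. It states no empirical
result that the test suite does not itself compute.

## 1. The per-CpG model

The atom of the methylome arm is a CpG dyad with methylated/unmethylated
read counts per sample. Bisulfite callers report the two strands of a
dyad separately (C at position p on +, C at p+1 on -);
`collapse_and_filter()` sums them into one record at p. Bismark-coverage
files carry no strand column, so for file input dyads are recovered by
greedy left-to-right pairing of adjacent positions in the cross-sample
union of sites; a record with no partner anywhere is kept at its own
position and flagged `one_sided`. In-memory tables from the simulator
carry strand and collapse exactly.

**Coverage filter.** Default `min_cov = 5` under the `every-sample`
scope: every sample must be present with at least 5 reads. This is the
stricter of the two defensible readings ("each CpG site was sequenced at
least five times"); the pooled scope is available. Missing counts are
*absent*, never imputed zeros — a site missing one sample fails the
every-sample filter outright.

**Test.** The default per-site test pools replicates per condition and
applies the two-sided Fisher exact test to the pooled 2x2 table. The
source study does not state its per-CpG test; Fisher on pooled counts was
chosen because it is assumption-light and *exactly verifiable* — the test
suite checks it against exhaustive hypergeometric enumeration for every
2x2 table with margins <= 12 at 1e-9 tolerance. A replicate-aware
binomial logistic likelihood-ratio test (`method = "logistic-lrt"`) is
provided for users worried about pooling; with the default simulator
dispersion the two agree closely on clear effects. Pooling ignores
replicate-level overdispersion, which makes the pooled test slightly
anti-conservative under strong replicate variation; the null-calibration
acceptance test bounds this (raw p < 0.05 fraction <= 0.06 at depth 30,
n = 3).

The effect size is `delta_pp`, the difference of pooled methylation
percentages (cut minus uncut), in percentage points on [-100, 100].

**Multiple testing and the DM call.** `adjust_bh()` is the standard BH
step-up (min-cummin formulation, ties handled by construction), verified
against an O(m^2) transcription of the definition.
`call_dm()` flags `q < 0.05 & |delta_pp| > 20` — both strict
inequalities, exactly as stated thresholds "p-adj < 0.05" and
"difference > 20%" read.

## 2. DMR chaining

"Clustering >= 2 DM CpGs within 500 bp of one another" is read as single
linkage on consecutive sorted DM sites with gap <= 500 bp, *inclusive* at
the boundary. This is the simplest reading that yields unique, disjoint
regions. On one dimension, single linkage at a cutoff equals
consecutive-gap chaining; the acceptance suite nevertheless checks
`cluster_dmrs()` against an O(n^2) connected-components oracle on random
inputs. Regions span only their member dyads (`end` = last member + 2);
they are not extended by flanks. Mixed-sign chains are kept and flagged
`mixed` rather than split — the source text states no direction
constraint, and a user can filter on the flag.

## 3. Feature context and enrichment

`assign_features()` gives each site exactly one primary label by the
precedence **promoter > exon > intron > enhancer > cpg_island >
intergenic**, chosen so gene-proximal labels dominate; enhancer overlap
is additionally reported as an orthogonal flag because enhancers are
frequently intronic (the motivating study's strongest example is an
intronic enhancer DMR). The promoter window is (-1500, +500) bp around
the TSS in the gene's orientation — a common convention; the source never
defines "promoter". Nearest-TSS ties break to the lexicographically
lower gene id, deterministically.

All enrichments share one backend: 2x2 cells kept in the output, sample
odds ratio `ad/bc` with the Haldane-Anscombe +0.5 correction when any
cell is zero (applied to the CI as well, so zero cells stay finite),
Woolf 95% CI, two-sided Fisher p, and BH across the tested units.

**Coverage-matched background.** The default background for feature and
motif enrichment is a stratified sample of tested non-DM sites: all
tested sites are binned into 10 coverage quantiles and the background is
drawn without replacement to match the DM set's stratum proportions at
10x its size. This mirrors the robustness check that DM enrichment is
"independent of technical variation in read coverage". The sampling seed
is explicit, so results are reproducible.

**TSS distance bins.** The figure in the source does not state its bin
edges; the default `[0,1k), [1k,10k), [10k,100k), [100k,500k), [500k,
Inf)` per orientation is a pipeline default and configurable.

## 4. Motif enrichment

Windows are 40 bp centered on the DM CpG (anchor C at offset 20),
N-padded and flagged at chromosome ends. PWM scanning uses log2-odds
scores against the PWM's background frequencies with a 0.01 pseudocount,
both strands, every offset; a window is a "hit" when its best score
reaches `score_fraction = 0.8` of the PWM's maximum attainable score. N
bases contribute 0 (the background expectation). The consensus sequence
attains the maximum score by construction, and hit calls are
reverse-complement symmetric — both are tested properties.

The de-novo search is canonical k-mer (k = 6-8) over-representation with
presence (not frequency) semantics per window, BH within each k. This is
a deliberate, documented stand-in for EM/Gibbs motif discovery tools:
deterministic, exactly testable, and sufficient to recover a planted
consensus. `inst/extdata/motifs_synthetic.meme` ships a synthetic AP-1
PWM (TGACTCA) and 11 decoy PWMs built from unrelated consensus motifs;
these are *synthetic* matrices for testing, not database motifs.

## 5. lncRNA classification

Rules in order: reject if spliced length <= 200 nt (">200" is strict);
reject if the coding-potential flag is set — coding-potential prediction
is consumed as an input flag because the upstream predictor is not part
of this pipeline; reject (`sense_overlap`) on same-strand overlap with a
coding gene; `antisense` on opposite-strand overlap; else `intergenic`.
Overlap is evaluated transcript-span against gene-span: this makes the
three outcomes exhaustive (an intron-only overlap is still an overlap)
and matches the field's working definition of "antisense" and
"intergenic". High confidence requires the 5' end within 50 bp of a
same-strand CAGE cluster — a concrete reading of "defined 5' ends";
distance and strandedness are configurable. The reject-reason code
`no_cage_support` is reserved but never emitted: absence of CAGE support
withholds the high-confidence flag rather than rejecting the call.

## 6. Gene sets, orthologs, correlation

The enrichment universe defaults to all ids in the DE table (all tested
genes); the source study never states its universe, which is why its
printed odds ratios are not reproducible targets. Many-to-many ortholog
rows expand to all targets (with the unmapped count reported) rather than
being dropped. Methylation-expression correlation uses Spearman's rho per
feature class — delta and log2FC live on different scales and only the
presence/absence of association is of interest; p-values are exact for
n <= 10 (the exact null distribution of the rank statistic, equivalent to
permutation enumeration) and asymptotic otherwise; classes with < 5 pairs
or constant delta are NA, not 0.

## 7. The synthetic-data generator

The generator emits the world the analysis assumes, with ground truth:

* **Genome**: i.i.d. bases at GC fraction 0.42 (mammalian-like), two
  500-kb chromosomes by default, giving ~43,000 CpG dyads — enough for
  stable calibration statistics while simulating in ~20 s. CpG sites are
  the emergent CG dinucleotides, not a planted lattice.
* **Coverage**: per site and sample, NB(mean 30, size 8) — a realistic
  WGBS depth with moderate depth variation. Reads are split binomially
  between the dyad's strands so the collapse step is genuinely exercised.
* **Methylation**: baseline per site from a two-component Beta mixture
  (hypo mode Beta(0.8, 6), weight 0.25; hyper mode Beta(6, 1.2)),
  mimicking the bimodal methylome of vertebrate genomes. Replicate-level
  probabilities are Beta-distributed around the site mean with
  concentration 150; the binomial model is the concentration -> infinity
  limit. 150 was chosen so the generator satisfies the stated
  null-calibration property of the pooled Fisher test (p < 0.05 fraction
  <= 0.06 at depth 30, n = 3) while still being visibly overdispersed.
* **Planted DMRs**: 30 regions of 5 consecutive CpGs within <= 400 bp,
  placed by sampling candidate runs with weight 3 for introns/enhancers
  vs 1 elsewhere (weights configurable). The weight applies to the whole
  run (mean member weight), not just an anchor CpG — anchor-only
  weighting measurably dilutes the planted feature preference. Member
  baselines are drawn uniformly from the sub-interval of [0.02, 0.98]
  where the full +40 pp shift fits, so the planted effect is never
  clamped and the delta estimator can be tested for unbiasedness. This
  replaces a clamp-at-the-boundary rule, which would silently shrink
  planted effects at hyper-methylated sites and make recovery criteria
  untestable.
* **Motifs**: the AP-1 heptamer is written into the genome within +/-20
  bp of 40% of planted DM CpGs and (necessarily — random sequence
  contains a given 7-mer in a 40-bp window with probability ~0.4%) near
  5% of background CpGs. Insertions never overwrite a protected CpG dyad
  or a previous insertion; the planted consensus contains no CG, so no
  member site is destroyed.
* **Expression**: DE flags are Bernoulli with odds multiplied by the
  planted odds ratio (default 3) for the designated EMT set; the baseline
  odds are solved so the expected DE count matches the configuration.
  This gives honest sampling variation across seeds, so confidence-
  interval coverage of the planted OR is a meaningful test.

**What the simulator does not emulate** — and hence what a green test
does not establish: read-level artefacts (bisulfite conversion failure,
mapping bias, PCR duplicates), non-CpG methylation, realistic genome
composition (repeats, isochores, true CpG-island structure), linkage
between methylation and expression, SNPs/CNVs, and biological replicate
structure beyond a single overdispersion parameter. Recovery results on
simulated data bound implementation correctness, not real-data power.

## 8. Determinism and numerics

Every simulator output is a pure function of the configuration seed (the
three simulators use seed, seed+1, seed+2 so they may be called in any
order); `run_pipeline()` with a fixed config and seed produces
byte-identical outputs, and the run log contains version, seed, and a
threshold echo but no timestamps. Fisher ties are compared with a 1e-7
relative guard (as in `stats::fisher.test`) which is exact for the
integer-representable probabilities at small margins. BED output is
0-based half-open, GTF 1-based closed, Bismark input 1-based; all
conversions happen at the file boundary and are round-trip tested.

## 9. Known limitations

* The pooled Fisher test does not model replicate random effects; for
  strongly overdispersed data prefer `logistic-lrt` or an external
  beta-binomial caller.
* DMR calling is threshold chaining, not an HMM/kernel method; it
  inherits the per-site calls' granularity and does not combine p-values
  across sites.
* The k-mer search cannot find degenerate motifs whose instances share no
  common word; it is a recovery tool for planted/strong consensus motifs.
* `enhancer_proximity()` measures coordinate distance to the nearest
  enhancer base; "syntenic conservation" of enhancers across genomes is
  out of scope (pre-mapped coordinates are an input).
* The lncRNA classifier trusts the provided coding-potential flags and
  transcript models; it performs no assembly or quantification.
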