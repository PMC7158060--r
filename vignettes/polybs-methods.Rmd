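---
title: "Calling m5C from bisulfite RNA-seq and tracking methylation across polysome fractions"
author: "polybs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m5C from bisulfite RNA-seq and tracking methylation across polysome fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polybs)
```

# The measurement model

Bisulfite chemistry converts unmethylated cytosine to uracil while m⁵C
(and hm⁵C, which bisulfite cannot distinguish) resists conversion. After
conversion-aware alignment, each read base over a reference cytosine is
either a retained C (non-conversion, the methylation signal) or a
converted T. At a site with true stoichiometry $p$ and per-cytosine
conversion-failure rate $\varepsilon$, a covering read retains C with
probability $p + (1-p)\varepsilon$; the non-conversion level
$\hat{p} = c/(c+t)$ is the stoichiometry estimator.

The analysis must reject three artefact classes that inflate $\hat p$:

1. **Structure-driven conversion failure.** Stable secondary structure
   shields whole stretches of cytosines, producing reads that co-retain
   many C's (typical of rRNA). Two defences: reads retaining more than 3
   cytosines are removed (**3C**), and positions where the surviving
   fraction of reads drops below 90 % are flagged and suppressed
   (**S/N90**). The read-level filter acts first; the position-level
   ratio (3C-surviving / raw coverage) then catches loci whose coverage
   was dominated by removed reads.
2. **Read-end cytosine bias.** Retained cytosines concentrate, for
   reasons not fully understood, within a few nucleotides of read ends.
   Base calls in the terminal 6 nt therefore carry no methylation
   evidence (the *overhang mask*), and calls below phred 30 are ignored.
3. **Mismatch-rich positions.** Sites where less than 80 % of the
   identified base calls are C or T (**80CT**) are discarded as probable
   alignment or reference artefacts.

Surviving positions become candidate sites when, in *every* biological
replicate, 3C-filtered coverage is at least 30 (**30RC**) and at least 5
retained cytosines are observed (**5C**), and when the mean of the
per-replicate non-conversion levels is at least 10 % (**10MM**). The
average is a mean of proportions, not a pooled-count ratio, so a
high-coverage replicate cannot mask a discordant low-coverage one.

## Boundary and denominator choices

Three numerical details of the cascade are genuinely open and are exposed
as configuration:

* **S/N boundary.** The flag fires when the ratio is strictly below 0.9
  (`sn_boundary = "lt"`); `"le"` also flags equality. With coverage in
  the tens, the measure is discrete and the boundary case is rare.
* **80CT denominator.** The rule is a *mismatch guard*: among identified
  base calls (post-mask, post-quality-floor) at least 80 % must be C or
  T, i.e. `(c+t)/(c+t+other) >= 0.8`. Measuring it against read depth
  instead would conflate masking (which removes ~12 % of calls at 100-nt
  reads) with mismatches and reject well-behaved sites by chance;
  coverage adequacy is 30RC's job, assessed on 3C-filtered depth
  (`coverage_basis` switches to raw depth).
* **Mask semantics.** By default a masked (terminal) call contributes to
  coverage but to neither $c$ nor $t$, which keeps $\hat p$ unbiased
  under the mask. The alternative `mask_as_converted = TRUE` counts a
  terminal retained C as converted; that variant is monotone (masking can
  only lower $\hat p$) but biases stoichiometry down at genuinely
  methylated sites, increasingly so for short reads, and is therefore not
  the default.

## tRNA handling

tRNA genes are represented as a mature region flanked by 100 nt of
precursor sequence on each side. Only *processed* reads — fully contained
in the mature interval — enter the cascade, so precursor molecules do not
dilute mature-tRNA methylation. Densely modified tRNAs expose a known
false-negative mode: a read covering four or more genuine sites fails 3C
itself, so recovery degrades as planted sites per tRNA approach and
exceed the 3C threshold. The tests assert the recovered set is a subset
of truth rather than complete.

# The synthetic-data generator

The generator is first-class, tested code: it emulates exactly the
statistical structure the cascade assumes, which is what makes every
downstream stage testable without external data.

What it emulates, with defaults chosen once as plausibly realistic for a
HeLa-style bsRNA-seq experiment:

* stranded conversion in transcript space (minus-strand genes show G→A on
  the plus strand), with conversion failure `0.002` per unmethylated
  cytosine (the >99.8 % conversion regime spike-ins are used to verify);
* a 4-fraction × 3-replicate design; planted mRNA sites with base
  stoichiometry uniform on 0.2–0.6 and, by default, equal thirds of
  negative/neutral/positive trajectories at ±0.08 stoichiometry per
  fraction step; replicate-level truth is Beta-jittered around the
  fraction value with concentration 200, which reproduces tight replicate
  concordance;
* structure-artefact clusters: five adjacent cytosines on rRNA-like genes
  co-retained by 25 % of covering reads, placed in the gene body so
  coverage is uniform over them;
* read-end bias: terminal cytosines spuriously retained at rate 0.01
  (a guess — the magnitude of the real artefact is uncharacterised — and
  a config knob);
* two-valued base quality (phred 37 with 2 % phred-20 calls), 100-nt
  ungapped reads (fragment-length reads inside tRNA mature regions; an
  optional single-N spliced-read mode), Poisson coverage at 50× mean,
  fully unmethylated spike-ins, and 1–4 clustered sites per tRNA.

What it does **not** emulate: sequencing errors beyond the quality model,
PCR duplicates, adapters, multi-mapping ambiguity, expression-level
variation between genes, incomplete annotation, or thermodynamically real
secondary structure. Passing tests therefore demonstrate the pipeline's
statistical behaviour under its own model assumptions — estimator
calibration, filter specificity and sensitivity, artefact suppression —
not robustness to alignment or library-preparation pathologies.

The generator records its own ground truth: per-site planted
stoichiometry per fraction (`truth` table), the replicate-realised
stoichiometry after Beta jitter, and exact per-site retained/covered
tallies, so tests can compare pipeline output against the data-generating
truth at the appropriate level. Estimator *calibration* is assessed
against the replicate-realised values: the jitter is planted biological
variation, part of the truth, not estimator error.

# Annotation and enrichment analyses

Sites are annotated to the longest transcript of the overlapping
same-strand gene (spliced length; ties broken lexicographically) and
classified into 5′UTR/CDS/3′UTR/intronic/ncRNA_exonic/ncRNA_intronic,
with intergenic as the fallback — exactly one label per site.

* **Metagene profiles** place each exonic mRNA site on a composite
  5′UTR–CDS–3′UTR axis whose segment widths are proportional to the
  median feature lengths of the represented transcripts (`scaling =
  "mean"` is available); background is every C in the same features.
  Both densities are normalised to sum to one.
* **Binned enrichment** anchors spliced positions at the start or stop
  codon (or transcript ends), bins them at 100 nt, and compares observed
  occupancy against a matched null drawn uniformly from the unmodified
  cytosines of the same transcripts, aggregated over 100 resamples to
  stabilise the null. Each bin gets Fisher's exact odds ratio, 95 % CI
  and BH-adjusted p (raw p is kept too, since multiplicity handling in
  comparable published analyses is often unstated); zero cells fall back
  to Haldane–Anscombe-corrected estimates and are flagged.
* **Sequence context** tabulates the transcript-strand 21-mer around each
  site into a position frequency matrix against an all-C background.
* **Codon bias** tests each (codon, codon position) against overall codon
  usage in the represented transcripts with Fisher's exact test.
* **Base-pairing profiles** fold 51-nt windows and report the fraction of
  windows in which each position is paired, versus random-C controls.

## The folding stand-in

Windows are folded by maximum base pairing (Nussinov dynamic programme:
AU/GC/GU pairs, minimum hairpin loop 3, non-crossing matching with
traceback). This is deliberately not a thermodynamic model: the pairing
profile's contract here is qualitative — structured versus unstructured
flanks — and the maximum-matching structure suffices for it, while being
exactly checkable against exhaustive enumeration for short sequences. For
publication-grade profiles, pass a thermodynamic folder via `fold_fun`
(any function returning a per-base paired indicator).

# Polysome-fraction trend analysis

Per-fraction site summaries (mean of replicate proportions, mean
coverage, replicate-averaged methylated/unmethylated counts) feed a
selection rule: sites observed in at least 9 of the 12 fraction samples
with mean coverage ≥ 10 in all four fractions (**F1234**), or in
fractions 2–4 only when fraction 1 lacks coverage (**F234**).

**Clustering.** Profiles are standardised per site (mean 0, SD 1 across
fractions) and soft-clustered with fuzzy c-means, fuzzifier `m = 2`,
`c = 9` clusters. Initialisation is k-means++ with 10 restarts keeping
the best objective; iterations stop when the relative objective change
falls below 1e-8; everything is seed-deterministic. Constant profiles
cannot be standardised and are excluded with a message. Memberships sum
to one by construction and the objective is non-increasing — both are
asserted in tests, and the partition is cross-checked against an
independent fuzzy c-means implementation.

**Trend labels.** Each cluster centroid's least-squares slope across
fraction index classifies it as negative/neutral/positive; sites inherit
the label of their argmax-membership cluster. The neutral band `epsilon`
defaults to 0.4 SD-units per fraction step: on the standardised scale a
perfectly linear monotone centroid has slope ≈ 0.775, so 0.4 is half the
attainable maximum; values as small as 0.1 sit below the slope noise
floor of noise-dominated centroids and label almost everything as a
trend.

**A known limitation worth stating plainly.** Per-site standardisation
destroys amplitude: a genuinely *flat* profile becomes unit-variance
noise, and a random 4-point profile correlates above 0.5 with some
monotone shape roughly half the time, independent of coverage or noise
level. Flat-trajectory sites therefore scatter into monotone clusters and
inherit trend labels, while monotone-trajectory sites are recovered
essentially perfectly. In the package's own end-to-end simulation with
equal thirds of negative/neutral/positive planted trajectories, label
accuracy is ~100 % on the monotone two-thirds and near 0 % on the neutral
third (overall ≈ 65 %). Any analysis that needs trustworthy *neutral*
calls should not take them from standardised-profile clustering; an
amplitude-aware check (e.g. the per-site differential-methylation tests
below, or a pre-standardisation variability floor) is the appropriate
instrument.

**Differential methylation.** For each adjacent fraction pair, sites with
mean coverage ≥ 10 in both fractions are tested by binomial logistic
regression on the replicate-averaged methylated/unmethylated counts,
rounded to integers (a proportion test needs counts; rounding is exposed
via `round_counts`). The likelihood-ratio statistic equals the classical
two-proportion deviance, which the tests verify against a hand-computed
oracle to 1e-6. q-values are Benjamini–Hochberg (a deliberate, documented
divergence from the SLIM default of the package that popularised this
test: BH is standard, monotone and reproducible). Significance requires
`q < 0.05` and an absolute difference of ≥ 10 percentage points; a
`relative` mode interprets the threshold relative to the first fraction's
level instead. Averaging counts before testing makes the test
conservative relative to nominal — the null rejection rate in simulation
is well below 5 % — which is accepted as the faithful behaviour of the
published procedure.

**Bulk comparisons.** Adjacent-fraction non-conversion distributions are
compared with unpaired two-tailed Student's t tests by default (`var_equal
= FALSE` gives Welch; the published analyses say "Student's", so equal
variances is the default), overall and per mRNA region. Region
composition per trend category is tested against the all-site composition
with exact binomial tests.

**Amplicon grids.** Targeted amplicon data are summarised at full depth
with the 3C filter and terminal mask off (amplicon depth saturates and
primer-defined ends are not read ends); replicated designs get per-site
Student's t tests of each sample against the designated knockdown
reference, single-replicate designs get the grid only.

**Expression association.** Translation efficiency is normalised RPF /
RNA with genes above 60 reads in both assays (strictly more than 60);
site-bearing versus remaining genes are compared by two-sample
Kolmogorov–Smirnov on the ECDFs.

# Problem sizes and determinism

The test suite and the acceptance script exercise: a fixed 50-read toy
alignment checked exactly against an exhaustive recount; ≥ 10⁵
unmethylated cytosine observations for specificity; 200 planted sites ×
3 replicates at ~60× for sensitivity and calibration; 2 structure
clusters × 3 replicates for artefact suppression; 2,000 null and 400
alternative sites for the differential-methylation statistics; a full
4 × 3 experiment with 180 planted sites for trend recovery; all
folding windows up to 12 nt against exhaustive enumeration; and 200
Monte-Carlo enrichment runs for CI calibration. These sizes were chosen
so each property is measured with useful precision while the whole suite
runs in a few minutes on one CPU. Every stochastic step takes an explicit
seed; identical (config, seed) pairs produce byte-identical FASTA, GTF
and SAM output.
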