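---
title: "Detecting mosaic TSC1/TSC2 mutations at low allele fraction: methods and design"
author: "mosaicscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mosaic TSC1/TSC2 mutations at low allele fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscan)
```

## The problem

Tuberous sclerosis complex (TSC) is caused by inactivating mutations in
*TSC1* or *TSC2*, but 10–15% of patients meeting clinical criteria have no
mutation identified (NMI) by conventional exon sequencing and deletion
testing. Two mechanisms explain most of these: **somatic mosaicism** — the
mutation is present in only a fraction of cells, so its allele fraction (AF)
in blood or saliva DNA can be far below the heterozygous 50%, down to ~0.2%
— and **intronic mutations** that disrupt splicing from positions ordinary
exon-targeted assays never read. Detecting either requires deep targeted
sequencing of the entire genomic extent of both genes and a calling strategy
whose floor lies well below the ~20% AF that Sanger sequencing resolves.

`mosaicscan` implements that calling strategy as a tested, reusable
pipeline, together with generators that simulate every input regime the
approach was designed for, so the whole chain is verifiable without access
to patient data.

## The calling model

The caller works from an orientation-aware pileup rather than a genotype
likelihood model, because at AFs of 0.2–1% the relevant question is not
"which genotype?" but "is this allele above the machine's error floor, and
does it look like biology rather than artifact?". The chain is:

1. **Read filtering.** Reads below a mapping-quality threshold are removed;
   bases below a base-quality threshold are masked out of the counts while
   the read is retained. Both default to Phred 20 — the community
   convention; the thresholds are exposed in `tier_config()`.
2. **Redundancy normalization.** Within every (start position, orientation)
   group at most 50 reads are kept, so PCR jackpots cannot manufacture
   allele fraction. Selection is deterministic: highest mapping quality
   first, ties broken by read identifier. The cap is the
   `redundancy_cap` parameter.
3. **Per-orientation pileup.** Base calls are counted per position split by
   read orientation. Insertions are keyed to the anchor base before the
   inserted sequence; small deletions are keyed at their anchor by deleted
   length, and deleted positions contribute no base call — so column depth
   always equals the number of quality-passing read bases covering it.
4. **Tiered calling.** Every non-reference allele at AF ≥ 1% is emitted for
   review. The sensitive tier lowers the cut-off to 0.5% with at least
   three supporting reads for SNVs, and 0.2% with at least two reads for
   indels. AF is combined-orientation support over combined depth at the
   column; the orientation split feeds only the filter below. Support
   thresholds count reads across both orientations.
5. **Artifact filters.** A call supported by a single read orientation is
   flagged `single_orientation` (strand-biased chemistry artifacts); a
   candidate whose (position, allele) signature recurs in at least two
   other samples of the cohort is flagged `panel_recurrent` (process
   artifacts). Flags annotate rather than delete: review of flagged calls
   replaces manual inspection.

Threshold comparisons use a 1e-9 guard so that exact-boundary fractions
such as 3/600 = 0.5% compare as intended in floating point.

## Deletion detection from insert sizes

Multi-kilobase mosaic deletions are invisible to pileup calling but
stretch the apparent insert size of read pairs spanning the breakpoints.
Pairs with outer distance above 1,200 nt are flagged and categorized
(large: > 2,000; intermediate: 1,200–2,000). A deletion is called for every
maximal 500-nt window of flagged-pair leftmost coordinates containing at
least 3 large-category pairs, or at least 5 intermediate-category pairs;
the two categories are evaluated independently and overlapping qualifying
windows merge into one call. Windows slide over the flagged coordinates
themselves — the least arbitrary reading of "clustered within a 500 nt
region" — and the cluster rule is verified in the tests against an
exhaustive enumeration of all windows. Clusters are counted in read
*pairs*: each fragment is one observation of the junction.

Breakpoints are estimated as the median left-read end and median mate
start of the supporting pairs; they are deliberately coarse (junction PCR,
a wet-lab step, refines them in practice). The deletion AF is the
discordant fraction among breakpoint-spanning pairs, evaluated at an
*interior* point of the estimated deletion: every discordant fragment
bridges an interior point, while concordant coverage there measures the
normal-allele depth, making the fraction an unbiased local estimate
comparable to an SNV AF. (Anchoring at the estimated start breakpoint
would drop the roughly half of discordant pairs whose leftmost coordinate
lies beyond a start estimate that is itself biased inward by half a
fragment length.)

## Amplicon quantification

Confirmation of a low-AF call uses ultra-deep sequencing of a single
amplicon and exact 20-mer counting — the grep approach. `make_query_kmers()`
builds a wild-type and a mutant 20-mer (SNVs: variant at position ⌈k/2⌉;
indels: the mutant k-mer spans the novel junction with k/2 bases on each
side) and verifies each occurs exactly once in its sequence context. A read
counts at most once if it contains the k-mer or its reverse complement
(both strands of an amplicon appear in raw reads). Reads matching neither
k-mer — errors at the query locus — are excluded from the AF denominator.

The observed AF is compared against a 25-sample control panel:
`above_noise` requires strict exceedance of the panel maximum *and* a
one-sided binomial tail probability below 0.01 at the pooled panel rate.
The panel comparison in the original workflow was informal ("always
higher"); the explicit two-part rule is this package's own formalization
and both parts are configurable.

## Splice-position classification and allelic distortion

Intronic variants are classified from their cDNA-relative notation
(`c.976-15G>A`: coding position 976, acceptor-side offset −15) into:
canonical (|offset| ≤ 2), branch region (acceptor −40…−10), near-exon
(donor +3…+50, acceptor −9…−3 and −50…−41), and deep intronic
(|offset| > 50). Only the canonical dinucleotides are sharply defined
biology; the branch-region and near-exon windows are conventional
boundaries around the branch-point consensus (typically 18–40 nt upstream
of the acceptor) and are configurable via `splice_windows()`. The tests
therefore pin only the assignments that are certain (three canonical-site
and two deep-intronic variants in the packaged cohort) plus the windows'
mutual exclusivity and exhaustiveness over offsets −300…+300.
Breakpoint-uncertain large-deletion notations and 5'UTR forms parse into a
distinct non-splice bucket and are excluded from classification. For range
variants (e.g. a deletion spanning −34…−9) the most exon-proximal offset
decides the class.

Expressed heterozygous SNPs give a transcript-level readout: nonsense-
mediated decay of the mutant transcript skews the allele ratio
(lower/higher count). In population RNA-seq of a *TSC2* coding SNP the
ratio centers at 0.89 with 99% of values above 0.43, so `allelic_ratio()`
marks ratios strictly below 0.43 as distorted. The strictness matters: a
ratio of exactly 0.43 sits on the population 1st percentile and is not
called distorted.

## Cohort statistics

The packaged 53-subject table (`load_table1_fixture()`) transcribes the
study cohort: mutation status (19 heterozygous / 26 mosaic / 8
persistent-NMI), gene, mutation notation and type, AF, age, sex, and
per-organ-system major-feature counts with kidney and lung merged as one
system (renal angiomyolipoma and pulmonary LAM share pathogenesis).
Skin-biopsy-only detections (AF absent in blood/saliva) are counted as
mosaic and inside the AF < 5% bin, which is what makes that bin total 17;
the AF < 1% bin reports numeric AFs only (3) with the two skin-only cases
reported separately, since whether they belong in the sub-1% bin is
genuinely ambiguous. Medians use the standard mean-of-central-pair rule
for even group sizes — needed for the mosaic group of 26.

Association tests are the field's standard calls: Pearson chi-square
without continuity correction for the organ-involvement-by-status table
(Yates correction available for 2×2), and Mann-Whitney rank-sum for
quantitative contrasts, exact for small untied samples and otherwise the
two-sided normal approximation with tie correction. On the transcribed
table the chi-square gives p ≈ 0.0027 and the heterozygous-vs-NMI severity
contrast p ≈ 0.013. The mosaic-vs-NMI contrast lands at p ≈ 0.061 here
versus a reported 0.046; the feature data are heavily tied and different
software lineages disagree on exact-vs-approximate handling of ties at
this sample size, so the package pins the direction and magnitude of that
contrast rather than a specific sub-0.05 value. This is a known limitation
of reproducing borderline rank-test p-values across implementations.

## What the generators emulate — and what they do not

`simulate_reads()` draws uniform read starts, Bernoulli(0.5) orientation,
per-read Bernoulli(AF) variant carriage, and independent per-base
substitution errors, with `strand_asymmetry` multiplying the error rate on
reverse reads to exercise the orientation filter. Defaults are the study
regimes: 5,000× depth (long-range PCR libraries; hybrid capture ran at
500×), 50 nt reads, insert sizes Normal(400, 80). The default per-base
error of 0.1% is a calibration choice consistent with the observed
control-panel noise (background k-mer rates of 0.07–0.16%); the original
work does not state a machine error rate.

`simulate_deletion_library()` inflates the insert of a `carrier_fraction`
subset of breakpoint-spanning pairs by the deletion length, which makes
the discordant fraction among spanning pairs estimate the carrier fraction
by construction. `simulate_control_panel()` draws each control's
background AF uniformly from a configured band and its count binomially —
a count-level model of panel noise, not a re-simulation of panel reads.

None of the generators model PCR duplicate families, indel sequencing
errors, quality-score miscalibration, alignment artifacts around true
indels, or position-dependent error profiles. Passing tests therefore
demonstrate the *algorithmic* correctness and statistical calibration of
the pipeline under binomial sampling and uniform error — not robustness to
every failure mode of real libraries. The recurrent-artifact and
strand-asymmetry simulations are constructed stress tests, not empirical
error models.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere (SAM/VCF convention);
  deletions are `[start, end]` of deleted bases.
* **CIGAR support** is limited to M/I/D — everything the generators emit —
  and reads with other operations are skipped and counted, not fatal.
* **AF recovery runs** (tests and acceptance script) simulate with
  per-base error 0 so that the 3-binomial-SD acceptance band is exactly
  centered on the target AF: substitution error adds a ~e/3 background to
  any specific alternate allele, which at AF 0.5% displaces the band
  noticeably. The default error rate is exercised by the caller and
  artifact-filter tests instead.
* **Problem sizes.** The AF-recovery check runs 200 replicates per AF in
  the test suite (50 per AF in the acceptance script) on a 150-nt locus at
  5,000×; deletion recovery runs 100 replicates at 500×-equivalent pair
  counts (~58,000 pairs). These sizes give the binomial bands quoted above
  while keeping a full run in minutes on one core.
* **Determinism.** Every generator takes a seed; a run-level seed derives
  per-stage child seeds (`derive_seed()`), and `run_pipeline()` writes a
  manifest whose checksums are byte-identical across re-runs of the same
  configuration.

## Known limitations

Indel calling is anchor-based without left-alignment of complex
representations; local realignment and base-quality recalibration are out
of scope, as are genotype-likelihood models (the complementary
GATK-style path in the original workflow). Breakpoint estimates are
median-based and ±~100 nt at 500×; exact junctions need PCR. The splice
windows are conventions, not predictions — position-weight-matrix or
MaxEnt-style splice-strength scoring is deliberately not implemented. The
Mann-Whitney caveat above applies to borderline p-values generally.
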