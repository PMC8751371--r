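---
title: "Methods: genomic characterization of endometrial cancer PDX models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic characterization of endometrial cancer PDX models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecpdx)
```

`ecpdx` characterizes tumor samples — primary tumors and the
patient-derived xenograft (PDX) lineages grown from them — from three
tabular inputs: a somatic variant table, an allele-specific copy-number
segmentation, and a microsatellite-panel summary. This vignette is the
package's account of the models and rules it implements, the parameters
that matter, what the synthetic generator does and does not emulate, and
the numerical choices behind the implementation.

## Coordinates and containers

All coordinates are 1-based inclusive throughout, the convention shared
by the MAF and SEG dialects the package reads and by the wider R genomics
ecosystem; no internal conversion layer exists, which removes a whole
class of off-by-one risk. Autosomes only: the burden and scar metrics
assume a heterozygous diploid baseline of (total, minor) = (2, 1), which
does not hold on X/Y. The bundled genome is the 22 GRCh37 autosomes with
centromere bounds from the cytogenetic (acen) bands; arm-level logic
splits chromosomes at the centromere midpoint, a single unambiguous
coordinate to which the ≥ Mb-scale scar metrics are insensitive.

Unknown purity is representable (`NA`); the one operation that needs
purity, cellular-prevalence computation, takes it explicitly and
`estimate_purity()` exists to supply it. Nothing silently assumes
purity 1.

## Burden metrics

- **TMB** counts all somatic variant classes (SNV, MNV, indel) per
  callable megabase. The callable size is a per-sample input
  (default 30 Mb, exome-like) because the right denominator differs
  between exome and genome assays and is not derivable from the variant
  table itself.
- **MSI score** is the percentage of assessed microsatellite sites
  called somatically unstable; 3% is the conventional instability
  threshold.
- **CNA burden** calls a segment altered when its allele-specific state
  differs from (2, 1) in absolute terms — deliberately not
  ploidy-relative, so a genome-doubled sample reads as pervasively
  altered. Contiguous same-state segments are merged first; the percent
  altered is taken over segmented bases only, so uncovered genome does
  not dilute it.

## Mutational-signature refitting

Catalogs use the standard 96-channel convention: six pyrimidine
substitution classes × 16 flanking contexts, with purine-reference calls
reverse-complemented. Refitting proceeds in three stages:

1. **Forward selection.** Candidates are scored by a one-dimensional
   line search mixing the candidate into the current reconstruction
   (`(1−a)·recon + a·signature`, optimized over `a` to tolerance 1e-4);
   the best scorer is admitted and the admitted set is refit jointly by
   non-negative least squares before the next round. The joint refit
   matters: pure greedy reweighting oscillates between correlated peaked
   signatures and can never hand weight to a broad, flat signature.
   Selection stops when the relative error improvement falls below 1e-3.
   Ties break by signature name, so the refit is deterministic.
2. **Minimum contribution.** Signatures below the 15% cut-off are
   dropped — the same overfitting guard used when assigning known
   signatures to individual samples.
3. **Restricted refit.** Non-negative least squares on the survivors,
   renormalized to sum to one.

A sample's **dominant etiology** is reported only when its largest
exposure reaches 30%; otherwise "none". The etiology map is
Signature 1/5 → ageing, 2/13 → APOBEC, 3 → HRD, 6/15/20/26 → MMR,
10 → POLE, 14 → concurrent POLE+MMR, everything else → other.

**The bundled reference is synthetic.** The package ships a
deterministic 30-signature catalog
(`inst/extdata/signatures_sbs96_synthetic.tsv`, regenerable via
`make_synthetic_signatures()`), not measured human spectra. Signatures
carrying a named etiology reproduce the qualitative shape associated
with that process (CpG-focused C>T for the ageing clock, TpC-focused
C>T/C>G for APOBEC, a near-flat spectrum for HR deficiency, TCT-context
C>A enrichment for polymerase-epsilon proofreading loss); the remainder
are sparse, mutually distinct filler spectra. All signature analyses in
the package are closed under this catalog — catalogs are simulated from
it and refit against it — so every stated recovery result is a statement
about the refitting machinery, not about concordance with any external
reference set. Swap in any 96-row TSV via `read_signature_catalog()` to
use measured signatures. No trinucleotide-opportunity normalization is
applied (uniform opportunity), consistent with the generator.

## HRD genomic scars

- **HRD-LOH**: contiguous LOH (minor 0, total ≥ 1) segments are merged
  into runs; runs longer than 15 Mb count unless they span ≥ 90% of
  their chromosome. The whole-chromosome exclusion needs a numeric rule
  — the scar literature says only "shorter than the whole chromosome" —
  and 90% is the configured operationalization.
- **LST**: per arm, contiguous same-state segments are merged *before*
  the 3 Mb smoothing filter (merging first is what makes the metric
  invariant to how a caller split same-state segments), sub-3 Mb
  segments are discarded, newly adjacent same-state runs merge, and
  every adjacent different-state pair with both members ≥ 10 Mb counts.
- **NtAI**: allelic imbalance means minor ≠ total − minor; merged
  imbalance runs count when they touch the first or last segmented base
  of a chromosome without crossing the centromere midpoint.

The sum is compared against the threshold of 42 established for
breast/ovarian HRD. No ploidy renormalization is applied under
whole-genome duplication (scar-tool variants differ here; the config
reserves a `wgd_adjust` flag, defaulting to none). A combined evidence
summary collects the scar score, the Signature-3 fraction, and somatic
hits in an HR-gene panel (PTEN and ARID1A flagged separately, as their
PARP-inhibitor relevance is preclinical); the weighted WGS classifier
probability used elsewhere in the field needs trained weights and
structural-variant signatures and is reported as `NA` rather than
approximated.

## Subtype classification

Precedence POLE → MMRd → CN-high → CN-low, applied to the thresholds in
`default_config()`. The ordering encodes two substantive rules: a
hypermutated MSI-high sample carrying a *non*-exonuclease POLE variant is
MMRd, not POLE; and a sample meeting both the MMRd and CN-high metric
patterns is MMRd. The POLE call additionally requires TMB > 100/Mb so a
passenger exonuclease-domain variant in a quiet genome cannot trigger
it. The exonuclease domain is codons 268–471 (configurable; the domain
is named in the literature without canonical boundaries). TP53 status is
reported as evidence but never used as a criterion — the copy-number-high
group is typically yet not universally TP53-mutant — and MMRd does not
require a detected MMR-gene mutation, since the deficiency can be
epigenetic. CN-low is the residual class: "moderately stable genome" has
no numeric definition, so nothing is gained by inventing one.

## Heterogeneity and clonality

Purity is twice the mode of the somatic VAF distribution (clonal
heterozygous variants in copy-neutral regions sit at VAF = purity/2),
with the mode located by Gaussian kernel density, bandwidth 0.03, on
[0.02, 1] over 512 grid points; estimates are therefore quantized at
about the 0.002 level. At least 50 SNVs of depth ≥ 30 are required.

A panel's presence matrix uses an explicit detection rule
(VAF ≥ 0.05 and depth ≥ 10 by default — the joint-calling thresholds of
the original analyses are not published, so these are surfaced in the
config rather than buried). Euler regions are counts per presence
pattern with sorted, `&`-joined labels.

Clustering replaces a Dirichlet-process mixture with a deliberately
simple, fully specified procedure: closed-form cellular prevalences
(multiplicity fixed at 1; mutations on total copy number 0 excluded;
undetected mutations enter at prevalence 0, because absence is exactly
the signal that separates lineage-private clones), then k-means over
k = 1..8 with 10 seeded restarts, k chosen by maximum mean silhouette.
Silhouette is undefined at k = 1, so k = 1 is chosen only when the total
profile variance is below 0.001. Clusters holding ≥ 5% of all somatic
substitutions are "top" clusters. This is a declared simplification, not
a re-implementation of the probabilistic model: it is deterministic
under a fixed config and directly testable against planted truth.

Clone trees are found by exhaustive enumeration over parent assignments
(feasible for ≤ 8 clusters) with the root fixed to the cluster maximal
in every sample, keeping trees in which, per sample, each parent's
children sum to at most the parent's prevalence + 0.05, returned
tightest-fit first. An error is raised when no cluster dominates
everywhere rather than guessing a root.

## Treatment response

Relative change per animal is computed from the first measured day to
the requested end day (falling back, flagged, to the last prior day).
TGI uses arm-mean absolute volume gains; it is reported `NA` with a
warning when the vehicle arm does not grow. Response categories apply
the −30%/+20% solid-tumor thresholds directly to volume changes by
default; the published categories do not state whether volume or
diameter-equivalent change was used, so a `diameter_equivalent` flag
(cube-root transform) exposes the other convention. The longitudinal
mixed-effects testing of the original in vivo analyses is out of scope;
a seeded end-of-study permutation test is provided and labelled as the
stand-in it is.

## The synthetic cohort generator

The generator's defaults are the study conditions the analyses assume:

- **POLE preset**: expected 19,500 SNVs on 30 callable Mb
  (TMB ≈ 650/Mb, above the > 600 ultramutation bound), signature mix
  0.8 Signature 10 / 0.2 Signature 1, microsatellite unstable fraction
  0.005 on a 1000-site panel, a p.Pro286Arg POLE driver, CNA-quiet.
- **MMRd preset**: expected 1,200 SNVs (TMB ≈ 40/Mb), mix
  0.6 Signature 6 / 0.4 Signature 1, unstable fraction 0.10, PTEN and
  ARID1A drivers plus an RPL22 frameshift at its A8 homopolymer
  (indels are labelled drivers only and never enter the 96 catalog).
- **CN-low preset**: expected 120 SNVs, ageing-dominated mix, unstable
  fraction 0.005, two arm-level copy-number events.
- **CN-high preset**: expected 150 SNVs (TMB ≈ 5/Mb), the equal
  four-way APOBEC/ageing mix of a serous-like genome, 14 whole-arm
  gains and 4 whole-arm losses plus planted sub-arm scar events
  (1 large + 1 small copy-neutral LOH block, 2 terminal imbalance
  segments, 2 transition pairs). Whole-arm events dominate real
  HR-proficient aneuploid genomes and are what keeps the LST count low
  here: arm-sized segments produce no within-arm transitions. The
  planted configuration yields a deterministic scar sum of 35
  (22 NtAI + 8 LST + 5 HRD-LOH), safely under the 42 threshold, while
  guaranteeing > 25% altered genome (every arm-level event occupies an
  arm ≥ 40 Mb, and 18 × 40 Mb plus the sub-arm events already exceeds
  25% of the 2.88 Gb autosome span) and > 15 merged segments.

Mutation channels are drawn from the mixture spectrum under uniform
trinucleotide opportunity; positions uniformly over the autosomes; VAFs
as Binomial(depth, purity/2)/depth with alt counts floored at one read
(an uncalled variant would not appear in a somatic table); default depth
80, default purity 0.8. Arm-level events are placed at most one per
chromosome so telomeric runs never fuse across a centromere, and sub-arm
events get ≥ 13 Mb diploid flanks. Baseline tumor volumes are drawn once
and shared between arms, so with equal growth rates and no noise TGI is
exactly 0.

Lineage panels are simulated from an explicit clone tree (validated
against the prevalence sum rule before sampling); each mutation's
expected VAF follows the same closed form the analysis inverts, and
binomial sampling at depth naturally produces the absence of
lineage-private mutations from other samples. The planted truth
(assignments, mixtures, purities, seeds) always travels with the
simulated data.

What the generator does **not** emulate: read-level noise and mapping
artifacts, mouse stromal contamination, trinucleotide opportunity
bias, subclonal copy number, structural variants, and sequencing-batch
effects. Passing recovery tests therefore demonstrate that the
estimators invert the generative model they assume, not that they are
robust to every artifact of real PDX sequencing.

## Problem sizes and determinism

The shipped tests and the acceptance script use 50 seeds per preset for
the burden bounds, 10 for scar scoring, catalogs of 3,000–5,000 SNVs for
refitting, 500-variant purity panels, 20-seed clustering recovery on
~550-mutation three-clone panels, and 200 random segment sets against
pixel-level oracles — sizes at which every statistical margin in the
defaults is many standard deviations wide. All randomness flows through
per-call integer seeds; a rerun of the pipeline on the same inputs is
byte-identical, and the k-means step restores the caller's RNG state.

## Known limitations

- The synthetic signature catalog supports self-consistent testing, not
  etiology assignment on real tumors; use a measured catalog for that.
- Scar metrics treat list-adjacent segments within an arm as adjacent
  even across unsegmented gaps; fully segmented input (as produced by
  common allele-specific callers and by the generator) is assumed.
- Cellular prevalence assumes multiplicity 1, which understates
  prevalence for mutations duplicated by a copy-number gain.
- The classifier's thresholds are those of the endometrial four-group
  scheme; other tumor types need a different config.
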