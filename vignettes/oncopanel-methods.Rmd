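---
title: "Tumor profiling from targeted panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor profiling from targeted panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncopanel)
```

## The problem

Large hybrid-capture oncology panels (here modeled on a 523-gene / 1.94 Mb
assay) let a single tumor-only sequencing run report four classes of
clinically relevant findings: pathogenic somatic driver variants,
gene-level copy-number changes, tumor mutational burden (TMB) and
microsatellite instability (MSI). `oncopanel` implements the
*post-variant-calling* half of that workflow. Alignment, primary variant
calling, primary copy-number calling and annotation engines are upstream
of this package: their outputs (annotated VCFs, fold-change tables,
locus read-length histograms) are its inputs. The package was built
around the profiling of formalin-fixed (FFPE) male breast cancer
samples, where the germline context (BRCA1/BRCA2/PALB2 carriers) and the
actionability map (PI3Kα inhibition, PARP inhibition, immune checkpoint
blockade) are specific and well-defined, but every stage is generic
panel logic.

## Driver triage

A variant is nominated as a pathogenic (driver) somatic variant when all
of the following hold:

* caller filter `PASS`;
* exonic non-synonymous (missense, stop-gained, frameshift, in-frame
  indel) or splice-site consequence — synonymous, intronic and other
  classes are always rejected;
* allele fraction (VAF) within `[0.05, 0.90]`. The floor sits above the
  bulk of FFPE deamination artifacts; the ceiling removes
  likely-germline homozygous calls in a tumor-only setting;
* total depth ≥ 40;
* global population allele frequency < 0.01;
* flagged somatic in the Cancer Gene Census and pathogenic in COSMIC,
  consumed as boolean annotations from the input (a static snapshot
  convention: reproducibility over database freshness).

Boundary conventions are literal readings of the stated operators: the
VAF window is a closed interval, depth is inclusive, the population
filter is strict. All are configurable in `panel_thresholds()`. A
variant with *no* population-frequency annotation passes the population
filter by default, because genuinely somatic hotspots are typically
absent from population databases; `pass_missing_popmax = FALSE` inverts
this. The cascade evaluates every condition (no short-circuit), so the
audit trail lists all reasons a call failed, which makes the filter
individually testable.

## LOH at germline variants

For declared germline pathogenic variants the package inspects the raw
tumor call set — not the triaged driver set, whose VAF ceiling would
censor exactly the interesting calls — and calls loss of heterozygosity
when the tumor VAF is strictly greater than 0.50. A heterozygous variant
in a diploid tumor sits near 50%; loss of the wild-type allele pushes it
above. The threshold is a single breakpoint: 0.50 itself is `NO_LOH`.
Variants are matched by gene symbol plus HGVS protein change normalized
to one-letter amino-acid codes (`p.His1047Arg` ≡ `p.H1047R`), falling
back to the coding change. A declared variant absent from the tumor
calls is `NOT_EVALUABLE`. No purity or copy-number correction is
attempted; with tumor cellularities of 50–90% the uncorrected VAF rule
is the assay-level convention this package reproduces.

## Copy-number classification

Gene-level fold-changes (1.0 = diploid) are classified gain at ≥ 1.5,
loss at ≤ 0.5, neutral between; the integer copy estimate is
`2 × fold-change` rounded half away from zero, so the gain boundary 1.5
maps to exactly three copies (base R's `round()` would give two at some
boundaries, hence the explicit convention). Copy-number calling is
restricted to the panel's 59 eligible genes; calls outside that subset
are an input error rather than a silent pass-through. Neutral calls are
reported explicitly rather than omitted. Fold-changes are consumed, not
computed: purity/ploidy modeling and segment-level calling are upstream
concerns.

## Tumor mutational burden

TMB is the count of eligible variants divided by the captured megabases
(default 1.94 Mb), stratified high at ≥ 10 mut/Mb. The eligibility rule
set follows the convention of large commercial assays: PASS coding
variants *including synonymous*, within the same VAF floor, depth and
population gates as triage, excluding database hotspots
(COSMIC-pathogenic) and known germline variants, so that recurrently
selected drivers and inherited variants do not inflate the count. Each
exclusion is individually toggleable, because TMB eligibility is the
least standardized step in panel bioinformatics and users must be able
to match their local convention. A per-sample callable-region override
of the denominator is supported; published per-sample TMB values are
often not integer multiples of 1/1.94, indicating per-sample callable
denominators upstream.

## Microsatellite instability

Each homopolymer locus contributes a histogram of read repeat lengths
plus a baseline of expected proportions under pure polymerase stutter.
Loci with fewer than 60 reads are not assessed. The default per-locus
statistic is the *excess off-reference read fraction*: the observed
fraction of reads at lengths different from the reference repeat length,
minus the baseline expectation; a locus is unstable when the excess
exceeds 0.20. This statistic was chosen over distribution distances for
transparency — it is a single subtraction with an obvious failure mode —
but a Jensen–Shannon divergence test against the baseline distribution
ships behind the same interface (`msi_locus_method = "jsd"`, threshold
0.10) for users who want sensitivity to shape changes that preserve the
off-reference mass. The vendor-level per-locus algorithm this stands in
for is proprietary and undocumented; the implementation is an explicit
design decision, not a reconstruction.

The sample-level MSI value is `100 × unstable / assessed`; ≥ 10% is
high, zero unstable loci is "stable", and a sample with *no* assessable
locus is reported not-evaluable rather than 0% — an important
distinction for low-input FFPE samples.

The shipped 125-locus baseline (`default_msi_baseline()`, also under
`inst/extdata/msi_baseline.tsv`) uses a deletion-biased stutter model
with total off-reference proportion `0.05 + 0.005 × repeat length` split
7:2:1 over one-shorter, two-shorter and one-longer. It is synthetic and
user-replaceable; real deployments should substitute baselines estimated
from a normal cohort on the same chemistry.

## Actionability

Matching runs against a bundled, versioned knowledge-base snapshot
(OncoKB-style) rather than a live query: no credentials, and results
reproduce. The snapshot carries four entry kinds — PIK3CA hotspot
alterations at codons 345/545/1047/1049 (PI3Kα inhibitor plus ER
antagonist), germline BRCA1/BRCA2/PALB2 (PARP inhibitor), TMB-high and
MSI-high (immune checkpoint inhibition). Germline findings count
*with or without* LOH: biallelic loss is recorded in the finding's
trigger, not used as a gate. Gene matching is case-insensitive and
protein changes are normalization-invariant. Findings are ordered
deterministically (hotspots by gene and position, then germline, then
TMB, then MSI).

## Cohort reporting

Gene-level variant frequencies count a gene once per sample regardless
of multiplicity. Medians use the mean-of-central-pair convention for
even counts (R's `median()`), stated explicitly because cohort sizes are
small and even splits occur in per-gene fold-change medians. Percentages
for display are rounded to one decimal, half-up. Clinical percentages
use the reduced (non-missing) denominator per field, so one missing
HER2 status turns 15 into 14. The oncoprint matrix uses a fixed cell
vocabulary (`missense`, `truncating`, `frameshift`, `amplification`,
`germline`, `none`), concatenating multiple alterations in that fixed
order, and keeps alteration-free samples as rows.

## The simulator and what it does (not) show

`simulate_cohort()` generates cohorts with known ground truth under the
data model the pipeline assumes: drivers drawn from a hotspot catalogue
at VAF = cellularity/2 plus Gaussian noise (sd 0.03), cellularity
uniform on 50–90%; FFPE artifacts as C>T/G>A calls below the 5% VAF
floor (they carry hotspot-like database flags, so the VAF floor is the
*only* thing excluding them — a deliberate stress on that one filter,
with `artifact_stress = TRUE` moving them into the window to measure
contamination); germline heterozygous variants near 50% VAF shifted by
at least ±0.08 according to the implanted LOH state; log-normal neutral
fold-changes (sdlog 0.05) with uniform gains on [1.5, 4.0]; multinomial
locus histograms from the stutter baseline with 30% of assessable loci
shifted in MSI-high samples; and Poisson(8.3) TMB-eligible background
counts (about 4.3 mut/Mb). Defaults mirror the cohort structure the
package was developed against (15 samples, 4/15 germline carriers, half
with LOH, 2/15 MSI-high).

What passing recovery tests shows: the filters implement their
definitions exactly, and under the assumed noise model the pipeline
recovers implanted truth with precision/recall ≥ 0.95 (drivers) and
exact LOH/TMB stratum recovery. What it does not show: robustness to
misannotation, alignment artifacts beyond the deamination model,
subclonal structure, purity below 50%, or baselines that do not match
the stutter model — real data can fail in ways this generator does not
emulate.

`mbc_cohort_fixture()` is a separate, fully deterministic 15-sample
reference cohort whose pipeline outputs reproduce the headline
statistics of a published-style MBC series (73.3% actionable, 40%
PIK3CA, two TMB-high, two MSI-high, two of four carriers with LOH, MYC
gains in eight samples with median fold-change 1.9). Quantities such a
series does not print — tumor VAFs at germline variants, locus-level
histograms, non-hotspot driver identities — are synthetic and chosen
once to be consistent with the encoded per-sample statuses.

## Numerical choices and degenerate inputs

* Closed VAF window, inclusive depth and TMB/MSI cutoffs, strict
  population and LOH thresholds — all documented at the parameter and
  all configurable.
* Copy estimates round half away from zero; display percentages round
  half-up to one decimal.
* Empty inputs: empty variant tables triage to empty driver sets; an
  empty cohort summarizes without division by zero; a sample with no
  assessable MSI locus is not-evaluable, not 0%.
* Baseline histograms must sum to 1 within 1e-9; negative read counts
  are input errors, not clamped.
* Problem sizes used in the shipped tests: property suites run on a few
  hundred randomized variants per case, and parameter recovery runs 50
  seeded cohorts of 15 samples — desk-scale sizes chosen so the whole
  suite exercises every stage in about a minute.

## Known limitations

* Tumor-only design: no matched-normal subtraction anywhere; the VAF
  ceiling and population filter are the only germline defenses in
  triage.
* TMB eligibility is a stand-in for an unpublished in-house selection;
  per-sample denominators are approximated by the panel size unless
  overridden.
* The per-locus MSI test and its baseline are package conventions, not
  vendor reconstructions.
* The knowledge base is a static snapshot without evidence-level
  grading.
* HGVS strings are matched, not validated against transcript databases.
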