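# oncopanel

Post-variant-calling tumor profiling for targeted cancer-panel
sequencing, developed around the profiling of male breast cancer (MBC)
from a 523-gene / 1.94 Mb hybrid-capture assay on FFPE tissue.

Upstream tools (aligner, somatic caller, copy-number caller, annotation
engine) produce annotated VCFs, gene-level fold-change tables and
microsatellite-locus read-length histograms. `oncopanel` turns those
into a clinical-style tumor profile:

* **Driver triage** — a variant is a pathogenic (driver) somatic variant
  iff it is `PASS`, exonic non-synonymous or splice-site, has allele
  fraction in [0.05, 0.90], depth ≥ 40, population allele frequency
  < 0.01, and is Cancer Gene Census-somatic and COSMIC-pathogenic. Every
  failed condition is recorded in an audit trail.
* **LOH** — at declared germline pathogenic variants (BRCA1/BRCA2/PALB2),
  tumor VAF > 50% calls loss of heterozygosity.
* **Copy number** — fold-change ≥ 1.5 is a gain (three copies), ≤ 0.5 a
  loss (one copy); copy estimate = round(2 × FC), half away from zero.
* **TMB** — eligible mutations (PASS coding incl. synonymous, excluding
  database hotspots and germline) per megabase; ≥ 10 mut/Mb is high.
* **MSI** — per homopolymer locus (≥ 60 reads), unstable when the
  off-reference read fraction exceeds the stutter baseline by > 0.20;
  sample MSI = 100 × unstable/assessed, ≥ 10% high, 0 unstable stable.
* **Actionability** — matching against a bundled OncoKB-style snapshot:
  PIK3CA hotspots (PI3Kα inhibitor + ER antagonist), germline
  BRCA1/2/PALB2 with or without LOH (PARP inhibitor), TMB-high and
  MSI-high (immune checkpoint inhibition).
* **Cohort reporting** — per-gene frequencies, biomarker medians/ranges,
  actionable fraction, germline/LOH counts and an oncoprint-style
  sample × gene matrix.

A synthetic cohort simulator (`simulate_cohort()`) generates all inputs
with known ground truth, and `mbc_cohort_fixture()` ships a
deterministic 15-sample reference cohort. Every threshold lives in
`panel_thresholds()`; see the methods vignette
(`vignettes/oncopanel-methods.Rmd`) for the reasoning behind each
default.

## Worked example

```r
library(oncopanel)

fx    <- mbc_cohort_fixture()                      # bundled 15-sample cohort
profs <- profile_cohort(fx$variants, fx$meta, fx$cnv, fx$msi)
profs$MBC03
#> Sample profile: MBC03
#>   drivers: 3 (GATA3, PIK3CA, PIK3R1)
#>   CNV: 4 gain(s), 0 loss(es)
#>   TMB: 11.86 mut/Mb (high)
#>   MSI: 2.4% (low)
#>   actionable findings: 2
```

Sample MBC03 carries the PIK3CA p.His1047Arg hotspot (one finding:
PI3Kα inhibitor + ER antagonist) and is TMB-high (second finding:
immune checkpoint inhibitor). Aggregating the cohort:

```r
summarize_cohort(profs)
#> Cohort summary: 15 samples
#>   driver variants/sample: median 2 (range 1-5)
#>   most mutated: PIK3CA 6 (40.0%), ARID1A 3 (20.0%), EP300 3 (20.0%)
#>   samples with CNV gain: 13 (86.7%)
#>   TMB: median 4.1 mut/Mb (range 1.0-12.4), 2 high
#>   MSI: median 2.4% (range 0.0-17.6), 2 high, 1 not evaluable
#>   germline carriers: 4 (26.7%), 2 with LOH
#>   actionable: 11 (73.3%)
```

Eleven of fifteen samples (73.3%) carry at least one clinically
actionable alteration; PIK3CA is the most frequently mutated gene
(6/15, 40.0%); two samples are TMB-high, two MSI-high, and two of the
four germline carriers show biallelic loss. `write_report()` writes the
summary as JSON plus TSV tables (including the oncoprint matrix).

A command-line wrapper is available for shell use:

```sh
exec/oncopanel simulate --reference-cohort --out cohort/
exec/oncopanel triage --vcf cohort/samples/MBC03.vcf --out drivers.tsv
exec/oncopanel report --dir cohort/ --out report/
```

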