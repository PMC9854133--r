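# Synthetic FFPE cohort simulator with ground truth.
#
# The generator emulates the data model of a targeted-panel study of
# formalin-fixed tumors: per-sample driver variants drawn from a hotspot
# catalogue at allele fractions scaled by tumor cellularity (a driver in
# a heterozygous diploid state is carried by cellularity/2 of the reads),
# low-VAF deamination-like FFPE artifacts (C>T / G>A) below the triage
# VAF floor, coding background variants that feed TMB, germline
# heterozygous variants with an optional allelic-imbalance shift encoding
# LOH, gene fold-changes with occasional amplifications, and homopolymer
# read-length histograms drawn from a stutter baseline with implanted
# unstable loci in MSI-high samples.

# Chromosome map for the genes the generator and fixture use.
GENE_CHROM <- c(
  PIK3CA = "3", ARID1A = "1", EP300 = "22", SMO = "7", SMARCA4 = "19",
  PAX5 = "9", NCOR1 = "17", MAP3K1 = "5", GATA3 = "10", CREBBP = "16",
  TRAF7 = "16", TP53 = "17", PIK3R1 = "5", PDGFRA = "4", NOTCH2 = "1",
  NOTCH1 = "9", FOXL2 = "3", CIC = "19", BRAF = "7", AXIN1 = "16",
  ASXL1 = "20", ARID2 = "12", ABL1 = "9", MYC = "8", CCND1 = "11",
  FGF19 = "11", FGF3 = "11", FGF4 = "11", CDK4 = "12", MDM2 = "12",
  BRCA1 = "17", BRCA2 = "13", PALB2 = "16", ERBB2 = "17", EGFR = "7",
  FGFR1 = "8", CCNE1 = "19", AKT2 = "19", MET = "7", CDK6 = "7",
  KRAS = "12", MYCN = "2", FGFR2 = "10", FGFR3 = "4", AR = "X",
  RAF1 = "3", IGF1R = "15"
)

gene_chrom <- function(gene) {
  ifelse(gene %in% names(GENE_CHROM), GENE_CHROM[gene], "1")
}

# Deterministic synthetic locus per gene/offset (not real coordinates).
gene_pos <- function(gene, offset = 0L) {
  idx <- match(gene, sort(unique(c(names(GENE_CHROM), gene))))
  as.integer(1e6 + idx * 13577L + offset * 101L)
}

#' Default hotspot catalogue for the simulator
#'
#' Spike-in driver variants: the five breast-cancer PIK3CA hotspot
#' alterations plus one recurrent (synthetic-coordinate) variant per
#' driver gene of the panel. All entries carry Cancer Gene Census and
#' COSMIC flags, so they pass the database filters of triage.
#'
#' @return a data.frame of catalogue variants.
#' @export
default_hotspot_catalogue <- function() {
  pik <- data.frame(
    gene = "PIK3CA",
    hgvs_c = c("c.1035T>A", "c.1633G>A", "c.3140A>G", "c.3140A>T",
               "c.3145G>C"),
    hgvs_p = c("p.Asn345Lys", "p.Glu545Lys", "p.His1047Arg", "p.His1047Leu",
               "p.Gly1049Arg"),
    ref = c("T", "G", "A", "A", "G"),
    alt = c("A", "A", "G", "T", "C"),
    consequence = "missense",
    offset = 0:4,
    stringsAsFactors = FALSE
  )
  others <- setdiff(SOMATIC_GENES, "PIK3CA")
  oth <- data.frame(
    gene = others,
    hgvs_c = sprintf("c.%dC>T", 300 + 3 * seq_along(others)),
    hgvs_p = sprintf("p.Ala%dVal", 100 + seq_along(others)),
    ref = "C", alt = "T",
    consequence = "missense",
    offset = 9L + seq_along(others),
    stringsAsFactors = FALSE
  )
  cat <- rbind(pik, oth)
  cat$chrom <- gene_chrom(cat$gene)
  cat$pos <- gene_pos(cat$gene, cat$offset)
  cat$offset <- NULL
  cat
}

#' Simulation configuration
#'
#' Defaults encode the cohort structure the simulator emulates: 15
#' samples, one to five drivers each (uniform), tumor cellularity uniform
#' on 50-90% with driver VAF = cellularity/2 plus noise, about three
#' low-VAF FFPE artifacts per sample, 4/15 germline carriers of whom half
#' show LOH, sporadic copy-number gains, 2/15 MSI-high samples and
#' Poisson TMB-eligible background counts with mean 8.3 (about 4.3
#' mut/Mb on a 1.94 Mb panel).
#'
#' @param n_samples cohort size.
#' @param seed RNG seed; the seed fully determines the output.
#' @param drivers_range integer range (inclusive) of drivers per sample,
#'   drawn uniformly.
#' @param hotspot_catalogue spike-in catalogue
#'   ([default_hotspot_catalogue()]).
#' @param cellularity_range tumor cell fraction range.
#' @param vaf_noise_sd Gaussian noise added to driver VAFs.
#' @param artifact_rate expected FFPE artifacts per sample (Poisson).
#' @param artifact_vaf_range VAF range of artifacts; the default sits
#'   entirely below the 0.05 triage floor.
#' @param artifact_stress when `TRUE`, artifact VAFs are drawn inside the
#'   triage window to measure driver-set contamination.
#' @param germline_carrier_fraction fraction of samples carrying a
#'   germline pathogenic variant.
#' @param loh_fraction_among_carriers fraction of carriers with implanted
#'   LOH.
#' @param loh_vaf_margin implanted LOH VAFs are at least this far above
#'   the 0.50 threshold (and NO-LOH VAFs at least this far below).
#' @param cnv_gain_rate per gene-sample probability of an implanted gain.
#' @param cnv_gain_fc_range fold-change range of implanted gains.
#' @param cnv_neutral_sdlog log-normal spread of neutral fold-changes.
#' @param msi_high_fraction,msi_stable_fraction fractions of samples
#'   simulated MSI-high / microsatellite-stable; the remainder are low.
#' @param msi_unstable_locus_fraction fraction of assessable loci
#'   implanted unstable in MSI-high samples.
#' @param msi_low_unstable_max maximum implanted unstable loci in
#'   MSI-low samples (drawn uniformly from 1..max).
#' @param locus_coverage_lambda Poisson mean of locus coverage.
#' @param locus_low_coverage_rate probability a locus is sequenced at
#'   sub-gate coverage.
#' @param shift_excess_range implanted off-reference excess at unstable
#'   loci.
#' @param tmb_eligible_lambda Poisson mean of TMB-eligible background
#'   variants per sample.
#' @param panel a [panel_definition()] the simulated data conform to.
#' @param baseline MSI baseline table.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 15, seed = 1L,
                       drivers_range = c(1L, 5L),
                       hotspot_catalogue = default_hotspot_catalogue(),
                       cellularity_range = c(0.50, 0.90),
                       vaf_noise_sd = 0.03,
                       artifact_rate = 3,
                       artifact_vaf_range = c(0.01, 0.049),
                       artifact_stress = FALSE,
                       germline_carrier_fraction = 4 / 15,
                       loh_fraction_among_carriers = 0.5,
                       loh_vaf_margin = 0.08,
                       cnv_gain_rate = 54 / (15 * 59),
                       cnv_gain_fc_range = c(1.5, 4.0),
                       cnv_neutral_sdlog = 0.05,
                       msi_high_fraction = 2 / 15,
                       msi_stable_fraction = 0.3,
                       msi_unstable_locus_fraction = 0.30,
                       msi_low_unstable_max = 6L,
                       locus_coverage_lambda = 150,
                       locus_low_coverage_rate = 0.05,
                       shift_excess_range = c(0.30, 0.50),
                       tmb_eligible_lambda = 8.3,
                       panel = default_panel(),
                       baseline = default_msi_baseline()) {
  cfg <- as.list(environment())
  for (f in c("germline_carrier_fraction", "loh_fraction_among_carriers",
              "cnv_gain_rate", "msi_high_fraction", "msi_stable_fraction",
              "msi_unstable_locus_fraction", "locus_low_coverage_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop_input("simulation rate '%s' must be in [0, 1]", f)
    }
  }
  if (cfg$n_samples < 1) stop_input("n_samples must be >= 1")
  if (cfg$artifact_rate < 0) stop_input("artifact_rate must be >= 0")
  if (cfg$msi_high_fraction + cfg$msi_stable_fraction > 1) {
    stop_input("msi_high_fraction + msi_stable_fraction must be <= 1")
  }
  structure(cfg, class = "sim_config")
}

clip01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

# Germline pathogenic variant catalogue used for carrier simulation.
GERMLINE_CATALOGUE <- data.frame(
  gene = c("PALB2", "BRCA1", "BRCA1", "BRCA2", "BRCA2", "PALB2"),
  hgvs_c = c("c.1984A>T", "c.5266dup", "c.4484G>T", "c.6275_6276del",
             "c.5946del", "c.3113G>A"),
  hgvs_p = c("p.Lys662Ter", "p.Gln1756fs", "p.Arg1495Met", "p.Leu2092fs",
             "p.Ser1982fs", "p.Trp1038Ter"),
  consequence = c("stop_gained", "frameshift", "missense", "frameshift",
                  "frameshift", "stop_gained"),
  ref = c("A", "C", "G", "CTT", "TA", "G"),
  alt = c("T", "CA", "T", "C", "T", "A"),
  stringsAsFactors = FALSE
)

#' Simulate a cohort with known ground truth
#'
#' Generates a full input set (annotated variants, CNV fold-changes, MSI
#' locus histograms, clinical metadata) together with the ground truth of
#' every implanted alteration, and optionally writes it as a cohort
#' directory ([write_cohort()]). The config seed fully determines the
#' output; the same config yields byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory to write the cohort to.
#' @return a list of class `sim_cohort`: `variants`, `cnv`, `msi`,
#'   `meta` input tables plus `truth` (per-sample implanted drivers,
#'   artifacts, germline variants with LOH flags, CNV gains, MSI stratum,
#'   TMB-eligible count) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%02d", seq_len(n))
  panel <- cfg$panel
  baseline <- cfg$baseline
  cat <- cfg$hotspot_catalogue

  variants <- list()
  truth_drivers <- list()
  truth_artifacts <- list()

  cellularity <- runif(n, cfg$cellularity_range[1], cfg$cellularity_range[2])
  drv_choices <- seq(cfg$drivers_range[1], cfg$drivers_range[2])
  n_drivers <- drv_choices[sample.int(length(drv_choices), n,
                                      replace = TRUE)]

  # germline carriers
  carriers <- runif(n) < cfg$germline_carrier_fraction
  germ_idx <- sample(nrow(GERMLINE_CATALOGUE), sum(carriers), replace = TRUE)
  loh_flag <- runif(sum(carriers)) < cfg$loh_fraction_among_carriers

  # MSI strata
  u <- runif(n)
  msi_stratum <- ifelse(u < cfg$msi_high_fraction, "high",
                        ifelse(u < cfg$msi_high_fraction +
                                 cfg$msi_stable_fraction, "stable", "low"))

  tmb_counts <- rpois(n, cfg$tmb_eligible_lambda)

  germ_rows <- list()
  gi <- 0L
  for (s in seq_len(n)) {
    sid <- ids[s]
    pick <- sample(nrow(cat), min(n_drivers[s], nrow(cat)))
    dv <- cat[pick, , drop = FALSE]
    vaf <- clip01(cellularity[s] / 2 + rnorm(nrow(dv), 0, cfg$vaf_noise_sd))
    drv <- variant_record(
      sample_id = sid, chrom = dv$chrom, pos = dv$pos, ref = dv$ref,
      alt = dv$alt, gene = dv$gene, consequence = dv$consequence,
      vaf = vaf, depth = round(runif(nrow(dv), 100, 800)),
      popmax_af = NA_real_, cgc_somatic = TRUE, cosmic_pathogenic = TRUE,
      filter_status = "PASS", hgvs_c = dv$hgvs_c, hgvs_p = dv$hgvs_p,
      origin = "somatic_candidate")
    truth_drivers[[sid]] <- drv

    # FFPE deamination-like artifacts: C>T / G>A at low VAF. They carry
    # hotspot-like database flags so that only the VAF floor excludes
    # them; the stress mode moves them into the filter window.
    n_art <- rpois(1, cfg$artifact_rate)
    art <- NULL
    if (n_art > 0) {
      ct <- runif(n_art) < 0.5
      avaf <- if (cfg$artifact_stress) {
        runif(n_art, 0.06, 0.30)
      } else {
        runif(n_art, cfg$artifact_vaf_range[1], cfg$artifact_vaf_range[2])
      }
      art <- variant_record(
        sample_id = sid, chrom = "1",
        pos = 5e6 + sample.int(1e6, n_art),
        ref = ifelse(ct, "C", "G"), alt = ifelse(ct, "T", "A"),
        gene = sample(panel$genes, n_art, replace = TRUE),
        consequence = "missense", vaf = avaf,
        depth = round(runif(n_art, 60, 400)), popmax_af = NA_real_,
        cgc_somatic = TRUE, cosmic_pathogenic = TRUE,
        filter_status = "PASS", origin = "somatic_candidate")
    }
    truth_artifacts[[sid]] <- art %||% empty_variants()

    # coding background feeding TMB (not CGC/COSMIC flagged)
    n_bg <- tmb_counts[s]
    bg <- NULL
    if (n_bg > 0) {
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n_bg, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      bg <- variant_record(
        sample_id = sid, chrom = "2", pos = 8e6 + sample.int(2e6, n_bg),
        ref = ref, alt = alt,
        gene = sample(panel$genes, n_bg, replace = TRUE),
        consequence = sample(c("missense", "synonymous"), n_bg,
                             replace = TRUE),
        vaf = runif(n_bg, 0.10, 0.60),
        depth = round(runif(n_bg, 100, 800)), popmax_af = NA_real_,
        cgc_somatic = FALSE, cosmic_pathogenic = FALSE,
        filter_status = "PASS", origin = "somatic_candidate")
    }

    germ <- NULL
    if (carriers[s]) {
      gi <- gi + 1L
      gv <- GERMLINE_CATALOGUE[germ_idx[gi], , drop = FALSE]
      gvaf <- if (loh_flag[gi]) {
        runif(1, 0.5 + cfg$loh_vaf_margin, 0.88)
      } else {
        runif(1, 0.35, 0.5 - cfg$loh_vaf_margin)
      }
      germ <- variant_record(
        sample_id = sid, chrom = gene_chrom(gv$gene),
        pos = gene_pos(gv$gene, germ_idx[gi]), ref = gv$ref, alt = gv$alt,
        gene = gv$gene, consequence = gv$consequence, vaf = gvaf,
        depth = round(runif(1, 150, 600)), popmax_af = NA_real_,
        cgc_somatic = FALSE, cosmic_pathogenic = FALSE,
        filter_status = "PASS", hgvs_c = gv$hgvs_c, hgvs_p = gv$hgvs_p,
        origin = "known_germline")
      germ_rows[[sid]] <- cbind(germ[, c("sample_id", "gene", "hgvs_c",
                                         "hgvs_p", "vaf")],
                                true_loh = loh_flag[gi])
    }

    variants[[sid]] <- do.call(rbind, Filter(Negate(is.null),
                                             list(drv, art, bg, germ)))
  }
  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL

  # CNV table: every CNV-eligible gene per sample, neutral log-normal
  # fold-changes with implanted gains.
  grid <- expand.grid(sample_id = ids, gene = panel$cnv_genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$gene), , drop = FALSE]
  gain <- runif(nrow(grid)) < cfg$cnv_gain_rate
  fc <- rlnorm(nrow(grid), meanlog = 0, sdlog = cfg$cnv_neutral_sdlog)
  fc[gain] <- runif(sum(gain), cfg$cnv_gain_fc_range[1],
                    cfg$cnv_gain_fc_range[2])
  cnv <- data.frame(sample_id = grid$sample_id, gene = grid$gene,
                    fold_change = round(fc, 3), cytoband = NA_character_,
                    stringsAsFactors = FALSE)
  truth_gains <- cnv[gain & cnv$fold_change >= cfg$cnv_gain_fc_range[1], ,
                     drop = FALSE]

  # MSI locus histograms
  msi_rows <- list()
  truth_msi <- list()
  n_loci <- min(panel$msi_locus_count, nrow(baseline))
  for (s in seq_len(n)) {
    sid <- ids[s]
    low <- runif(n_loci) < cfg$locus_low_coverage_rate
    coverage <- rpois(n_loci, cfg$locus_coverage_lambda)
    coverage[low] <- rpois(sum(low), 40)
    assessable <- which(coverage >= 60)
    n_unstable <- switch(msi_stratum[s],
                         high = round(cfg$msi_unstable_locus_fraction *
                                        length(assessable)),
                         low = sample.int(cfg$msi_low_unstable_max, 1),
                         stable = 0L)
    n_unstable <- min(n_unstable, length(assessable))
    unstable_at <- if (n_unstable > 0) {
      sort(sample(assessable, n_unstable))
    } else {
      integer(0)
    }
    hists <- character(n_loci)
    for (l in seq_len(n_loci)) {
      b <- parse_hist(baseline$baseline[l])
      p <- b
      if (l %in% unstable_at) {
        excess <- runif(1, cfg$shift_excess_range[1],
                        cfg$shift_excess_range[2])
        ref <- as.character(baseline$ref_len[l])
        shift_to <- as.character(baseline$ref_len[l] - 1L)
        p[ref] <- p[ref] - excess
        p[shift_to] <- p[shift_to] + excess
      }
      counts <- as.vector(rmultinom(1, coverage[l], p))
      names(counts) <- names(p)
      hists[l] <- format_hist(counts[counts > 0 | names(counts) ==
                                       as.character(baseline$ref_len[l])])
    }
    msi_rows[[sid]] <- data.frame(
      sample_id = sid, locus_id = baseline$locus_id[seq_len(n_loci)],
      ref_len = baseline$ref_len[seq_len(n_loci)], histogram = hists,
      baseline = baseline$baseline[seq_len(n_loci)],
      stringsAsFactors = FALSE)
    truth_msi[[sid]] <- list(
      stratum = if (length(assessable) == 0) NA_character_ else msi_stratum[s],
      n_unstable = length(unstable_at),
      unstable_loci = baseline$locus_id[unstable_at])
  }
  msi <- do.call(rbind, msi_rows)
  rownames(msi) <- NULL

  meta <- data.frame(
    sample_id = ids,
    er = sample(c("positive", "negative"), n, replace = TRUE,
                prob = c(0.85, 0.15)),
    pr = sample(c("positive", "negative"), n, replace = TRUE,
                prob = c(0.8, 0.2)),
    her2 = sample(c("positive", "negative"), n, replace = TRUE,
                  prob = c(0.2, 0.8)),
    ar = "positive",
    grade = sample(2:3, n, replace = TRUE),
    tnm_stage = NA_character_,
    ki67_class = sample(c("high", "low"), n, replace = TRUE,
                        prob = c(0.7, 0.3)),
    intrinsic_subtype = sample(c("Luminal B HER2-", "Luminal A"), n,
                               replace = TRUE),
    tils_percent = round(pmin(70, stats::rexp(n, 1 / 12))),
    family_history = sample(c("yes", "no"), n, replace = TRUE,
                            prob = c(0.3, 0.7)),
    germline_variants = "",
    stringsAsFactors = FALSE
  )
  for (sid in names(germ_rows)) {
    g <- germ_rows[[sid]]
    meta$germline_variants[meta$sample_id == sid] <-
      format_germline(g$gene, g$hgvs_c, g$hgvs_p)
  }

  truth <- list(
    cellularity = stats::setNames(cellularity, ids),
    drivers = truth_drivers,
    artifacts = truth_artifacts,
    germline = germ_rows,
    cnv_gains = truth_gains,
    msi = truth_msi,
    tmb_eligible_count = stats::setNames(as.integer(tmb_counts), ids)
  )
  cohort <- structure(list(variants = variants, cnv = cnv, msi = msi,
                           meta = meta, truth = truth, config = cfg),
                      class = "sim_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to a directory
#'
#' Writes per-sample VCFs under `samples/`, plus `cnv.tsv`, `msi.tsv`,
#' `meta.tsv` and (when ground truth is present) `truth.json`, in the
#' formats of the package readers; [read_cohort_dir()] reads the layout
#' back.
#'
#' @param cohort a list with `variants`, `cnv`, `msi`, `meta` (and
#'   optionally `truth`), e.g. from [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  for (sid in cohort$meta$sample_id) {
    v <- cohort$variants[cohort$variants$sample_id == sid, , drop = FALSE]
    write_variants(v, file.path(dir, "samples", paste0(sid, ".vcf")))
  }
  write_cnv_table(cohort$cnv, file.path(dir, "cnv.tsv"))
  write_msi_table(cohort$msi, file.path(dir, "msi.tsv"))
  write_sample_meta(cohort$meta, file.path(dir, "meta.tsv"))
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$config <- NULL
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  invisible(dir)
}
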