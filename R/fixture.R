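# Bundled 15-sample male-breast-cancer reference cohort.
#
# A fully deterministic desk-scale cohort encoding the alteration pattern
# of a published-style MBC series: 40 driver variants over 23 genes
# (median 2 per sample, range 1-5, three samples with five), six samples
# with actionable PIK3CA hotspot variants, four germline BRCA1/BRCA2/PALB2
# carriers of whom two show LOH in the tumor, 54 copy-number gains over 22
# genes in 13 samples (MYC in eight samples, median fold-change 1.9,
# range 1.8-3.8), two TMB-high samples (about 12.4 and 11.9 mut/Mb), two
# MSI-high samples (17.6% and 14.3%) and one sample whose microsatellite
# loci all fall below the coverage gate (MSI not evaluable).
#
# Values the underlying series does not pin down (tumor VAFs at germline
# variants, non-hotspot driver identities, locus-level histograms) are
# synthetic, chosen to be consistent with the encoded per-sample statuses.

FIXTURE_IDS <- sprintf("MBC%02d", 1:15)

# sample index, gene, consequence; PIK3CA hotspot rows are added from the
# catalogue separately.
fixture_driver_plan <- function() {
  plan <- list(
    `1` = list(c("MAP3K1", "missense"), c("TP53", "stop_gained")),
    `2` = list(c("BRAF", "missense")),
    `3` = list(c("GATA3", "missense"), c("PIK3R1", "missense")),
    `4` = list(c("AXIN1", "missense")),
    `5` = list(c("CREBBP", "missense"), c("PDGFRA", "missense")),
    `6` = list(c("ASXL1", "missense")),
    `7` = list(c("ARID2", "missense")),
    `8` = list(c("ARID1A", "frameshift"), c("NOTCH2", "missense")),
    `9` = list(c("ABL1", "missense")),
    `10` = list(c("EP300", "missense"), c("NOTCH1", "missense")),
    `11` = list(c("PAX5", "missense"), c("NCOR1", "missense"),
                c("TRAF7", "missense")),
    `12` = list(c("FOXL2", "missense"), c("CIC", "stop_gained")),
    `13` = list(c("ARID1A", "missense"), c("ARID1A", "frameshift"),
                c("EP300", "missense"), c("SMO", "missense"),
                c("SMARCA4", "missense")),
    `14` = list(c("PAX5", "missense"), c("NCOR1", "frameshift"),
                c("MAP3K1", "missense"), c("GATA3", "missense"),
                c("CREBBP", "missense")),
    `15` = list(c("ARID1A", "missense"), c("EP300", "missense"),
                c("SMO", "missense"), c("SMARCA4", "missense"))
  )
  rows <- list()
  k <- 0L
  for (s in names(plan)) {
    for (entry in plan[[s]]) {
      k <- k + 1L
      rows[[k]] <- data.frame(sample = as.integer(s), gene = entry[1],
                              consequence = entry[2], idx = k,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# PIK3CA hotspot assignment: sample index -> coding change.
FIXTURE_PIK3CA <- data.frame(
  sample = c(2L, 3L, 7L, 10L, 11L, 15L),
  hgvs_c = c("c.3145G>C", "c.3140A>G", "c.3140A>T", "c.1035T>A",
             "c.1633G>A", "c.3140A>G"),
  stringsAsFactors = FALSE
)

fixture_hgvs <- function(consequence, idx) {
  switch(consequence,
         missense = c(sprintf("c.%dC>T", 448 + 3 * idx),
                      sprintf("p.Ala%dVal", 150 + idx)),
         frameshift = c(sprintf("c.%ddel", 600 + 3 * idx),
                        sprintf("p.Lys%dfs", 200 + idx)),
         stop_gained = c(sprintf("c.%dC>T", 328 + 3 * idx),
                         sprintf("p.Arg%dTer", 110 + idx)))
}

fixture_driver_variants <- function() {
  plan <- fixture_driver_plan()
  vafs <- rep(c(0.18, 0.22, 0.27, 0.31, 0.35, 0.40, 0.44),
              length.out = nrow(plan))
  depths <- rep(seq(150L, 650L, by = 50L), length.out = nrow(plan))
  # two of the 40 drivers sit below 10% VAF, both at depth > 100
  low <- which(plan$sample == 13 & plan$consequence == "frameshift")[1]
  vafs[low] <- 0.07
  low2 <- which(plan$sample == 14 & plan$gene == "PAX5")[1]
  vafs[low2] <- 0.09
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    hg <- fixture_hgvs(p$consequence, p$idx)
    ref <- if (p$consequence == "frameshift") "CT" else "C"
    alt <- if (p$consequence == "frameshift") "C" else "T"
    variant_record(
      sample_id = FIXTURE_IDS[p$sample], chrom = gene_chrom(p$gene),
      pos = gene_pos(p$gene, p$idx), ref = ref, alt = alt, gene = p$gene,
      consequence = p$consequence, vaf = vafs[i], depth = depths[i],
      popmax_af = NA_real_, cgc_somatic = TRUE, cosmic_pathogenic = TRUE,
      filter_status = "PASS", hgvs_c = hg[1], hgvs_p = hg[2],
      origin = "somatic_candidate")
  })
  cat <- default_hotspot_catalogue()
  pik <- lapply(seq_len(nrow(FIXTURE_PIK3CA)), function(i) {
    hs <- cat[cat$gene == "PIK3CA" &
                cat$hgvs_c == FIXTURE_PIK3CA$hgvs_c[i], ][1, ]
    variant_record(
      sample_id = FIXTURE_IDS[FIXTURE_PIK3CA$sample[i]], chrom = hs$chrom,
      pos = hs$pos, ref = hs$ref, alt = hs$alt, gene = "PIK3CA",
      consequence = "missense", vaf = 0.24 + 0.03 * i, depth = 400L + 20L * i,
      popmax_af = NA_real_, cgc_somatic = TRUE, cosmic_pathogenic = TRUE,
      filter_status = "PASS", hgvs_c = hs$hgvs_c, hgvs_p = hs$hgvs_p,
      origin = "somatic_candidate")
  })
  out <- do.call(rbind, c(rows, pik))
  rownames(out) <- NULL
  out
}

# Germline pathogenic variants: carriers, coding/protein changes, tumor
# VAFs consistent with the encoded LOH statuses (> 0.50 for LOH).
FIXTURE_GERMLINE <- data.frame(
  sample = c(1L, 4L, 5L, 12L),
  gene = c("PALB2", "BRCA1", "BRCA1", "BRCA2"),
  hgvs_c = c("c.1984A>T", "c.5266dup", "c.4484G>T", "c.6275_6276del"),
  hgvs_p = c("p.Lys662Ter", "p.Gln1756fs", "p.Arg1495Met", "p.Leu2092fs"),
  consequence = c("stop_gained", "frameshift", "missense", "frameshift"),
  ref = c("A", "C", "G", "CTT"),
  alt = c("T", "CA", "T", "C"),
  tumor_vaf = c(0.72, 0.45, 0.68, 0.42),
  true_loh = c(TRUE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

fixture_germline_variants <- function() {
  g <- FIXTURE_GERMLINE
  out <- variant_record(
    sample_id = FIXTURE_IDS[g$sample], chrom = gene_chrom(g$gene),
    pos = gene_pos(g$gene, g$sample), ref = g$ref, alt = g$alt,
    gene = g$gene, consequence = g$consequence, vaf = g$tumor_vaf,
    depth = c(310L, 280L, 295L, 305L), popmax_af = NA_real_,
    cgc_somatic = FALSE, cosmic_pathogenic = FALSE, filter_status = "PASS",
    hgvs_c = g$hgvs_c, hgvs_p = g$hgvs_p, origin = "known_germline")
  out
}

# TMB-eligible background counts per sample; 24/1.94 and 23/1.94 mut/Mb
# put samples 1 and 3 above the 10 mut/Mb cutoff, cohort median 8
# eligible variants (about 4.1 mut/Mb).
FIXTURE_TMB_COUNTS <- c(24L, 8L, 23L, 4L, 7L, 5L, 8L, 10L, 2L, 11L, 12L,
                        6L, 14L, 16L, 8L)

fixture_background_variants <- function(panel = default_panel()) {
  rows <- list()
  j <- 0L
  bases <- c("A", "C", "G", "T")
  for (s in 1:15) {
    n <- FIXTURE_TMB_COUNTS[s]
    if (n == 0L) next
    jj <- j + seq_len(n)
    ref <- bases[1 + (jj %% 4)]
    alt <- bases[1 + ((jj + 1) %% 4)]
    rows[[s]] <- variant_record(
      sample_id = FIXTURE_IDS[s], chrom = "2", pos = 8e6 + 137L * jj,
      ref = ref, alt = alt,
      gene = panel$genes[1 + (jj %% 50)],
      consequence = ifelse(jj %% 2 == 0, "missense", "synonymous"),
      vaf = 0.15 + 0.01 * (jj %% 25), depth = 120L + 7L * (jj %% 60),
      popmax_af = NA_real_, cgc_somatic = FALSE, cosmic_pathogenic = FALSE,
      filter_status = "PASS", origin = "somatic_candidate")
    j <- j + n
  }
  do.call(rbind, rows)
}

# Two deamination-like FFPE artifacts per sample, below the 5% VAF floor.
fixture_artifact_variants <- function() {
  rows <- lapply(1:15, function(s) {
    variant_record(
      sample_id = FIXTURE_IDS[s], chrom = "1",
      pos = c(5e6 + 31L * s, 5e6 + 31L * s + 7L),
      ref = c("C", "G"), alt = c("T", "A"),
      gene = c("TP53", "EGFR"), consequence = "missense",
      vaf = c(0.02, 0.035), depth = c(80L, 120L), popmax_af = NA_real_,
      cgc_somatic = TRUE, cosmic_pathogenic = TRUE, filter_status = "PASS",
      origin = "somatic_candidate")
  })
  do.call(rbind, rows)
}

# Copy-number gains: 54 gains over 22 genes in 13 samples; MYC in eight
# samples with fold-changes 1.8-3.8 (median 1.9); the 11q13.3 cluster
# (CCND1/FGF19/FGF3/FGF4) and the 12q genes (CDK4, MDM2) as per-gene
# medians 3.7 / 2.4 / 2.9 / 5.9 / 2.9 / 2.9.
fixture_cnv_gains <- function() {
  g <- function(gene, cytoband, samples, fcs) {
    data.frame(sample = samples, gene = gene, cytoband = cytoband,
               fold_change = fcs, stringsAsFactors = FALSE)
  }
  rbind(
    g("MYC", "8q24.21", c(1, 2, 3, 5, 7, 10, 13, 15),
      c(1.8, 1.8, 1.9, 1.9, 1.9, 2.0, 3.0, 3.8)),
    g("CCND1", "11q13.3", c(2, 5, 8, 13, 14), c(2.5, 3.0, 3.7, 4.8, 5.9)),
    g("FGF19", "11q13.3", c(2, 5, 13, 14), c(1.9, 2.2, 2.6, 3.4)),
    g("FGF3", "11q13.3", c(2, 13, 14), c(2.0, 2.9, 3.5)),
    g("FGF4", "11q13.3", c(13, 14), c(5.6, 6.2)),
    g("CDK4", "12q14.1", c(3, 10, 12), c(1.8, 2.9, 4.0)),
    g("MDM2", "12q15", c(3, 10, 12, 15), c(2.1, 2.7, 3.1, 3.6)),
    g("ERBB2", "17q12", c(4, 7), c(2.8, 3.2)),
    g("EGFR", "7p11.2", c(1, 11), c(1.7, 2.1)),
    g("FGFR1", "8p11.23", c(5, 8), c(1.9, 2.3)),
    g("CCNE1", "19q12", c(3, 14), c(2.2, 2.6)),
    g("AKT2", "19q13.2", c(10, 13), c(1.6, 1.8)),
    g("MET", "7q31.2", c(7, 15), c(1.7, 2.4)),
    g("CDK6", "7q21.2", c(8, 12), c(1.8, 2.0)),
    g("KRAS", "12p12.1", c(1, 11), c(1.6, 1.9)),
    g("MYCN", "2p24.3", c(5, 14), c(2.0, 2.5)),
    g("PDGFRA", "4q12", c(4, 13), c(1.7, 2.2)),
    g("FGFR2", "10q26.13", 11, 1.8),
    g("FGFR3", "4p16.3", 12, 1.6),
    g("AR", "Xq12", 2, 1.9),
    g("RAF1", "3p25.2", 8, 1.7),
    g("IGF1R", "15q26.3", 10, 2.0)
  )
}

fixture_cnv_table <- function(panel = default_panel()) {
  gains <- fixture_cnv_gains()
  gains$sample_id <- FIXTURE_IDS[gains$sample]
  grid <- expand.grid(sample_id = FIXTURE_IDS, gene = panel$cnv_genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$sample_id, grid$gene)
  gkey <- paste(gains$sample_id, gains$gene)
  neutral <- grid[!key %in% gkey, , drop = FALSE]
  gi <- match(neutral$gene, panel$cnv_genes) +
    match(neutral$sample_id, FIXTURE_IDS)
  neutral$fold_change <- 0.90 + 0.01 * (gi %% 20)
  neutral$cytoband <- NA_character_
  out <- rbind(gains[, c("sample_id", "gene", "fold_change", "cytoband")],
               neutral[, c("sample_id", "gene", "fold_change", "cytoband")])
  out <- out[order(out$sample_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Unstable locus counts per sample. Sample 1 has every locus below the
# 60-read gate (MSI not evaluable); sample 2 is 22/125 = 17.6% and
# sample 8 is 17/119 = 14.3% (six of its loci below the gate); four
# samples are fully stable; the rest are low (cohort median 2.4%).
FIXTURE_MSI_UNSTABLE <- c(0L, 22L, 3L, 0L, 3L, 0L, 3L, 17L, 0L, 4L, 5L,
                          6L, 0L, 8L, 2L)

# Deterministic histogram: floor(p * coverage) with the remainder on the
# reference bin; unstable loci move `excess` mass from the reference
# length to one repeat unit shorter.
fixture_locus_hist <- function(ref_len, coverage, excess = 0) {
  p <- stutter_baseline(ref_len)
  if (excess > 0) {
    ref <- as.character(ref_len)
    shift_to <- as.character(ref_len - 1L)
    p[ref] <- p[ref] - excess
    p[shift_to] <- p[shift_to] + excess
  }
  counts <- floor(p * coverage)
  counts[as.character(ref_len)] <- counts[as.character(ref_len)] +
    coverage - sum(counts)
  format_hist(counts)
}

fixture_msi_table <- function(baseline = default_msi_baseline()) {
  rows <- list()
  for (s in 1:15) {
    n_loci <- nrow(baseline)
    coverage <- 100L + (seq_len(n_loci) - 1L) %% 40L
    if (s == 1L) coverage[] <- 45L
    if (s == 8L) coverage[1:6] <- 59L
    n_unst <- FIXTURE_MSI_UNSTABLE[s]
    unstable_at <- if (n_unst > 0) 9L + seq_len(n_unst) else integer(0)
    hists <- vapply(seq_len(n_loci), function(l) {
      fixture_locus_hist(baseline$ref_len[l], coverage[l],
                         excess = if (l %in% unstable_at) 0.35 else 0)
    }, "")
    rows[[s]] <- data.frame(
      sample_id = FIXTURE_IDS[s], locus_id = baseline$locus_id,
      ref_len = baseline$ref_len, histogram = hists,
      baseline = baseline$baseline, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fixture_meta <- function() {
  pos <- "positive"
  neg <- "negative"
  g <- FIXTURE_GERMLINE
  gv <- character(15)
  for (i in seq_len(nrow(g))) {
    gv[g$sample[i]] <- format_germline(g$gene[i], g$hgvs_c[i], g$hgvs_p[i])
  }
  data.frame(
    sample_id = FIXTURE_IDS,
    er = c(neg, pos, pos, neg, pos, pos, pos, pos, pos, pos, pos, pos,
           pos, pos, pos),
    pr = c(pos, pos, pos, neg, pos, pos, pos, pos, pos, pos, pos, pos,
           pos, pos, pos),
    her2 = c(NA, neg, neg, pos, neg, neg, pos, neg, neg, neg, neg, pos,
             neg, neg, neg),
    ar = c(NA, rep(pos, 14)),
    grade = c(3L, 2L, 3L, 3L, 2L, 2L, 3L, 2L, 2L, 3L, 2L, 3L, 3L, 2L, 2L),
    tnm_stage = NA_character_,
    ki67_class = c("high", "high", "high", "high", "low", "low", "high",
                   "high", "low", "high", "high", "high", "high", "high",
                   "high"),
    intrinsic_subtype = c("triple negative", "Luminal B HER2-",
                          "Luminal B HER2-", "HER2-enriched",
                          "Luminal B HER2-", "Luminal A",
                          "Luminal B HER2+", "Luminal B HER2-",
                          "Luminal A", "Luminal B HER2-",
                          "Luminal B HER2-", "Luminal B HER2+",
                          "Luminal B HER2-", "Luminal A",
                          "Luminal B HER2-"),
    tils_percent = c(10, 5, 20, 0, 10, 15, 70, 10, 0, 10, 5, 30, 10, 0, 10),
    family_history = c("yes", "no", NA, "no", "yes", "no", "no", "no",
                       "no", "yes", "no", "no", "yes", "no", "no"),
    germline_variants = gv,
    stringsAsFactors = FALSE
  )
}

#' Bundled 15-sample male-breast-cancer reference cohort
#'
#' A deterministic desk-scale cohort (see the file-level description in
#' the source) whose pipeline outputs reproduce the headline statistics of
#' a targeted-panel MBC series: 11/15 (73.3%) actionable samples, PIK3CA
#' drivers in 6/15 (40.0%) with five distinct hotspot alterations, four
#' germline carriers (26.7%) with LOH in two, two TMB-high and two
#' MSI-high samples, MYC gains in 8/15 (median fold-change 1.9). Sample
#' `MBC01` has all microsatellite loci below the coverage gate and is MSI
#' not-evaluable. Quantities the underlying series leaves unstated are
#' synthetic and consistent with the encoded statuses.
#'
#' @param out_dir optional directory to write the cohort to
#'   ([write_cohort()] layout).
#' @return a list of class `sim_cohort` with `variants`, `cnv`, `msi`,
#'   `meta`, `truth`.
#' @export
mbc_cohort_fixture <- function(out_dir = NULL) {
  panel <- default_panel()
  baseline <- default_msi_baseline()
  drivers <- fixture_driver_variants()
  germ <- fixture_germline_variants()
  variants <- rbind(drivers, fixture_artifact_variants(),
                    fixture_background_variants(panel), germ)
  variants <- variants[order(variants$sample_id, variants$chrom,
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  g <- FIXTURE_GERMLINE
  truth <- list(
    drivers = split(drivers, drivers$sample_id),
    germline = data.frame(sample_id = FIXTURE_IDS[g$sample],
                          gene = g$gene, hgvs_c = g$hgvs_c,
                          hgvs_p = g$hgvs_p, tumor_vaf = g$tumor_vaf,
                          true_loh = g$true_loh, stringsAsFactors = FALSE),
    cnv_gains = {
      x <- fixture_cnv_gains()
      x$sample_id <- FIXTURE_IDS[x$sample]
      x[, c("sample_id", "gene", "cytoband", "fold_change")]
    },
    msi_unstable = stats::setNames(FIXTURE_MSI_UNSTABLE, FIXTURE_IDS),
    tmb_eligible_count = stats::setNames(FIXTURE_TMB_COUNTS, FIXTURE_IDS)
  )
  cohort <- structure(list(variants = variants, cnv = fixture_cnv_table(panel),
                           msi = fixture_msi_table(baseline),
                           meta = fixture_meta(), truth = truth,
                           config = NULL),
                      class = "sim_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}
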