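make_meta <- function(sample_id = "S01", gene = "PALB2",
                      hgvs_c = "c.1984A>T", hgvs_p = "p.Lys662Ter") {
  data.frame(sample_id = sample_id, er = "positive", pr = "positive",
             her2 = "negative", ar = NA, grade = NA, tnm_stage = NA,
             ki67_class = NA, intrinsic_subtype = NA, tils_percent = NA,
             family_history = NA,
             germline_variants = sprintf("%s|%s|%s", gene, hgvs_c, hgvs_p),
             stringsAsFactors = FALSE)
}

germ_call <- function(vaf, hgvs_p = "p.Lys662Ter", gene = "PALB2") {
  variant_record("S01", chrom = "16", pos = 23641000, ref = "A", alt = "T",
                 gene = gene, consequence = "stop_gained", vaf = vaf,
                 depth = 300, cgc_somatic = FALSE,
                 cosmic_pathogenic = FALSE, hgvs_c = "c.1984A>T",
                 hgvs_p = hgvs_p, origin = "known_germline")
}

test_that("tumor VAF above 50% is LOH, the threshold itself is not", {
  meta <- make_meta()
  expect_equal(evaluate_loh(meta, germ_call(0.72))$status, "LOH")
  expect_equal(evaluate_loh(meta, germ_call(0.50))$status, "NO_LOH")
  expect_equal(evaluate_loh(meta, germ_call(0.501))$status, "LOH")
  # germline VAFs above the somatic triage ceiling still evaluate
  expect_equal(evaluate_loh(meta, germ_call(0.95))$status, "LOH")
})

test_that("LOH status is a step function of tumor VAF with one breakpoint", {
  meta <- make_meta()
  cfg <- panel_thresholds()
  vafs <- seq(0.05, 0.95, by = 0.05)
  status <- vapply(vafs,
                   function(v) evaluate_loh(meta, germ_call(v), cfg)$status,
                   "")
  expect_equal(status, ifelse(vafs > cfg$loh_vaf, "LOH", "NO_LOH"))
  expect_equal(sum(diff(status == "LOH") != 0), 1)
})

test_that("matching normalizes amino-acid codes and falls back to hgvs_c", {
  meta <- make_meta(hgvs_p = "p.Lys662Ter")
  one_letter <- germ_call(0.72, hgvs_p = "p.K662*")
  expect_equal(evaluate_loh(meta, one_letter)$status, "LOH")
  no_p <- germ_call(0.72, hgvs_p = NA)
  expect_equal(evaluate_loh(meta, no_p)$status, "LOH")
})

test_that("absent tumor calls and absent germline variants are handled", {
  meta <- make_meta()
  other <- variant_record("S01", gene = "TP53")
  out <- evaluate_loh(meta, other)
  expect_equal(out$status, "NOT_EVALUABLE")
  expect_true(is.na(out$tumor_vaf))
  none <- make_meta()
  none$germline_variants <- ""
  expect_equal(nrow(evaluate_loh(none, other)), 0)
})

test_that("the fixture cohort recovers two LOH events among four carriers", {
  profs <- fixture_profiles()
  loh <- do.call(rbind, lapply(profs, `[[`, "loh"))
  expect_equal(nrow(loh), 4)
  expect_equal(sum(loh$status == "LOH"), 2)
  expect_setequal(loh$gene[loh$status == "LOH"], c("PALB2", "BRCA1"))
  expect_equal(loh$status[loh$sample_id %in% c("MBC04", "MBC12")],
               c("NO_LOH", "NO_LOH"))
})
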