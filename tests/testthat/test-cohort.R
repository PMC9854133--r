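test_that("cohort aggregation reproduces the fixture's headline frequencies", {
  s <- fixture_summary()
  expect_equal(s$n_samples, 15L)
  expect_equal(s$n_actionable, 11L)
  expect_equal(s$pct_actionable, 73.3)
  pik <- s$gene_variant_freq[s$gene_variant_freq$gene == "PIK3CA", ]
  expect_equal(pik$n_mutated, 6L)
  expect_equal(pik$percent, 40.0)
  expect_equal(s$germline_summary$n_carriers, 4L)
  expect_equal(s$germline_summary$pct_carriers, 26.7)
  expect_equal(s$germline_summary$n_with_loh, 2L)
  expect_equal(s$variants_per_sample_summary,
               list(median = 2, min = 1L, max = 5L))
  expect_equal(sum(s$variants_per_sample$n_variants), 40L)
  expect_equal(sum(s$variants_per_sample$n_variants == 5), 3L)
  expect_equal(s$tmb_summary$n_high, 2L)
  expect_equal(s$msi_summary$n_high, 2L)
  expect_equal(s$msi_summary$n_not_evaluable, 1L)
  expect_equal(s$pct_samples_with_gain, 86.7)
})

test_that("clinical percentages use reduced denominators for missing data", {
  s <- fixture_summary()
  fh <- s$clinical[s$clinical$field == "family_history", ]
  expect_equal(fh$denominator, 14L)
  expect_equal(fh$percent, 28.6)
  her2 <- s$clinical[s$clinical$field == "her2_positive", ]
  expect_equal(her2$denominator, 14L)
})

test_that("oncoprint and frequency table conserve (sample, gene) mutation pairs", {
  profs <- fixture_profiles()
  s <- fixture_summary()
  op <- s$oncoprint
  expect_equal(nrow(op), 15)
  has_variant <- apply(op, c(1, 2), function(cell) {
    any(strsplit(cell, ";", fixed = TRUE)[[1]] %in%
          c("missense", "truncating", "frameshift"))
  })
  expect_equal(sum(has_variant), sum(s$gene_variant_freq$n_mutated))
  expect_true(all(unlist(strsplit(as.vector(op), ";")) %in%
                    c("missense", "truncating", "frameshift",
                      "amplification", "germline", "none")))
  # alteration-free samples still appear as oncoprint rows
  expect_true(all(sprintf("MBC%02d", 1:15) %in% rownames(op)))
})

test_that("an empty cohort summarizes without division by zero", {
  s <- summarize_cohort(list())
  expect_equal(s$n_samples, 0L)
  expect_equal(s$n_actionable, 0L)
  expect_true(is.na(s$pct_actionable))
  expect_equal(nrow(s$gene_variant_freq), 0)
})

test_that("duplicate sample identifiers are rejected", {
  profs <- fixture_profiles()
  expect_error(summarize_cohort(list(profs$MBC01, profs$MBC01)),
               class = "oncopanel_input_error")
})

test_that("reports round-trip through JSON", {
  s <- fixture_summary()
  dir <- withr::local_tempdir()
  write_report(s, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "report.json", "gene_frequencies.tsv", "cnv_frequencies.tsv",
    "biomarkers.tsv", "findings.tsv", "oncoprint.tsv")))))
  back <- read_report(dir)
  expect_equal(back$n_samples, s$n_samples)
  expect_equal(back$pct_actionable, s$pct_actionable)
  expect_equal(back$gene_variant_freq, s$gene_variant_freq)
  expect_equal(back$cnv_gene_freq, s$cnv_gene_freq)
  expect_equal(back$tmb_summary, s$tmb_summary)
  expect_equal(back$msi_summary, s$msi_summary)
  expect_equal(back$germline_summary, s$germline_summary)
  expect_equal(back$oncoprint, s$oncoprint)
  # report carries the germline carrier and LOH counts
  json <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(json$germline_summary$n_carriers, 4)
  expect_equal(json$germline_summary$n_with_loh, 2)
})
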