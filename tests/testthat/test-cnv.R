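cnv_call <- function(gene, fc, sample_id = "S01") {
  data.frame(sample_id = sample_id, gene = gene, fold_change = fc,
             cytoband = NA_character_, stringsAsFactors = FALSE)
}

test_that("fold-change thresholds classify gains, losses and neutral calls", {
  out <- classify_cnv(cnv_call("MYC", 1.8))
  expect_equal(out$label, "gain")
  expect_equal(out$estimated_copies, 4L)

  out <- classify_cnv(cnv_call("MYC", 0.5))
  expect_equal(out$label, "loss")
  expect_equal(out$estimated_copies, 1L)

  out <- classify_cnv(cnv_call("MYC", 1.0))
  expect_equal(out$label, "neutral")
  expect_equal(out$estimated_copies, 2L)

  # boundaries are inclusive; 1.5 maps to three copies (half away from zero)
  expect_equal(classify_cnv(cnv_call("MYC", 1.5))$label, "gain")
  expect_equal(classify_cnv(cnv_call("MYC", 1.5))$estimated_copies, 3L)
  expect_equal(classify_cnv(cnv_call("MYC", 1.25))$estimated_copies, 3L)
})

test_that("genes outside the CNV-eligible subset are rejected", {
  expect_error(classify_cnv(cnv_call("GATA3", 2.0)),
               "GATA3", class = "oncopanel_input_error")
})

test_that("every call gets exactly one label and labels partition by fold-change", {
  withr::with_seed(31, {
    fc <- round(exp(runif(400, log(0.2), log(5))), 3)
  })
  calls <- cnv_call(rep("MYC", 400), fc)
  cfg <- panel_thresholds()
  out <- classify_cnv(calls, cfg = cfg)
  expect_true(all(out$label %in% c("gain", "loss", "neutral")))
  expect_equal(out$label == "gain", fc >= cfg$cnv_gain_fc)
  expect_equal(out$label == "loss", fc <= cfg$cnv_loss_fc)
  expect_false(any(out$label == "gain" & out$label == "loss"))
  expect_equal(out$estimated_copies, as.integer(floor(2 * fc + 0.5)))
})

test_that("per-gene summaries use the mean-of-central-pair median", {
  fcs <- c(1.8, 1.8, 1.9, 1.9, 1.9, 2.0, 3.0, 3.8)
  calls <- cnv_call(rep("MYC", 8), fcs,
                    sample_id = sprintf("S%02d", 1:8))
  smry <- summarize_cnv(classify_cnv(calls))
  expect_equal(smry$n_gain, 8L)
  expect_equal(smry$median_gain_fc, 1.9)
  # even-count median of the central pair
  even <- summarize_cnv(classify_cnv(cnv_call(rep("MYC", 4), c(2.1, 2.7, 3.1, 3.6),
                                              sample_id = sprintf("S%02d", 1:4))))
  expect_equal(even$median_gain_fc, 2.9)
  expect_equal(nrow(summarize_cnv(classify_cnv(cnv_call("MYC", 1.0)))), 0)
  expect_equal(nrow(summarize_cnv(cnv_call("MYC", 1.2)[0, ])), 0)
})

test_that("the fixture cohort reproduces the published gain pattern", {
  fx <- fixture_cohort()
  classified <- classify_cnv(fx$cnv)
  gains <- classified[classified$label == "gain", ]
  expect_equal(nrow(gains), 54)
  expect_equal(length(unique(gains$gene)), 22)
  expect_equal(length(unique(gains$sample_id)), 13)
  expect_equal(sum(classified$label == "loss"), 0)
  smry <- summarize_cnv(classified)
  myc <- smry[smry$gene == "MYC", ]
  expect_equal(myc$n_gain, 8L)
  expect_equal(myc$median_gain_fc, 1.9)
  expect_equal(range(gains$fold_change[gains$gene == "MYC"]), c(1.8, 3.8))
  # recovered gain set equals the implanted set
  key <- function(df) sort(paste(df$sample_id, df$gene))
  expect_equal(key(gains), key(fx$truth$cnv_gains))
})
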