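test_that("the PIK3CA hotspot passes the cascade and boundary cases fail it", {
  hotspot <- variant_record("S03", chrom = "3", pos = 178952085, ref = "A",
                            alt = "G", gene = "PIK3CA",
                            consequence = "missense", vaf = 0.35,
                            depth = 500, popmax_af = 0,
                            hgvs_c = "c.3140A>G", hgvs_p = "p.His1047Arg")
  res <- classify_variant(hotspot)
  expect_equal(res$verdict, "driver")
  expect_length(res$rejection_reasons, 0)

  syn <- hotspot
  syn$consequence <- "synonymous"
  res <- classify_variant(syn)
  expect_equal(res$verdict, "rejected")
  expect_equal(res$rejection_reasons, "excluded_consequence")

  hi <- hotspot
  hi$vaf <- 0.95
  res <- classify_variant(hi)
  expect_equal(res$rejection_reasons, "vaf_out_of_range")

  # closed interval: both VAF endpoints are drivers
  for (vaf in c(0.05, 0.90)) {
    v <- hotspot
    v$vaf <- vaf
    expect_equal(classify_variant(v)$verdict, "driver")
  }
  # depth >= 40 inclusive; popmax < 0.01 strict
  lo <- hotspot
  lo$depth <- 40L
  expect_equal(classify_variant(lo)$verdict, "driver")
  pop <- hotspot
  pop$popmax_af <- 0.01
  expect_equal(classify_variant(pop)$rejection_reasons,
               "common_in_population")
})

test_that("every failing condition is recorded, in cascade order", {
  bad <- variant_record("S01", consequence = "intronic", vaf = 0.02,
                        depth = 10, popmax_af = 0.2, cgc_somatic = FALSE,
                        cosmic_pathogenic = FALSE, filter_status = "q30")
  res <- classify_variant(bad)
  expect_equal(res$rejection_reasons,
               c("not_pass", "excluded_consequence", "vaf_out_of_range",
                 "low_depth", "common_in_population", "not_cgc_somatic",
                 "not_cosmic_pathogenic"))
})

test_that("missing population frequency passes by default and is configurable", {
  v <- variant_record("S01", popmax_af = NA)
  expect_equal(classify_variant(v)$verdict, "driver")
  strict <- panel_thresholds(pass_missing_popmax = FALSE)
  expect_equal(classify_variant(v, strict)$rejection_reasons,
               "common_in_population")
})

test_that("triage matches an exhaustive independent re-evaluation", {
  cfg <- panel_thresholds()
  for (seed in c(1, 2, 3)) {
    v <- random_variants(200, seed = seed)
    tri <- triage_sample(v, cfg)
    oracle <- oracle_driver_flags(v, cfg)
    expect_equal(sum(tri$audit$verdict == "driver"), sum(oracle))
    key <- function(df) sort(paste(df$chrom, df$pos, df$alt, df$vaf))
    expect_equal(key(tri$drivers), key(v[oracle, ]))
    # audit is aligned with the input and consistent with the verdict
    expect_equal(tri$audit$verdict == "driver", oracle)
    expect_equal(tri$audit$rejection_reasons == "",
                 tri$audit$verdict == "driver")
  }
})

test_that("relaxing any single threshold never shrinks the driver set", {
  base <- panel_thresholds()
  relaxed <- list(
    panel_thresholds(vaf_min = 0.01),
    panel_thresholds(vaf_max = 0.99),
    panel_thresholds(depth_min = 5),
    panel_thresholds(popmax_af_max = 0.05)
  )
  for (seed in 11:13) {
    v <- random_variants(300, seed = seed)
    n0 <- nrow(triage_sample(v, base)$drivers)
    for (cfg in relaxed) {
      expect_gte(nrow(triage_sample(v, cfg)$drivers), n0)
    }
  }
})

test_that("triage is deterministic and order-invariant", {
  v <- random_variants(150, seed = 42)
  cfg <- panel_thresholds()
  a <- triage_sample(v, cfg)
  shuffled <- v[withr::with_seed(9, sample.int(nrow(v))), ]
  b <- triage_sample(shuffled, cfg)
  expect_identical(a$drivers, b$drivers)
  akey <- paste(a$audit$chrom, a$audit$pos, a$audit$alt,
                a$audit$rejection_reasons)
  bkey <- paste(b$audit$chrom, b$audit$pos, b$audit$alt,
                b$audit$rejection_reasons)
  expect_setequal(akey, bkey)
})

test_that("sample-level triage guards inputs and sorts drivers", {
  mixed <- rbind(variant_record("S01"), variant_record("S02"))
  expect_error(triage_sample(mixed), class = "oncopanel_input_error")
  empty <- variant_record("S01")[0, ]
  out <- triage_sample(empty)
  expect_equal(nrow(out$drivers), 0)
  expect_equal(nrow(out$audit), 0)
  v <- random_variants(80, seed = 5)
  drv <- triage_sample(v)$drivers
  expect_false(is.unsorted(order(drv$chrom, drv$pos)))
})

test_that("the fixture cohort yields a PIK3CA driver for its hotspot carrier", {
  fx <- fixture_cohort()
  s3 <- fx$variants[fx$variants$sample_id == "MBC03", ]
  drv <- triage_sample(s3)$drivers
  expect_true(any(drv$gene == "PIK3CA" & drv$hgvs_p == "p.His1047Arg"))
  # germline PALB2/BRCA variants never enter the somatic driver set
  s1 <- fx$variants[fx$variants$sample_id == "MBC01", ]
  expect_false(any(triage_sample(s1)$drivers$origin == "known_germline"))
})
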