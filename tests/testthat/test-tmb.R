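test_that("TMB eligibility counts coding variants and applies the exclusions", {
  syn <- variant_record("S01", consequence = "synonymous", vaf = 0.20,
                        depth = 200, popmax_af = 0, cgc_somatic = FALSE,
                        cosmic_pathogenic = FALSE)
  expect_equal(nrow(select_tmb_eligible(syn)), 1)

  hot <- variant_record("S01", cosmic_pathogenic = TRUE)
  expect_equal(nrow(select_tmb_eligible(hot)), 0)

  germ <- variant_record("S01", cgc_somatic = FALSE,
                         cosmic_pathogenic = FALSE,
                         origin = "known_germline", vaf = 0.48)
  expect_equal(nrow(select_tmb_eligible(germ)), 0)

  intronic <- variant_record("S01", consequence = "intronic",
                             cosmic_pathogenic = FALSE)
  expect_equal(nrow(select_tmb_eligible(intronic)), 0)

  # each exclusion is individually toggleable
  cfg <- panel_thresholds(tmb_exclude_hotspots = FALSE,
                          tmb_exclude_germline = FALSE,
                          tmb_include_synonymous = FALSE)
  expect_equal(nrow(select_tmb_eligible(hot, cfg)), 1)
  expect_equal(nrow(select_tmb_eligible(germ, cfg)), 1)
  expect_equal(nrow(select_tmb_eligible(syn, cfg)), 0)
})

test_that("TMB is eligible count over panel megabases with >= 10 high", {
  v <- do.call(rbind, lapply(1:24, function(i) {
    variant_record("S01", pos = 1000 + i, consequence = "missense",
                   vaf = 0.3, depth = 200, popmax_af = 0,
                   cgc_somatic = FALSE, cosmic_pathogenic = FALSE)
  }))
  res <- compute_tmb(v)
  expect_equal(res$eligible_count, 24L)
  expect_equal(res$tmb, 24 / 1.94)
  expect_equal(res$stratum, "high")

  empty <- compute_tmb(v[0, ])
  expect_equal(empty$tmb, 0)
  expect_equal(empty$stratum, "low")

  # the cutoff itself stratifies high; callable-region override works
  at_cutoff <- compute_tmb(v[1:20, ], callable_mb = 2)
  expect_equal(at_cutoff$tmb, 10)
  expect_equal(at_cutoff$stratum, "high")
  below <- compute_tmb(v[1:19, ], callable_mb = 2)
  expect_equal(below$stratum, "low")
})

test_that("TMB is linear in count, inverse in panel size, and ignores ineligible variants", {
  v <- do.call(rbind, lapply(1:12, function(i) {
    variant_record("S01", pos = 2000 + i, vaf = 0.3, depth = 150,
                   popmax_af = 0, cgc_somatic = FALSE,
                   cosmic_pathogenic = FALSE)
  }))
  t1 <- compute_tmb(v)
  t2 <- compute_tmb(rbind(v, transform(v, pos = pos + 1000)))
  expect_equal(t2$tmb, 2 * t1$tmb)
  half_panel <- panel_definition("TP53", character(0), target_size_mb = 0.97)
  expect_equal(compute_tmb(v, half_panel)$tmb, 2 * t1$tmb)

  ineligible <- rbind(
    variant_record("S01", pos = 9000, vaf = 0.02, cgc_somatic = FALSE,
                   cosmic_pathogenic = FALSE),
    variant_record("S01", pos = 9001, cosmic_pathogenic = TRUE),
    variant_record("S01", pos = 9002, filter_status = "q30",
                   cosmic_pathogenic = FALSE, cgc_somatic = FALSE)
  )
  expect_equal(compute_tmb(rbind(v, ineligible))$tmb, t1$tmb)
})

test_that("the fixture cohort has two TMB-high samples at the printed levels", {
  profs <- fixture_profiles()
  strata <- vapply(profs, function(p) p$tmb$stratum, "")
  expect_equal(sum(strata == "high"), 2L)
  expect_setequal(names(strata)[strata == "high"], c("MBC01", "MBC03"))
  expect_equal(profs$MBC01$tmb$tmb, 24 / 1.94)
  expect_equal(round(profs$MBC03$tmb$tmb, 1), 11.9)
  # eligible counts equal the implanted background counts
  fx <- fixture_cohort()
  counts <- vapply(profs, function(p) p$tmb$eligible_count, 0L)
  expect_equal(unname(counts), unname(fx$truth$tmb_eligible_count))
})
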