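test_that("the coverage gate controls assessment", {
  below <- assess_locus(msi_obs_row(coverage = 59L, off_fraction = 0.6))
  expect_false(below$assessed)
  expect_false(below$unstable)
  at_gate <- assess_locus(msi_obs_row(coverage = 60L, off_fraction = 0.6))
  expect_true(at_gate$assessed)
  expect_true(at_gate$unstable)
})

test_that("a histogram matching pure stutter is stable", {
  obs <- msi_obs_row(coverage = 100L, off_fraction = 0)
  b <- stutter_baseline(10L)
  counts <- round(100 * b)
  obs$histogram <- paste(sprintf("%s:%d", names(counts), counts),
                         collapse = ",")
  a <- assess_locus(obs)
  expect_true(a$assessed)
  expect_false(a$unstable)
  expect_lt(abs(a$shift_fraction), 0.05)
})

test_that("excess off-reference fraction beyond the threshold is unstable", {
  # observed off-reference 0.40 against baseline 0.05: excess 0.35 > 0.20
  obs <- msi_obs_row(coverage = 100L, off_fraction = 0.40)
  obs$baseline <- "9:0.05,10:0.95"
  a <- assess_locus(obs)
  expect_equal(a$shift_fraction, 0.35)
  expect_true(a$unstable)
  # same observation under a 0.5 threshold is stable
  lax <- panel_thresholds(locus_instability_threshold = 0.5)
  expect_false(assess_locus(obs, lax)$unstable)
})

test_that("the divergence-based locus test agrees on clear-cut cases", {
  cfg <- panel_thresholds(msi_locus_method = "jsd")
  shifted <- msi_obs_row(coverage = 200L, off_fraction = 0.5)
  expect_true(assess_locus(shifted, cfg)$unstable)
  b <- stutter_baseline(10L)
  counts <- round(200 * b)
  clean <- msi_obs_row(coverage = 200L)
  clean$histogram <- paste(sprintf("%s:%d", names(counts), counts),
                           collapse = ",")
  expect_false(assess_locus(clean, cfg)$unstable)
})

test_that("MSI percentage, strata and the not-evaluable state follow the counts", {
  mk <- function(n_unstable, n_assessed, n_below = 0) {
    rows <- list()
    for (i in seq_len(n_assessed)) {
      rows[[i]] <- msi_obs_row(locus_id = sprintf("L%03d", i),
                               coverage = 100L,
                               off_fraction = if (i <= n_unstable) 0.5 else 0)
    }
    for (j in seq_len(n_below)) {
      rows[[n_assessed + j]] <- msi_obs_row(
        locus_id = sprintf("LB%03d", j), coverage = 40L, off_fraction = 0.5)
    }
    do.call(rbind, rows)
  }
  res <- compute_msi(assess_msi_loci(mk(22, 125)))
  expect_equal(res$msi_percent, 17.6)
  expect_equal(res$stratum, "high")

  res <- compute_msi(assess_msi_loci(mk(0, 125)))
  expect_equal(res$msi_percent, 0)
  expect_equal(res$stratum, "stable")

  res <- compute_msi(assess_msi_loci(mk(3, 120)))
  expect_equal(res$msi_percent, 2.5)
  expect_equal(res$stratum, "low")

  # sub-gate loci do not enter the denominator
  res <- compute_msi(assess_msi_loci(mk(3, 120, n_below = 30)))
  expect_equal(res$n_assessed, 120L)
  expect_equal(res$msi_percent, 2.5)

  ne <- compute_msi(assess_msi_loci(mk(0, 0, n_below = 5)))
  expect_false(ne$evaluable)
  expect_true(is.na(ne$msi_percent))
  expect_true(is.na(ne$stratum))
})

test_that("MSI is order-invariant and unaffected by unassessed loci", {
  rows <- do.call(rbind, lapply(1:40, function(i) {
    msi_obs_row(locus_id = sprintf("L%03d", i), coverage = 100L,
                off_fraction = if (i <= 6) 0.5 else 0)
  }))
  base <- compute_msi(assess_msi_loci(rows))
  shuffled <- rows[withr::with_seed(3, sample.int(nrow(rows))), ]
  expect_equal(compute_msi(assess_msi_loci(shuffled)), base)
  extra <- rbind(rows, msi_obs_row(locus_id = "LX", coverage = 10L,
                                   off_fraction = 0.9))
  expect_equal(compute_msi(assess_msi_loci(extra))$msi_percent,
               base$msi_percent)
})

test_that("strata partition: stable excludes high, high/low split at the cutoff", {
  cfg <- panel_thresholds()
  for (n_unst in c(0, 1, 11, 12, 13, 60)) {
    rows <- do.call(rbind, lapply(1:120, function(i) {
      msi_obs_row(locus_id = sprintf("L%03d", i), coverage = 80L,
                  off_fraction = if (i <= n_unst) 0.5 else 0)
    }))
    res <- compute_msi(assess_msi_loci(rows), cfg)
    expect_equal(res$n_unstable, n_unst)
    if (n_unst == 0) {
      expect_equal(res$stratum, "stable")
    } else if (100 * n_unst / 120 >= cfg$msi_high_pct) {
      expect_equal(res$stratum, "high")
    } else {
      expect_equal(res$stratum, "low")
    }
  }
})

test_that("the fixture cohort reproduces the published MSI pattern", {
  profs <- fixture_profiles()
  strata <- vapply(profs, function(p) p$msi$stratum, "")
  expect_false(profs$MBC01$msi$evaluable)
  expect_equal(profs$MBC02$msi$msi_percent, 17.6)
  expect_equal(profs$MBC08$msi$n_assessed, 119L)
  expect_equal(round(profs$MBC08$msi$msi_percent, 1), 14.3)
  expect_equal(sum(strata == "high", na.rm = TRUE), 2L)
  evaluable <- vapply(profs, function(p) p$msi$evaluable, NA)
  pcts <- vapply(profs, function(p) p$msi$msi_percent, 0)[evaluable]
  expect_equal(median(pcts), 2.4)
  expect_equal(range(pcts), c(0, 17.6))
})
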