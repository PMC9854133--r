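test_that("the same seed produces byte-identical cohort files", {
  cfg <- sim_config(n_samples = 4, seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("simulated output parses cleanly through the readers", {
  cfg <- sim_config(n_samples = 3, seed = 7)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, out_dir = dir)
  back <- read_cohort_dir(dir)
  expect_equal(back$variants, sim$variants[order(sim$variants$sample_id), ],
               ignore_attr = TRUE)
  expect_equal(back$cnv, sim$cnv)
  expect_equal(back$msi, sim$msi)
  expect_equal(back$meta, sim$meta)
})

test_that("noise-free simulation recovers exactly the implanted drivers", {
  cfg <- sim_config(n_samples = 6, seed = 11, drivers_range = c(3L, 3L),
                    artifact_rate = 0)
  sim <- simulate_cohort(cfg)
  for (sid in sim$meta$sample_id) {
    v <- sim$variants[sim$variants$sample_id == sid, ]
    drv <- triage_sample(v)$drivers
    expect_equal(nrow(drv), 3)
    key <- function(df) sort(paste(df$chrom, df$pos, df$alt))
    expect_equal(key(drv), key(sim$truth$drivers[[sid]]))
  }
})

test_that("default artifacts sit below the VAF floor; stress mode contaminates", {
  cfg <- sim_config(n_samples = 6, seed = 21, artifact_rate = 6)
  sim <- simulate_cohort(cfg)
  arts <- do.call(rbind, sim$truth$artifacts)
  expect_gt(nrow(arts), 0)
  expect_true(all(arts$vaf < 0.05))
  stress <- simulate_cohort(sim_config(n_samples = 6, seed = 21,
                                       artifact_rate = 6,
                                       artifact_stress = TRUE))
  sarts <- do.call(rbind, stress$truth$artifacts)
  expect_true(all(sarts$vaf >= 0.05))
  # contamination: stressed artifacts pass triage
  sid <- sarts$sample_id[1]
  drv <- triage_sample(
    stress$variants[stress$variants$sample_id == sid, ])$drivers
  expect_gt(nrow(drv), nrow(stress$truth$drivers[[sid]]))
})

test_that("disabling MSI-high simulation leaves no high stratum", {
  cfg <- sim_config(n_samples = 8, seed = 31, msi_high_fraction = 0)
  sim <- simulate_cohort(cfg)
  for (sid in sim$meta$sample_id) {
    res <- compute_msi(assess_msi_loci(
      sim$msi[sim$msi$sample_id == sid, ]))
    if (res$evaluable) expect_true(res$stratum %in% c("stable", "low"))
  }
})

test_that("driver VAFs track tumor cellularity", {
  sim <- simulate_cohort(sim_config(n_samples = 20, seed = 41,
                                    drivers_range = c(5L, 5L)))
  diffs <- unlist(lapply(sim$meta$sample_id, function(sid) {
    sim$truth$drivers[[sid]]$vaf - sim$truth$cellularity[[sid]] / 2
  }))
  se <- 0.03 / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("invalid simulation configs fail before generating anything", {
  expect_error(sim_config(germline_carrier_fraction = 1.2),
               class = "oncopanel_input_error")
  expect_error(sim_config(n_samples = 0), class = "oncopanel_input_error")
  expect_error(sim_config(msi_high_fraction = 0.8,
                          msi_stable_fraction = 0.5),
               class = "oncopanel_input_error")
})
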