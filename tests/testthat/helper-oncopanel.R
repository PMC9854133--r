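# Shared test fixtures and an independent re-statement of the driver
# predicate used as oracle.

# Random annotated variants exercising every filter dimension.
random_variants <- function(n, seed, sample_id = "S01") {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    variant_record(
      sample_id = sample_id,
      chrom = sample(c(as.character(1:22), "X"), n, replace = TRUE),
      pos = sample.int(5e7, n),
      ref = ref, alt = alt,
      gene = sample(c("PIK3CA", "TP53", "GATA3", "MAP3K1", "BRCA2"), n,
                    replace = TRUE),
      consequence = sample(c("missense", "synonymous", "stop_gained",
                             "frameshift", "inframe_indel", "splice_site",
                             "intronic", "other"), n, replace = TRUE),
      vaf = round(runif(n), 3),
      depth = sample.int(600, n),
      popmax_af = ifelse(runif(n) < 0.4, NA_real_,
                         round(runif(n, 0, 0.05), 4)),
      cgc_somatic = runif(n) < 0.6,
      cosmic_pathogenic = runif(n) < 0.6,
      filter_status = sample(c("PASS", "q30", "LowDP"), n, replace = TRUE,
                             prob = c(0.7, 0.15, 0.15)),
      origin = "somatic_candidate"
    )
  })
}

# Independent per-record re-statement of the driver predicate (plain
# if-chains, no shared code with the vectorized implementation).
oracle_is_driver <- function(v, cfg) {
  if (v$filter_status != "PASS") return(FALSE)
  ok_csq <- v$consequence == "missense" || v$consequence == "stop_gained" ||
    v$consequence == "frameshift" || v$consequence == "inframe_indel" ||
    v$consequence == "splice_site"
  if (!ok_csq) return(FALSE)
  if (v$vaf < cfg$vaf_min || v$vaf > cfg$vaf_max) return(FALSE)
  if (v$depth < cfg$depth_min) return(FALSE)
  if (is.na(v$popmax_af)) {
    if (!cfg$pass_missing_popmax) return(FALSE)
  } else if (v$popmax_af >= cfg$popmax_af_max) {
    return(FALSE)
  }
  if (!v$cgc_somatic) return(FALSE)
  if (!v$cosmic_pathogenic) return(FALSE)
  TRUE
}

oracle_driver_flags <- function(variants, cfg) {
  vapply(seq_len(nrow(variants)),
         function(i) oracle_is_driver(variants[i, ], cfg), NA)
}

# Cached reference cohort, profiled once per test run.
fixture_env <- new.env()

fixture_cohort <- function() {
  if (is.null(fixture_env$cohort)) fixture_env$cohort <- mbc_cohort_fixture()
  fixture_env$cohort
}

fixture_profiles <- function() {
  if (is.null(fixture_env$profiles)) {
    fx <- fixture_cohort()
    fixture_env$profiles <- profile_cohort(fx$variants, fx$meta, fx$cnv,
                                           fx$msi)
  }
  fixture_env$profiles
}

fixture_summary <- function() {
  if (is.null(fixture_env$summary)) {
    fixture_env$summary <- summarize_cohort(fixture_profiles())
  }
  fixture_env$summary
}

# Independent "length:value" pair parser for checking files and tables.
parse_pairs <- function(s) {
  kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  vapply(kv, `[`, "", 1))
}

# One MSI observation row with an explicit off-reference read fraction.
msi_obs_row <- function(sample_id = "S01", locus_id = "L1", ref_len = 10L,
                        coverage = 100L, off_fraction = 0) {
  b <- stutter_baseline(ref_len)
  off <- round(coverage * off_fraction)
  h <- c(off, coverage - off)
  names(h) <- c(ref_len - 1L, ref_len)
  data.frame(sample_id = sample_id, locus_id = locus_id, ref_len = ref_len,
             histogram = paste(sprintf("%s:%d", names(h), h), collapse = ","),
             baseline = paste(sprintf("%s:%s", names(b), b), collapse = ","),
             stringsAsFactors = FALSE)
}
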