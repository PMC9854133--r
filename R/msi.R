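# Microsatellite instability from homopolymer-locus read-length
# histograms.
#
# Each locus contributes a histogram of read repeat lengths plus a
# baseline of expected proportions under pure polymerase stutter. A locus
# is assessed only when its coverage reaches the gate (default 60 reads).
# The default per-locus instability statistic is the excess off-reference
# read fraction: observed fraction of reads at lengths different from the
# reference repeat length, minus the baseline expectation; the locus is
# unstable when the excess exceeds a fixed threshold (default 0.20). A
# Jensen-Shannon divergence statistic against the baseline distribution
# is available behind the same interface.
#
# The sample-level MSI value is 100 * unstable / assessed; >= 10% is
# stratified high, zero unstable loci is "stable", and a sample with no
# assessable locus is not evaluable.

# Jensen-Shannon divergence (base-2, in [0,1]) between two histograms
# given as named vectors keyed by repeat length.
js_divergence <- function(p, q) {
  lens <- union(names(p), names(q))
  pv <- stats::setNames(numeric(length(lens)), lens)
  qv <- pv
  pv[names(p)] <- p / sum(p)
  qv[names(q)] <- q / sum(q)
  m <- (pv + qv) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(pv, m) + kl(qv, m)) / 2
}

#' Assess the stability of one homopolymer locus
#'
#' @param obs a one-row MSI observation (see [read_msi_table()]):
#'   `sample_id`, `locus_id`, `ref_len`, `histogram`, `baseline`.
#' @param cfg a [panel_thresholds()] configuration; `msi_min_coverage`
#'   gates assessment, `msi_locus_method` selects the statistic
#'   (`"excess"` or `"jsd"`) and `locus_instability_threshold` /
#'   `msi_jsd_threshold` its cutoff.
#' @return a list: `locus_id`, `coverage`, `assessed`, `unstable`,
#'   `shift_fraction` (the excess off-reference fraction; for the JSD
#'   method, the divergence).
#' @export
assess_locus <- function(obs, cfg = panel_thresholds()) {
  h <- parse_hist(obs$histogram)
  if (any(h < 0)) stop_input("negative read count at locus %s", obs$locus_id)
  b <- parse_hist(obs$baseline)
  coverage <- sum(h)
  assessed <- coverage >= cfg$msi_min_coverage
  ref <- as.character(obs$ref_len)
  off_obs <- if (coverage > 0) sum(h[names(h) != ref]) / coverage else 0
  off_base <- sum(b[names(b) != ref])
  stat <- switch(cfg$msi_locus_method,
                 excess = off_obs - off_base,
                 jsd = if (coverage > 0) js_divergence(h, b) else 0)
  cutoff <- switch(cfg$msi_locus_method,
                   excess = cfg$locus_instability_threshold,
                   jsd = cfg$msi_jsd_threshold)
  list(locus_id = obs$locus_id,
       coverage = coverage,
       assessed = assessed,
       unstable = assessed && stat > cutoff,
       shift_fraction = stat)
}

#' Assess all loci of a sample
#'
#' Vectorized [assess_locus()] over an observation table.
#'
#' @param observations an MSI observation table for one sample.
#' @param cfg a [panel_thresholds()] configuration.
#' @return a data.frame with columns `sample_id`, `locus_id`, `coverage`,
#'   `assessed`, `unstable`, `shift_fraction`.
#' @export
assess_msi_loci <- function(observations, cfg = panel_thresholds()) {
  rows <- lapply(seq_len(nrow(observations)), function(i) {
    a <- assess_locus(observations[i, ], cfg)
    data.frame(sample_id = observations$sample_id[i],
               locus_id = a$locus_id, coverage = a$coverage,
               assessed = a$assessed, unstable = a$unstable,
               shift_fraction = a$shift_fraction, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(sample_id = character(), locus_id = character(),
                      coverage = numeric(), assessed = logical(),
                      unstable = logical(), shift_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Compute the sample-level MSI result
#'
#' The MSI percentage is 100 times the number of unstable loci divided by
#' the number of assessed loci. Samples at or above `cfg$msi_high_pct`
#' (default 10%) are stratified `high`; samples with zero unstable loci
#' are `stable`; anything between is `low`. A sample with no assessed
#' locus is flagged not evaluable (`NA` percentage and stratum).
#'
#' @param assessments output of [assess_msi_loci()] for one sample.
#' @param cfg a [panel_thresholds()] configuration.
#' @return an object of class `msi_result`: `sample_id`, `n_assessed`,
#'   `n_unstable`, `msi_percent`, `stratum` (`high` / `low` / `stable` /
#'   `NA`), `evaluable`.
#' @export
compute_msi <- function(assessments, cfg = panel_thresholds()) {
  sid <- unique(assessments$sample_id)
  if (length(sid) > 1L) stop_input("compute_msi expects one sample")
  n_assessed <- sum(assessments$assessed)
  n_unstable <- sum(assessments$unstable & assessments$assessed)
  if (n_assessed == 0L) {
    res <- list(sample_id = if (length(sid)) sid else NA_character_,
                n_assessed = 0L, n_unstable = 0L,
                msi_percent = NA_real_, stratum = NA_character_,
                evaluable = FALSE)
    return(structure(res, class = "msi_result"))
  }
  pct <- 100 * n_unstable / n_assessed
  stratum <- if (n_unstable == 0L) "stable" else
    if (pct >= cfg$msi_high_pct) "high" else "low"
  structure(list(sample_id = if (length(sid)) sid else NA_character_,
                 n_assessed = as.integer(n_assessed),
                 n_unstable = as.integer(n_unstable),
                 msi_percent = pct, stratum = stratum, evaluable = TRUE),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("MSI [%s]: not evaluable (no locus at coverage gate)\n",
                x$sample_id))
  } else {
    cat(sprintf("MSI [%s]: %d unstable / %d assessed = %.1f%% (%s)\n",
                x$sample_id, x$n_unstable, x$n_assessed, x$msi_percent,
                x$stratum))
  }
  invisible(x)
}
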