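# Tumor mutational burden: eligible somatic mutations per megabase of
# captured genome, stratified high/low at a conventional cutoff
# (default 10 mut/Mb, inclusive).
#
# Eligibility follows the convention of large commercial panels: PASS
# coding variants (including synonymous) within the quality gates, with
# database hotspots (COSMIC-pathogenic) and known germline variants
# excluded so that recurrently selected drivers and inherited variants do
# not inflate the mutation count. Every exclusion is individually
# toggleable in the threshold configuration.

#' Select the variants eligible for TMB calculation
#'
#' @param variants a variant table for one sample.
#' @param cfg a [panel_thresholds()] configuration; the relevant switches
#'   are `tmb_include_synonymous`, `tmb_exclude_hotspots`,
#'   `tmb_exclude_germline` plus the `vaf_min`, `depth_min` and
#'   `popmax_af_max` gates shared with triage.
#' @return the eligible subset of `variants`.
#' @export
select_tmb_eligible <- function(variants, cfg = panel_thresholds()) {
  variants <- validate_variants(variants)
  coding <- if (cfg$tmb_include_synonymous) CODING_CONSEQUENCES else
    DRIVER_CONSEQUENCES
  keep <- variants$filter_status == "PASS" &
    variants$consequence %in% coding &
    variants$vaf >= cfg$vaf_min &
    variants$depth >= cfg$depth_min
  pop_known <- !is.na(variants$popmax_af)
  pop_ok <- (pop_known & variants$popmax_af < cfg$popmax_af_max) |
    (!pop_known & cfg$pass_missing_popmax)
  keep <- keep & pop_ok
  if (cfg$tmb_exclude_hotspots) keep <- keep & !variants$cosmic_pathogenic
  if (cfg$tmb_exclude_germline) {
    keep <- keep & !(variants$origin %in% "known_germline")
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute tumor mutational burden for one sample
#'
#' TMB is the eligible variant count divided by the megabases of captured
#' genome; samples at or above `cfg$tmb_high_cutoff` (default 10 mut/Mb)
#' are stratified high.
#'
#' @param variants a variant table for one sample.
#' @param panel a [panel_definition()]; `panel$target_size_mb` is the
#'   default denominator.
#' @param cfg a [panel_thresholds()] configuration.
#' @param callable_mb optional per-sample callable-region override of the
#'   denominator, in megabases.
#' @return an object of class `tmb_result`: `sample_id`, `eligible_count`,
#'   `panel_mb`, `tmb` (mut/Mb), `stratum` (`"high"` or `"low"`).
#' @export
compute_tmb <- function(variants, panel = default_panel(),
                        cfg = panel_thresholds(), callable_mb = NULL) {
  variants <- validate_variants(variants)
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L) stop_input("compute_tmb expects one sample")
  mb <- callable_mb %||% panel$target_size_mb
  if (!is.numeric(mb) || mb <= 0) stop_input("panel size must be positive")
  eligible <- select_tmb_eligible(variants, cfg)
  n <- nrow(eligible)
  tmb <- n / mb
  structure(list(
    sample_id = if (length(sid)) sid else NA_character_,
    eligible_count = n,
    panel_mb = mb,
    tmb = tmb,
    stratum = if (tmb >= cfg$tmb_high_cutoff) "high" else "low"
  ), class = "tmb_result")
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB [%s]: %d eligible variants / %.2f Mb = %.2f mut/Mb (%s)\n",
              x$sample_id, x$eligible_count, x$panel_mb, x$tmb, x$stratum))
  invisible(x)
}
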