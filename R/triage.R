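# Pathogenic (driver) somatic variant triage.
#
# A variant is nominated as a driver when ALL of the following hold:
#   * caller FILTER is PASS;
#   * consequence is exonic non-synonymous (missense, stop_gained,
#     frameshift, inframe_indel) or splice_site;
#   * allele fraction lies in the closed window [vaf_min, vaf_max]
#     (defaults 5%-90%: below sits FFPE artifact noise, above sits
#     likely-germline homozygosity);
#   * total read depth >= depth_min (default 40);
#   * global population allele frequency < popmax_af_max (default 0.01;
#     a missing frequency passes by default -- rare somatic hotspots are
#     typically absent from population databases);
#   * flagged somatic in the Cancer Gene Census AND pathogenic in COSMIC.
#
# Every failing condition is recorded (no short-circuit), so the audit
# trail lists all reasons a call was rejected.

#' Triage a single annotated variant
#'
#' Applies the driver filter cascade to one variant and returns the
#' verdict together with every failed condition.
#'
#' @param v a one-row variant table (see [variant_record()]).
#' @param cfg a [panel_thresholds()] configuration.
#' @return a list with elements `variant` (the input row), `verdict`
#'   (`"driver"` or `"rejected"`) and `rejection_reasons` (character
#'   vector, empty iff driver, ordered as
#'   `not_pass`, `excluded_consequence`, `vaf_out_of_range`, `low_depth`,
#'   `common_in_population`, `not_cgc_somatic`, `not_cosmic_pathogenic`).
#' @export
classify_variant <- function(v, cfg = panel_thresholds()) {
  v <- validate_variants(as.data.frame(v, stringsAsFactors = FALSE))
  if (nrow(v) != 1L) stop_input("classify_variant expects exactly one variant")
  audit <- triage_audit(v, cfg)
  reasons <- strsplit(audit$rejection_reasons, ",", fixed = TRUE)[[1]]
  list(variant = v, verdict = audit$verdict,
       rejection_reasons = reasons[nzchar(reasons)])
}

# Vectorized evaluation of the cascade; returns verdict + comma-joined
# ordered rejection reasons per row.
triage_audit <- function(variants, cfg) {
  n <- nrow(variants)
  fail <- matrix(FALSE, nrow = n, ncol = length(REJECTION_REASONS),
                 dimnames = list(NULL, REJECTION_REASONS))
  fail[, "not_pass"] <- variants$filter_status != "PASS"
  fail[, "excluded_consequence"] <- !variants$consequence %in% DRIVER_CONSEQUENCES
  fail[, "vaf_out_of_range"] <-
    variants$vaf < cfg$vaf_min | variants$vaf > cfg$vaf_max
  fail[, "low_depth"] <- variants$depth < cfg$depth_min
  pop_known <- !is.na(variants$popmax_af)
  common <- pop_known & variants$popmax_af >= cfg$popmax_af_max
  if (!cfg$pass_missing_popmax) common <- common | !pop_known
  fail[, "common_in_population"] <- common
  fail[, "not_cgc_somatic"] <- !variants$cgc_somatic
  fail[, "not_cosmic_pathogenic"] <- !variants$cosmic_pathogenic
  reasons <- apply(fail, 1L, function(f) {
    paste(REJECTION_REASONS[f], collapse = ",")
  })
  if (!n) reasons <- character(0)
  data.frame(
    sample_id = variants$sample_id, chrom = variants$chrom,
    pos = variants$pos, ref = variants$ref, alt = variants$alt,
    gene = variants$gene,
    verdict = ifelse(nzchar(reasons), "rejected", "driver"),
    rejection_reasons = reasons,
    stringsAsFactors = FALSE
  )
}

#' Triage all variants of one sample
#'
#' Runs [classify_variant()]'s cascade over a sample's calls and splits
#' them into the nominated driver set and a full audit trail.
#'
#' @param variants a variant table for a single sample.
#' @param cfg a [panel_thresholds()] configuration.
#' @return a list with `drivers` (variant table sorted by chromosome and
#'   position) and `audit` (one row per input variant with `verdict` and
#'   comma-joined `rejection_reasons`).
#' @export
triage_sample <- function(variants, cfg = panel_thresholds()) {
  variants <- validate_variants(variants)
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L) {
    stop_input("triage_sample expects one sample, got: %s",
               paste(sid, collapse = ", "))
  }
  audit <- triage_audit(variants, cfg)
  drivers <- variants[audit$verdict == "driver", , drop = FALSE]
  drivers <- drivers[order(drivers$chrom, drivers$pos, drivers$alt), ,
                     drop = FALSE]
  rownames(drivers) <- NULL
  list(drivers = drivers, audit = audit)
}
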