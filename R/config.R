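#' Threshold configuration for the profiling pipeline
#'
#' Collects every numeric cutoff the pipeline applies, with the defaults
#' used throughout: somatic drivers are PASS exonic (non-synonymous) or
#' splice-site variants with allele fraction in \[`vaf_min`, `vaf_max`\],
#' depth at least `depth_min` and population allele frequency below
#' `popmax_af_max`; LOH is tumor VAF strictly above `loh_vaf`; copy-number
#' gains/losses at fold-change `>= cnv_gain_fc` / `<= cnv_loss_fc`; TMB is
#' stratified high at `>= tmb_high_cutoff` mutations per megabase; MSI is
#' stratified high at `>= msi_high_pct` percent unstable loci among loci
#' covered by at least `msi_min_coverage` reads.
#'
#' @param vaf_min,vaf_max closed allele-fraction window for driver triage
#'   (defaults 0.05 and 0.90).
#' @param depth_min minimum total read depth (default 40, inclusive).
#' @param popmax_af_max strict upper bound on global population allele
#'   frequency (default 0.01).
#' @param pass_missing_popmax logical; should a variant with no population
#'   frequency annotation pass the population filter? Default `TRUE`
#'   (absent from population databases is taken as rare).
#' @param loh_vaf tumor allele fraction strictly above which a germline
#'   variant is called LOH (default 0.50).
#' @param cnv_gain_fc,cnv_loss_fc fold-change thresholds for copy-number
#'   gain (`>=`, default 1.5) and loss (`<=`, default 0.5).
#' @param tmb_high_cutoff mutations-per-megabase cutoff for TMB-high
#'   (default 10, inclusive).
#' @param tmb_include_synonymous,tmb_exclude_hotspots,tmb_exclude_germline
#'   toggles of the TMB eligibility rule set: count synonymous coding
#'   variants (default `TRUE`), exclude database hotspot
#'   (COSMIC-pathogenic) variants (default `TRUE`), exclude known germline
#'   variants (default `TRUE`).
#' @param msi_high_pct percent-unstable cutoff for MSI-high (default 10,
#'   inclusive).
#' @param msi_min_coverage minimum reads for a microsatellite locus to be
#'   assessed (default 60, inclusive).
#' @param locus_instability_threshold a locus is unstable when its
#'   off-reference read fraction exceeds the baseline expectation by more
#'   than this (default 0.20).
#' @param msi_locus_method per-locus instability statistic: `"excess"`
#'   (off-reference fraction minus baseline, the default) or `"jsd"`
#'   (Jensen-Shannon divergence between observed and baseline length
#'   distributions).
#' @param msi_jsd_threshold divergence cutoff used when
#'   `msi_locus_method = "jsd"` (default 0.10).
#' @return an object of class `panel_thresholds` (a named list).
#' @seealso [read_thresholds()], [write_thresholds()]
#' @export
panel_thresholds <- function(vaf_min = 0.05,
                             vaf_max = 0.90,
                             depth_min = 40,
                             popmax_af_max = 0.01,
                             pass_missing_popmax = TRUE,
                             loh_vaf = 0.50,
                             cnv_gain_fc = 1.5,
                             cnv_loss_fc = 0.5,
                             tmb_high_cutoff = 10,
                             tmb_include_synonymous = TRUE,
                             tmb_exclude_hotspots = TRUE,
                             tmb_exclude_germline = TRUE,
                             msi_high_pct = 10.0,
                             msi_min_coverage = 60,
                             locus_instability_threshold = 0.20,
                             msi_locus_method = c("excess", "jsd"),
                             msi_jsd_threshold = 0.10) {
  msi_locus_method <- match.arg(msi_locus_method)
  cfg <- list(vaf_min = vaf_min, vaf_max = vaf_max, depth_min = depth_min,
              popmax_af_max = popmax_af_max,
              pass_missing_popmax = isTRUE(pass_missing_popmax),
              loh_vaf = loh_vaf,
              cnv_gain_fc = cnv_gain_fc, cnv_loss_fc = cnv_loss_fc,
              tmb_high_cutoff = tmb_high_cutoff,
              tmb_include_synonymous = isTRUE(tmb_include_synonymous),
              tmb_exclude_hotspots = isTRUE(tmb_exclude_hotspots),
              tmb_exclude_germline = isTRUE(tmb_exclude_germline),
              msi_high_pct = msi_high_pct,
              msi_min_coverage = msi_min_coverage,
              locus_instability_threshold = locus_instability_threshold,
              msi_locus_method = msi_locus_method,
              msi_jsd_threshold = msi_jsd_threshold)
  validate_thresholds(cfg)
  structure(cfg, class = "panel_thresholds")
}

validate_thresholds <- function(cfg) {
  num <- c("vaf_min", "vaf_max", "depth_min", "popmax_af_max", "loh_vaf",
           "cnv_gain_fc", "cnv_loss_fc", "tmb_high_cutoff", "msi_high_pct",
           "msi_min_coverage", "locus_instability_threshold",
           "msi_jsd_threshold")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop_input("threshold '%s' must be a single number", f)
    }
  }
  if (!(cfg$vaf_min >= 0 && cfg$vaf_min < cfg$vaf_max && cfg$vaf_max <= 1)) {
    stop_input("need 0 <= vaf_min < vaf_max <= 1")
  }
  pos <- c("depth_min", "popmax_af_max", "cnv_gain_fc", "cnv_loss_fc",
           "tmb_high_cutoff", "msi_high_pct", "msi_min_coverage",
           "locus_instability_threshold")
  for (f in pos) {
    if (cfg[[f]] <= 0) stop_input("threshold '%s' must be positive", f)
  }
  if (cfg$cnv_loss_fc >= cfg$cnv_gain_fc) {
    stop_input("need cnv_loss_fc < cnv_gain_fc")
  }
  if (cfg$loh_vaf < 0 || cfg$loh_vaf > 1) stop_input("loh_vaf must be in [0,1]")
  invisible(cfg)
}

#' @export
print.panel_thresholds <- function(x, ...) {
  cat("Panel thresholds\n")
  cat(sprintf("  driver VAF window   [%.2f, %.2f], depth >= %g, popmax < %g%s\n",
              x$vaf_min, x$vaf_max, x$depth_min, x$popmax_af_max,
              if (x$pass_missing_popmax) " (missing passes)" else ""))
  cat(sprintf("  LOH at tumor VAF    > %.2f\n", x$loh_vaf))
  cat(sprintf("  CNV gain/loss       fc >= %.2f / fc <= %.2f\n",
              x$cnv_gain_fc, x$cnv_loss_fc))
  cat(sprintf("  TMB high            >= %g mut/Mb\n", x$tmb_high_cutoff))
  cat(sprintf("  MSI high            >= %g%% unstable, coverage >= %g, %s test\n",
              x$msi_high_pct, x$msi_min_coverage, x$msi_locus_method))
  invisible(x)
}

#' Read or write a threshold configuration as YAML
#'
#' `write_thresholds()` serializes a [panel_thresholds()] object to YAML;
#' `read_thresholds()` reads one back, filling unspecified fields with the
#' defaults. The round trip is lossless.
#'
#' @param cfg a `panel_thresholds` object.
#' @param path file path.
#' @return `read_thresholds()` returns a `panel_thresholds` object;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(panel_thresholds))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_schema("unknown threshold field(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(panel_thresholds, vals)
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(cfg, path) {
  stopifnot(inherits(cfg, "panel_thresholds"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
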