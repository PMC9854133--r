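# Per-sample profiling: one call that runs triage, LOH, CNV
# classification, TMB, MSI and actionability for a sample and bundles the
# results.

#' Profile one sample
#'
#' Runs the full post-calling pipeline for a single sample: driver
#' triage over the annotated variants, LOH evaluation at declared
#' germline variants, copy-number classification, TMB, MSI and
#' knowledge-base actionability annotation.
#'
#' @param sample_id the sample to profile.
#' @param variants annotated variant table (may contain other samples;
#'   rows are subset by `sample_id`).
#' @param meta metadata table containing the sample's row.
#' @param cnv_calls CNV fold-change table (may be empty).
#' @param msi_obs MSI locus observation table (may be empty).
#' @param panel a [panel_definition()].
#' @param cfg a [panel_thresholds()] configuration.
#' @param kb a knowledge base from [load_kb()].
#' @return an object of class `sample_profile` with elements `sample_id`,
#'   `meta` (one row), `drivers`, `audit`, `loh`, `cnv` (classified
#'   calls), `tmb` (`tmb_result`), `msi` (`msi_result`) and `findings`
#'   (actionable findings).
#' @export
profile_sample <- function(sample_id, variants, meta,
                           cnv_calls = NULL, msi_obs = NULL,
                           panel = default_panel(),
                           cfg = panel_thresholds(), kb = load_kb()) {
  mrow <- meta[meta$sample_id == sample_id, , drop = FALSE]
  if (nrow(mrow) != 1L) {
    stop_input("expected exactly one metadata row for sample '%s', found %d",
               sample_id, nrow(mrow))
  }
  sv <- validate_variants(variants)
  sv <- sv[sv$sample_id == sample_id, , drop = FALSE]
  tri <- triage_sample(sv, cfg)
  loh <- evaluate_loh(mrow, sv, cfg)
  cnv <- if (!is.null(cnv_calls) && nrow(cnv_calls)) {
    classify_cnv(cnv_calls[cnv_calls$sample_id == sample_id, , drop = FALSE],
                 panel, cfg)
  } else {
    classify_cnv(data.frame(sample_id = character(), gene = character(),
                            fold_change = numeric(),
                            cytoband = character(),
                            stringsAsFactors = FALSE), panel, cfg)
  }
  tmb <- compute_tmb(sv, panel, cfg)
  tmb$sample_id <- sample_id
  msi_rows <- if (!is.null(msi_obs) && nrow(msi_obs)) {
    msi_obs[msi_obs$sample_id == sample_id, , drop = FALSE]
  } else {
    msi_obs[0, ]
  }
  msi <- if (!is.null(msi_rows) && nrow(msi_rows)) {
    compute_msi(assess_msi_loci(msi_rows, cfg), cfg)
  } else {
    compute_msi(data.frame(sample_id = sample_id, locus_id = character(0),
                           coverage = numeric(0), assessed = logical(0),
                           unstable = logical(0),
                           shift_fraction = numeric(0))[0, ], cfg)
  }
  msi$sample_id <- sample_id
  prof <- structure(list(sample_id = sample_id, meta = mrow,
                         drivers = tri$drivers, audit = tri$audit,
                         loh = loh, cnv = cnv, tmb = tmb, msi = msi,
                         findings = NULL),
                    class = "sample_profile")
  prof$findings <- annotate_sample(prof, kb)
  prof
}

#' Profile every sample of a cohort
#'
#' @param variants,cnv_calls,msi_obs,meta cohort-level input tables; one
#'   profile is built per metadata row.
#' @param panel,cfg,kb as in [profile_sample()].
#' @return a named list of `sample_profile` objects.
#' @export
profile_cohort <- function(variants, meta, cnv_calls = NULL, msi_obs = NULL,
                           panel = default_panel(),
                           cfg = panel_thresholds(), kb = load_kb()) {
  if (anyDuplicated(meta$sample_id)) {
    stop_input("duplicate sample_id in metadata: %s",
               meta$sample_id[duplicated(meta$sample_id)][1])
  }
  profs <- lapply(meta$sample_id, profile_sample, variants = variants,
                  meta = meta, cnv_calls = cnv_calls, msi_obs = msi_obs,
                  panel = panel, cfg = cfg, kb = kb)
  stats::setNames(profs, meta$sample_id)
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("Sample profile: %s\n", x$sample_id))
  cat(sprintf("  drivers: %d", nrow(x$drivers)))
  if (nrow(x$drivers)) {
    cat(" (", paste(unique(x$drivers$gene), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  if (nrow(x$loh)) {
    cat(sprintf("  germline: %s\n",
                paste(sprintf("%s [%s]", x$loh$gene, x$loh$status),
                      collapse = "; ")))
  }
  gains <- sum(x$cnv$label == "gain")
  losses <- sum(x$cnv$label == "loss")
  cat(sprintf("  CNV: %d gain(s), %d loss(es)\n", gains, losses))
  cat(sprintf("  TMB: %.2f mut/Mb (%s)\n", x$tmb$tmb, x$tmb$stratum))
  if (x$msi$evaluable) {
    cat(sprintf("  MSI: %.1f%% (%s)\n", x$msi$msi_percent, x$msi$stratum))
  } else {
    cat("  MSI: not evaluable\n")
  }
  cat(sprintf("  actionable findings: %d\n", nrow(x$findings)))
  invisible(x)
}

#' Read a cohort directory
#'
#' Reads the file layout produced by [write_cohort()] /
#' [simulate_cohort()]: per-sample VCFs under `samples/`, plus `cnv.tsv`,
#' `msi.tsv` and `meta.tsv`.
#'
#' @param dir cohort directory.
#' @param baseline MSI baseline table used when `msi.tsv` lacks a
#'   `baseline` column.
#' @return a list with `variants`, `cnv`, `msi`, `meta` tables.
#' @export
read_cohort_dir <- function(dir, baseline = default_msi_baseline()) {
  meta <- read_sample_meta(file.path(dir, "meta.tsv"))
  vcfs <- file.path(dir, "samples", paste0(meta$sample_id, ".vcf"))
  missing <- !file.exists(vcfs)
  if (any(missing)) {
    stop_format("missing per-sample VCF(s): %s",
                paste(basename(vcfs[missing]), collapse = ", "))
  }
  variants <- do.call(rbind, Map(read_variants, vcfs, meta$sample_id))
  rownames(variants) <- NULL
  list(variants = variants,
       cnv = read_cnv_table(file.path(dir, "cnv.tsv")),
       msi = read_msi_table(file.path(dir, "msi.tsv"), baseline = baseline),
       meta = meta)
}
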