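# Cohort-level aggregation: per-gene variant and copy-number frequencies,
# biomarker medians and ranges, actionable fraction, germline/LOH counts,
# clinical percentages over non-missing denominators, and an
# oncoprint-style sample-by-gene alteration matrix.

ONCOPRINT_VOCAB <- c("missense", "truncating", "frameshift", "amplification",
                     "germline")

consequence_to_oncoprint <- function(consequence) {
  ifelse(consequence %in% c("missense", "inframe_indel"), "missense",
         ifelse(consequence %in% c("stop_gained", "splice_site"), "truncating",
                ifelse(consequence == "frameshift", "frameshift", "missense")))
}

pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, 1)
}

#' Build the oncoprint alteration matrix
#'
#' A sample-by-gene character matrix with cell vocabulary `missense`,
#' `truncating`, `frameshift`, `amplification`, `germline` and `none`;
#' multiple alterations in one cell are concatenated with `;` in that
#' fixed order. Every profiled sample appears as a row even when
#' alteration-free; genes are ordered by decreasing number of altered
#' samples, ties alphabetically.
#'
#' @param profiles a list of `sample_profile` objects.
#' @return a character matrix (samples x genes); zero columns for an
#'   alteration-free cohort.
#' @export
oncoprint_matrix <- function(profiles) {
  samples <- unname(vapply(profiles, `[[`, "", "sample_id"))
  cells <- list()
  add <- function(sample, gene, label) {
    key <- paste(sample, gene, sep = "\r")
    cells[[key]] <<- union(cells[[key]], label)
  }
  for (p in profiles) {
    if (nrow(p$drivers)) {
      lab <- consequence_to_oncoprint(p$drivers$consequence)
      for (i in seq_len(nrow(p$drivers))) {
        add(p$sample_id, p$drivers$gene[i], lab[i])
      }
    }
    gains <- p$cnv[p$cnv$label == "gain", , drop = FALSE]
    for (g in unique(gains$gene)) add(p$sample_id, g, "amplification")
    for (g in unique(p$loh$gene)) add(p$sample_id, g, "germline")
  }
  if (!length(cells)) {
    return(matrix(character(0), nrow = length(samples), ncol = 0,
                  dimnames = list(samples, NULL)))
  }
  keys <- do.call(rbind, strsplit(names(cells), "\r", fixed = TRUE))
  genes <- unique(keys[, 2])
  altered_n <- vapply(genes, function(g) length(unique(keys[keys[, 2] == g, 1])),
                      integer(1))
  genes <- genes[order(-altered_n, genes)]
  m <- matrix("none", nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  for (k in seq_len(nrow(keys))) {
    labs <- cells[[names(cells)[k]]]
    labs <- ONCOPRINT_VOCAB[ONCOPRINT_VOCAB %in% labs]
    m[keys[k, 1], keys[k, 2]] <- paste(labs, collapse = ";")
  }
  m
}

#' Summarize a profiled cohort
#'
#' Aggregates per-sample profiles into cohort-level results: per-gene
#' variant frequencies (a gene counts once per sample), variants per
#' sample (median/range), per-gene copy-number gain frequencies with
#' median fold-change among gains, TMB and MSI medians/ranges and high
#' counts, actionable-sample count and percentage, germline carrier and
#' LOH counts, clinical percentages computed over non-missing
#' denominators, and the oncoprint matrix. Percentages are displayed to
#' one decimal, half-up.
#'
#' @param profiles a list of `sample_profile` objects (one per sample).
#' @param metas the cohort metadata table (defaults to the rows carried by
#'   the profiles).
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(profiles, metas = NULL) {
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop_input("duplicate sample_id among profiles: %s",
               ids[duplicated(ids)][1])
  }
  if (is.null(metas)) {
    metas <- do.call(rbind, lapply(profiles, `[[`, "meta"))
  }
  n <- length(profiles)

  empty_summary <- function() {
    structure(list(
      n_samples = 0L,
      gene_variant_freq = data.frame(gene = character(),
                                     n_mutated = integer(),
                                     percent = numeric()),
      variants_per_sample = data.frame(sample_id = character(),
                                       n_variants = integer()),
      variants_per_sample_summary = list(median = NA_real_, min = NA_real_,
                                         max = NA_real_),
      cnv_gene_freq = data.frame(gene = character(), cytoband = character(),
                                 n_gain = integer(), percent = numeric(),
                                 median_gain_fc = numeric()),
      n_samples_with_gain = 0L, pct_samples_with_gain = NA_real_,
      tmb = data.frame(sample_id = character(), eligible_count = integer(),
                       tmb = numeric(), stratum = character()),
      tmb_summary = list(median = NA_real_, min = NA_real_, max = NA_real_,
                         n_high = 0L),
      msi = data.frame(sample_id = character(), msi_percent = numeric(),
                       stratum = character(), evaluable = logical()),
      msi_summary = list(median = NA_real_, min = NA_real_, max = NA_real_,
                         n_high = 0L, n_not_evaluable = 0L),
      findings = empty_findings(),
      n_actionable = 0L, pct_actionable = NA_real_,
      germline_summary = list(n_carriers = 0L, pct_carriers = NA_real_,
                              n_with_loh = 0L),
      clinical = data.frame(field = character(), n = integer(),
                            denominator = integer(), percent = numeric()),
      oncoprint = matrix(character(0), 0, 0)
    ), class = "cohort_summary")
  }
  if (n == 0L) return(empty_summary())

  # per-gene variant frequency: a gene counts once per sample
  mutated <- lapply(profiles, function(p) unique(p$drivers$gene))
  tab <- table(unlist(mutated))
  gene_freq <- data.frame(gene = names(tab),
                          n_mutated = as.integer(tab),
                          stringsAsFactors = FALSE)
  gene_freq$percent <- pct1(gene_freq$n_mutated, n)
  gene_freq <- gene_freq[order(-gene_freq$n_mutated, gene_freq$gene), ,
                         drop = FALSE]
  rownames(gene_freq) <- NULL

  vps <- data.frame(sample_id = ids,
                    n_variants = vapply(profiles,
                                        function(p) nrow(p$drivers), 0L),
                    stringsAsFactors = FALSE)
  vps_summary <- list(median = stats::median(vps$n_variants),
                      min = min(vps$n_variants), max = max(vps$n_variants))

  cnv_all <- do.call(rbind, lapply(profiles, `[[`, "cnv"))
  cnv_freq <- summarize_cnv(cnv_all)
  cnv_freq$percent <- pct1(cnv_freq$n_gain, n)
  cnv_freq <- cnv_freq[, c("gene", "cytoband", "n_gain", "percent",
                           "median_gain_fc")]
  with_gain <- vapply(profiles, function(p) any(p$cnv$label == "gain"), NA)

  tmb_df <- data.frame(
    sample_id = ids,
    eligible_count = vapply(profiles, function(p) p$tmb$eligible_count, 0L),
    tmb = vapply(profiles, function(p) p$tmb$tmb, 0),
    stratum = vapply(profiles, function(p) p$tmb$stratum, ""),
    stringsAsFactors = FALSE)
  tmb_summary <- list(median = stats::median(tmb_df$tmb),
                      min = min(tmb_df$tmb), max = max(tmb_df$tmb),
                      n_high = sum(tmb_df$stratum == "high"))

  msi_df <- data.frame(
    sample_id = ids,
    msi_percent = vapply(profiles, function(p) p$msi$msi_percent, 0),
    stratum = vapply(profiles,
                     function(p) p$msi$stratum %||% NA_character_, ""),
    evaluable = vapply(profiles, function(p) p$msi$evaluable, NA),
    stringsAsFactors = FALSE)
  ev <- msi_df$evaluable
  msi_summary <- list(
    median = if (any(ev)) stats::median(msi_df$msi_percent[ev]) else NA_real_,
    min = if (any(ev)) min(msi_df$msi_percent[ev]) else NA_real_,
    max = if (any(ev)) max(msi_df$msi_percent[ev]) else NA_real_,
    n_high = sum(msi_df$stratum == "high", na.rm = TRUE),
    n_not_evaluable = sum(!ev))

  findings <- do.call(rbind, lapply(profiles, `[[`, "findings"))
  rownames(findings) <- NULL
  n_actionable <- sum(vapply(profiles, function(p) nrow(p$findings) > 0, NA))

  n_carriers <- sum(vapply(profiles, function(p) nrow(p$loh) > 0, NA))
  n_with_loh <- sum(vapply(profiles,
                           function(p) any(p$loh$status == "LOH"), NA))

  clin_field <- function(values, positive) {
    known <- !is.na(values)
    data.frame(n = sum(values[known] == positive), denominator = sum(known))
  }
  clin <- rbind(
    cbind(field = "er_positive", clin_field(metas$er, "positive")),
    cbind(field = "pr_positive", clin_field(metas$pr, "positive")),
    cbind(field = "her2_positive", clin_field(metas$her2, "positive")),
    cbind(field = "family_history",
          clin_field(tolower(as.character(metas$family_history)), "yes"))
  )
  clin$percent <- mapply(pct1, clin$n, clin$denominator)

  structure(list(
    n_samples = n,
    gene_variant_freq = gene_freq,
    variants_per_sample = vps,
    variants_per_sample_summary = vps_summary,
    cnv_gene_freq = cnv_freq,
    n_samples_with_gain = sum(with_gain),
    pct_samples_with_gain = pct1(sum(with_gain), n),
    tmb = tmb_df, tmb_summary = tmb_summary,
    msi = msi_df, msi_summary = msi_summary,
    findings = findings,
    n_actionable = as.integer(n_actionable),
    pct_actionable = pct1(n_actionable, n),
    germline_summary = list(n_carriers = as.integer(n_carriers),
                            pct_carriers = pct1(n_carriers, n),
                            n_with_loh = as.integer(n_with_loh)),
    clinical = clin,
    oncoprint = oncoprint_matrix(profiles)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d samples\n", x$n_samples))
  if (!x$n_samples) return(invisible(x))
  cat(sprintf("  driver variants/sample: median %g (range %g-%g)\n",
              x$variants_per_sample_summary$median,
              x$variants_per_sample_summary$min,
              x$variants_per_sample_summary$max))
  if (nrow(x$gene_variant_freq)) {
    top <- utils::head(x$gene_variant_freq, 3)
    cat(sprintf("  most mutated: %s\n",
                paste(sprintf("%s %d (%.1f%%)", top$gene, top$n_mutated,
                              top$percent), collapse = ", ")))
  }
  cat(sprintf("  samples with CNV gain: %d (%.1f%%)\n",
              x$n_samples_with_gain, x$pct_samples_with_gain))
  cat(sprintf("  TMB: median %.1f mut/Mb (range %.1f-%.1f), %d high\n",
              x$tmb_summary$median, x$tmb_summary$min, x$tmb_summary$max,
              x$tmb_summary$n_high))
  if (!is.na(x$msi_summary$median)) {
    cat(sprintf("  MSI: median %.1f%% (range %.1f-%.1f), %d high, %d not evaluable\n",
                x$msi_summary$median, x$msi_summary$min, x$msi_summary$max,
                x$msi_summary$n_high, x$msi_summary$n_not_evaluable))
  }
  cat(sprintf("  germline carriers: %d (%.1f%%), %d with LOH\n",
              x$germline_summary$n_carriers, x$germline_summary$pct_carriers,
              x$germline_summary$n_with_loh))
  cat(sprintf("  actionable: %d (%.1f%%)\n", x$n_actionable,
              x$pct_actionable))
  invisible(x)
}

#' Write or read a cohort report
#'
#' `write_report()` writes a structured JSON report plus human-readable
#' TSV tables (gene frequencies, CNV frequencies, per-sample biomarkers,
#' findings, oncoprint matrix) into a directory. `read_report()` restores
#' the `cohort_summary` from the JSON so that a write/read round trip is
#' an equality.
#'
#' @param summary a [summarize_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `write_report()` returns `dir` invisibly; `read_report()`
#'   returns a `cohort_summary`.
#' @export
write_report <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- unclass(summary)
  op <- x$oncoprint
  x$oncoprint <- cbind(data.frame(sample_id = rownames(op),
                                  stringsAsFactors = FALSE),
                       as.data.frame(op, stringsAsFactors = FALSE))
  jsonlite::write_json(x, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  write_tsv(summary$gene_variant_freq, file.path(dir, "gene_frequencies.tsv"))
  write_tsv(summary$cnv_gene_freq, file.path(dir, "cnv_frequencies.tsv"))
  biomarkers <- merge(summary$tmb, summary$msi, by = "sample_id",
                      suffixes = c("_tmb", "_msi"))
  write_tsv(biomarkers, file.path(dir, "biomarkers.tsv"))
  write_tsv(summary$findings, file.path(dir, "findings.tsv"))
  write_tsv(x$oncoprint, file.path(dir, "oncoprint.tsv"))
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) stop_format("no report.json under %s", dir)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  op <- x$oncoprint
  if (is.data.frame(op) && nrow(op)) {
    m <- as.matrix(op[, setdiff(names(op), "sample_id"), drop = FALSE])
    rownames(m) <- op$sample_id
    x$oncoprint <- m
  } else {
    sn <- if (is.data.frame(op)) op$sample_id else character(0)
    x$oncoprint <- matrix(character(0), nrow = length(sn), ncol = 0,
                          dimnames = list(sn, NULL))
  }
  for (f in c("gene_variant_freq", "variants_per_sample", "cnv_gene_freq",
              "tmb", "msi", "findings", "clinical")) {
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  }
  structure(x, class = "cohort_summary")
}
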