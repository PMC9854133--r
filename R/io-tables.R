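# Tab-separated I/O for copy-number calls, microsatellite locus
# observations and sample metadata. All readers validate the schema and
# report the offending row; all writer/reader pairs round-trip losslessly.

CNV_COLUMNS <- c("sample_id", "gene", "fold_change", "cytoband")
MSI_COLUMNS <- c("sample_id", "locus_id", "ref_len", "histogram")
META_COLUMNS <- c("sample_id", "er", "pr", "her2", "ar", "grade",
                  "tnm_stage", "ki67_class", "intrinsic_subtype",
                  "tils_percent", "family_history", "germline_variants")

read_tsv <- function(path, what) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# --- copy-number calls --------------------------------------------------

#' Read or write gene-level copy-number fold-change tables
#'
#' The TSV schema is `sample_id`, `gene`, `fold_change` (positive real,
#' 1.0 = diploid baseline), `cytoband` (optional label). Round trips are
#' lossless.
#'
#' @param path TSV file path.
#' @param calls a CNV call table.
#' @return `read_cnv_table()` returns a data.frame of CNV calls.
#' @export
read_cnv_table <- function(path) {
  df <- read_tsv(path)
  if (!"cytoband" %in% names(df)) df$cytoband <- NA_character_
  check_columns(df, CNV_COLUMNS, "CNV table")
  df <- df[, CNV_COLUMNS]
  df$fold_change <- suppressWarnings(as.numeric(df$fold_change))
  bad <- is.na(df$fold_change) | df$fold_change <= 0
  if (any(bad)) {
    stop_schema("CNV table row %d: fold_change must be a positive number",
                which(bad)[1])
  }
  df$cytoband <- as.character(df$cytoband)
  df
}

#' @rdname read_cnv_table
#' @export
write_cnv_table <- function(calls, path) {
  check_columns(calls, setdiff(CNV_COLUMNS, "cytoband"), "CNV table")
  if (!"cytoband" %in% names(calls)) calls$cytoband <- NA_character_
  write_tsv(calls[, CNV_COLUMNS], path)
}

# --- microsatellite locus observations ----------------------------------

#' Stutter baseline for a homopolymer locus
#'
#' Expected read-length proportions at a microsatellite locus in the
#' absence of instability, under a polymerase-slippage (stutter) model:
#' most reads sit at the reference repeat length, a deletion-biased tail
#' sits at one and two units shorter, and a small fraction one unit
#' longer. Stutter grows with repeat length: the total off-reference
#' proportion is `0.05 + 0.005 * ref_len`.
#'
#' @param ref_len reference repeat length (integer >= 1).
#' @return named numeric vector of proportions (names are repeat lengths)
#'   summing to 1.
#' @export
stutter_baseline <- function(ref_len) {
  ref_len <- as.integer(ref_len)
  stopifnot(ref_len >= 1L)
  off <- 0.05 + 0.005 * ref_len
  p <- c(0.2 * off, 0.7 * off, 1 - off, 0.1 * off)
  names(p) <- c(ref_len - 2L, ref_len - 1L, ref_len, ref_len + 1L)
  p[as.integer(names(p)) >= 1L]
}

#' Default homopolymer-locus baseline table
#'
#' The 125 homopolymer MSI loci of the default panel with their reference
#' repeat lengths (cycling 8-15 bp) and [stutter_baseline()] proportions.
#' A copy ships as `inst/extdata/msi_baseline.tsv`; users may substitute
#' their own baseline table with the same schema (`locus_id`, `ref_len`,
#' `baseline` as `length:proportion` pairs).
#'
#' @param n_loci number of loci (default 125).
#' @return a data.frame with columns `locus_id`, `ref_len`, `baseline`.
#' @export
default_msi_baseline <- function(n_loci = 125) {
  ref_len <- 8L + (seq_len(n_loci) - 1L) %% 8L
  data.frame(
    locus_id = sprintf("MSI_%03d", seq_len(n_loci)),
    ref_len = ref_len,
    baseline = vapply(ref_len, function(r) format_hist(stutter_baseline(r)), ""),
    stringsAsFactors = FALSE
  )
}

#' Read a baseline table from disk
#'
#' @param path TSV with columns `locus_id`, `ref_len`, `baseline`;
#'   defaults to the bundled 125-locus baseline.
#' @return a baseline data.frame.
#' @export
read_msi_baseline <- function(path = system.file("extdata", "msi_baseline.tsv",
                                                 package = "oncopanel")) {
  df <- read_tsv(path)
  check_columns(df, c("locus_id", "ref_len", "baseline"), "MSI baseline table")
  df$ref_len <- as.integer(df$ref_len)
  for (i in seq_len(nrow(df))) {
    p <- parse_hist(df$baseline[i])
    if (abs(sum(p) - 1) > 1e-9) {
      stop_schema("MSI baseline row %d: proportions sum to %g, not 1",
                  i, sum(p))
    }
  }
  df[, c("locus_id", "ref_len", "baseline")]
}

#' Read or write microsatellite locus observation tables
#'
#' The TSV schema is `sample_id`, `locus_id`, `ref_len`, `histogram`
#' (read counts by repeat length as comma-joined `length:count` pairs) and
#' optionally `baseline` (expected proportions in the same encoding). When
#' the file has no `baseline` column, baselines are joined from the
#' `baseline` table by `locus_id`. Observations are kept whatever their
#' coverage; the coverage gate is applied at assessment time.
#'
#' @param path TSV file path.
#' @param baseline a baseline table ([default_msi_baseline()] by default),
#'   used when the file carries no `baseline` column.
#' @param observations an MSI observation table.
#' @return `read_msi_table()` returns a data.frame with columns
#'   `sample_id`, `locus_id`, `ref_len`, `histogram`, `baseline`.
#' @export
read_msi_table <- function(path, baseline = default_msi_baseline()) {
  df <- read_tsv(path)
  check_columns(df, MSI_COLUMNS, "MSI table")
  df$ref_len <- as.integer(df$ref_len)
  if (any(is.na(df$ref_len) | df$ref_len < 1L)) {
    stop_schema("MSI table row %d: ref_len must be a positive integer",
                which(is.na(df$ref_len) | df$ref_len < 1L)[1])
  }
  if (!"baseline" %in% names(df)) {
    idx <- match(df$locus_id, baseline$locus_id)
    if (anyNA(idx)) {
      stop_schema("MSI table row %d: locus '%s' not in the baseline table",
                  which(is.na(idx))[1], df$locus_id[is.na(idx)][1])
    }
    df$baseline <- baseline$baseline[idx]
  }
  for (i in seq_len(nrow(df))) {
    h <- parse_hist(df$histogram[i])
    if (any(h < 0)) stop_schema("MSI table row %d: negative read count", i)
    b <- parse_hist(df$baseline[i])
    if (abs(sum(b) - 1) > 1e-9) {
      stop_schema("MSI table row %d: baseline proportions sum to %g, not 1",
                  i, sum(b))
    }
  }
  df[, c(MSI_COLUMNS, "baseline")]
}

#' @rdname read_msi_table
#' @export
write_msi_table <- function(observations, path) {
  check_columns(observations, c(MSI_COLUMNS, "baseline"), "MSI table")
  write_tsv(observations[, c(MSI_COLUMNS, "baseline")], path)
}

# --- sample metadata ----------------------------------------------------

parse_status <- function(x, col) {
  x <- tolower(as.character(x))
  x[x %in% c("na", "")] <- NA_character_
  bad <- !is.na(x) & !x %in% STATUS_LEVELS
  if (any(bad)) {
    stop_schema("metadata row %d: %s status '%s' not in {positive, negative}",
                which(bad)[1], col, x[bad][1])
  }
  x
}

#' Read or write sample clinical metadata tables
#'
#' The TSV schema is `sample_id`; receptor statuses `er`, `pr`, `her2`,
#' `ar` (`positive` / `negative` / `NA`); optional clinical fields
#' `grade`, `tnm_stage`, `ki67_class`, `intrinsic_subtype`,
#' `tils_percent`, `family_history`; and `germline_variants`, a
#' semicolon-separated list of `GENE|c.notation|p.notation` triplets
#' (empty for non-carriers). Use [germline_table()] to expand the triplets.
#'
#' @param path TSV file path.
#' @param meta a metadata table.
#' @return `read_sample_meta()` returns a data.frame with the columns above.
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("sample_id", "er", "pr", "her2"), "metadata table")
  for (col in setdiff(META_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, META_COLUMNS]
  for (col in c("er", "pr", "her2", "ar")) {
    df[[col]] <- parse_status(df[[col]], col)
  }
  for (col in c("tnm_stage", "ki67_class", "intrinsic_subtype",
                "family_history")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$tils_percent <- suppressWarnings(as.numeric(df$tils_percent))
  df$germline_variants <- ifelse(is.na(df$germline_variants), "",
                                 as.character(df$germline_variants))
  if (anyDuplicated(df$sample_id)) {
    stop_schema("metadata table: duplicate sample_id '%s'",
                df$sample_id[duplicated(df$sample_id)][1])
  }
  df
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path) {
  check_columns(meta, META_COLUMNS, "metadata table")
  out <- meta[, META_COLUMNS]
  out$germline_variants[!nzchar(out$germline_variants)] <- NA
  write_tsv(out, path)
}

#' Expand declared germline variants from a metadata table
#'
#' @param meta a metadata table (or subset of rows).
#' @return a data.frame with one row per declared germline variant:
#'   `sample_id`, `gene`, `hgvs_c`, `hgvs_p`.
#' @export
germline_table <- function(meta) {
  out <- data.frame(sample_id = character(), gene = character(),
                    hgvs_c = character(), hgvs_p = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(meta))) {
    gv <- meta$germline_variants[i]
    if (is.na(gv) || !nzchar(gv)) next
    trip <- strsplit(strsplit(gv, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
    bad <- lengths(trip) != 3L
    if (any(bad)) {
      stop_schema("sample %s: malformed germline variant entry '%s'",
                  meta$sample_id[i],
                  paste(trip[bad][[1]], collapse = "|"))
    }
    out <- rbind(out, data.frame(
      sample_id = meta$sample_id[i],
      gene = vapply(trip, `[[`, "", 1L),
      hgvs_c = vapply(trip, `[[`, "", 2L),
      hgvs_p = vapply(trip, `[[`, "", 3L),
      stringsAsFactors = FALSE
    ))
  }
  out
}

# Encode a germline_table back into the metadata string form.
format_germline <- function(gene, hgvs_c, hgvs_p) {
  if (!length(gene)) return("")
  paste(sprintf("%s|%s|%s", gene, hgvs_c, hgvs_p), collapse = ";")
}
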