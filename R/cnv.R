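# Gene-level copy-number classification from fold-changes.
#
# Fold-changes arrive from an upstream copy-number caller (1.0 = diploid
# baseline) and are classified by fixed thresholds: gain at fold-change
# >= 1.5 (three copies), loss at <= 0.5 (one copy), neutral between. The
# integer copy estimate is 2 * fold-change rounded half away from zero,
# so the gain boundary 1.5 maps to exactly three copies.

#' Classify copy-number fold-changes into gains and losses
#'
#' @param calls a CNV call table (`sample_id`, `gene`, `fold_change`,
#'   optional `cytoband`); every gene must belong to the panel's
#'   CNV-eligible subset.
#' @param panel a [panel_definition()]; CNV calling is restricted to
#'   `panel$cnv_genes`.
#' @param cfg a [panel_thresholds()] configuration.
#' @return the input table with added columns `label` (`gain`, `loss` or
#'   `neutral`) and `estimated_copies` (non-negative integer).
#' @export
classify_cnv <- function(calls, panel = default_panel(),
                         cfg = panel_thresholds()) {
  check_columns(calls, c("sample_id", "gene", "fold_change"), "CNV calls")
  if (!"cytoband" %in% names(calls)) calls$cytoband <- NA_character_
  if (any(is.na(calls$fold_change) | calls$fold_change <= 0)) {
    stop_input("fold_change must be positive")
  }
  bad <- !calls$gene %in% panel$cnv_genes
  if (any(bad)) {
    stop_input("gene(s) not eligible for CNV calling on this panel: %s",
               paste(unique(calls$gene[bad]), collapse = ", "))
  }
  calls$label <- ifelse(calls$fold_change >= cfg$cnv_gain_fc, "gain",
                        ifelse(calls$fold_change <= cfg$cnv_loss_fc,
                               "loss", "neutral"))
  calls$estimated_copies <- copies_from_fc(calls$fold_change)
  rownames(calls) <- NULL
  calls
}

#' Summarize classified copy-number calls per gene
#'
#' Aggregates a cohort's classified CNV calls gene by gene: number of
#' gains and losses and the median fold-change among gain-labeled calls
#' (even counts use the mean of the central pair). Genes with neither
#' gains nor losses are omitted.
#'
#' @param classified output of [classify_cnv()], possibly several samples.
#' @param cfg a [panel_thresholds()] configuration (unused thresholds are
#'   accepted for interface symmetry).
#' @return a data.frame with columns `gene`, `cytoband`, `n_gain`,
#'   `n_loss`, `median_gain_fc`, sorted by decreasing `n_gain`.
#' @export
summarize_cnv <- function(classified, cfg = panel_thresholds()) {
  empty <- data.frame(gene = character(), cytoband = character(),
                      n_gain = integer(), n_loss = integer(),
                      median_gain_fc = numeric(), stringsAsFactors = FALSE)
  if (!nrow(classified)) return(empty)
  check_columns(classified, c("gene", "fold_change", "label"), "classified CNV")
  keep <- classified$label %in% c("gain", "loss")
  if (!any(keep)) return(empty)
  x <- classified[keep, , drop = FALSE]
  rows <- lapply(split(x, x$gene), function(g) {
    gains <- g$fold_change[g$label == "gain"]
    cb <- g$cytoband[!is.na(g$cytoband)]
    data.frame(
      gene = g$gene[1],
      cytoband = if (length(cb)) cb[1] else NA_character_,
      n_gain = sum(g$label == "gain"),
      n_loss = sum(g$label == "loss"),
      median_gain_fc = if (length(gains)) stats::median(gains) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_gain, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
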