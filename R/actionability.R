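# Clinical actionability annotation against a bundled, versioned
# knowledge-base snapshot (OncoKB-style, but static: reproducibility over
# freshness; users may swap in their own snapshot).
#
# Entry kinds:
#   variant_hotspot  gene + normalized protein change, matched against the
#                    triaged driver set (case-insensitive gene symbols,
#                    normalization-invariant protein changes);
#   germline_gene    gene matched against declared germline pathogenic
#                    variants, with or without LOH (the LOH status is
#                    recorded in the finding's trigger);
#   tmb_high         fires when the sample's TMB stratum is high;
#   msi_high         fires when the sample's MSI stratum is high.

KB_COLUMNS <- c("alteration_kind", "gene", "protein_change", "therapy",
                "evidence_note")
KB_KINDS <- c("variant_hotspot", "germline_gene", "tmb_high", "msi_high")

#' Load an actionability knowledge-base snapshot
#'
#' Reads and validates a knowledge-base TSV (columns `alteration_kind`,
#' `gene`, `protein_change`, `therapy`, `evidence_note`; `#`-prefixed
#' header lines carry the snapshot version). Hotspot entries must carry a
#' gene and protein change; biomarker entries (`tmb_high`, `msi_high`)
#' must carry neither. Duplicate entries are rejected.
#'
#' @param path TSV file path; defaults to the bundled snapshot.
#' @return a data.frame of class `oncopanel_kb`.
#' @export
load_kb <- function(path = system.file("extdata", "kb_snapshot.tsv",
                                       package = "oncopanel")) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  kb <- read_tsv(path)
  check_columns(kb, KB_COLUMNS, "knowledge base")
  kb <- kb[, KB_COLUMNS]
  bad <- !kb$alteration_kind %in% KB_KINDS
  if (any(bad)) {
    stop_schema("knowledge base line %d: unknown alteration_kind '%s'",
                which(bad)[1], kb$alteration_kind[bad][1])
  }
  hs <- kb$alteration_kind == "variant_hotspot"
  miss <- hs & (is.na(kb$gene) | is.na(kb$protein_change))
  if (any(miss)) {
    stop_schema("knowledge base line %d: variant_hotspot entry needs gene and protein_change",
                which(miss)[1])
  }
  gg <- kb$alteration_kind == "germline_gene"
  miss <- gg & is.na(kb$gene)
  if (any(miss)) {
    stop_schema("knowledge base line %d: germline_gene entry needs a gene",
                which(miss)[1])
  }
  bm <- kb$alteration_kind %in% c("tmb_high", "msi_high")
  extra <- bm & (!is.na(kb$gene) | !is.na(kb$protein_change))
  if (any(extra)) {
    stop_schema("knowledge base line %d: biomarker entry must not carry gene or protein_change",
                which(extra)[1])
  }
  key <- paste(kb$alteration_kind, toupper(kb$gene),
               normalize_hgvs_p(kb$protein_change))
  if (anyDuplicated(key)) {
    stop_schema("knowledge base line %d: duplicate entry",
                which(duplicated(key))[1])
  }
  class(kb) <- c("oncopanel_kb", class(kb))
  kb
}

empty_findings <- function() {
  data.frame(sample_id = character(), alteration_kind = character(),
             gene = character(), trigger = character(),
             therapy = character(), evidence_note = character(),
             stringsAsFactors = FALSE)
}

#' Annotate a sample profile with actionable findings
#'
#' Matches a completed [profile_sample()] bundle against a knowledge base:
#' triaged drivers against hotspot entries, declared germline variants
#' against germline-gene entries (regardless of LOH status, which is
#' recorded in the trigger), and high TMB / MSI strata against the
#' biomarker entries. Findings are ordered deterministically: variant
#' hotspots (by gene, then position), then germline, then TMB, then MSI.
#'
#' @param profile a `sample_profile` object (or a list with elements
#'   `sample_id`, `drivers`, `loh`, `tmb`, `msi`).
#' @param kb a knowledge base from [load_kb()].
#' @return a data.frame of findings: `sample_id`, `alteration_kind`,
#'   `gene`, `trigger`, `therapy`, `evidence_note`. Zero rows when nothing
#'   is actionable.
#' @export
annotate_sample <- function(profile, kb = load_kb()) {
  if (!inherits(kb, "oncopanel_kb")) {
    stop_input("kb must be loaded through load_kb()")
  }
  out <- empty_findings()
  sid <- profile$sample_id

  hs <- kb[kb$alteration_kind == "variant_hotspot", , drop = FALSE]
  drivers <- profile$drivers
  if (nrow(hs) && !is.null(drivers) && nrow(drivers)) {
    drivers <- drivers[order(drivers$gene, drivers$pos), , drop = FALSE]
    for (i in seq_len(nrow(drivers))) {
      hit <- which(toupper(hs$gene) == toupper(drivers$gene[i]) &
                     normalize_hgvs_p(hs$protein_change) ==
                       normalize_hgvs_p(drivers$hgvs_p[i]))
      if (length(hit)) {
        out <- rbind(out, data.frame(
          sample_id = sid, alteration_kind = "variant_hotspot",
          gene = drivers$gene[i],
          trigger = sprintf("%s %s (%s), VAF %.2f", drivers$gene[i],
                            drivers$hgvs_p[i], drivers$hgvs_c[i],
                            drivers$vaf[i]),
          therapy = hs$therapy[hit[1]],
          evidence_note = hs$evidence_note[hit[1]],
          stringsAsFactors = FALSE
        ))
      }
    }
  }

  gg <- kb[kb$alteration_kind == "germline_gene", , drop = FALSE]
  loh <- profile$loh
  if (nrow(gg) && !is.null(loh) && nrow(loh)) {
    for (i in seq_len(nrow(loh))) {
      hit <- which(toupper(gg$gene) == toupper(loh$gene[i]))
      if (length(hit)) {
        out <- rbind(out, data.frame(
          sample_id = sid, alteration_kind = "germline_gene",
          gene = loh$gene[i],
          trigger = sprintf("germline %s %s (%s), tumor status %s",
                            loh$gene[i], loh$germline_hgvs_p[i],
                            loh$germline_hgvs_c[i], loh$status[i]),
          therapy = gg$therapy[hit[1]],
          evidence_note = gg$evidence_note[hit[1]],
          stringsAsFactors = FALSE
        ))
      }
    }
  }

  tmb_kb <- kb[kb$alteration_kind == "tmb_high", , drop = FALSE]
  if (nrow(tmb_kb) && !is.null(profile$tmb) &&
      identical(profile$tmb$stratum, "high")) {
    out <- rbind(out, data.frame(
      sample_id = sid, alteration_kind = "tmb_high", gene = NA_character_,
      trigger = sprintf("TMB %.1f mut/Mb (high)", profile$tmb$tmb),
      therapy = tmb_kb$therapy[1], evidence_note = tmb_kb$evidence_note[1],
      stringsAsFactors = FALSE
    ))
  }

  msi_kb <- kb[kb$alteration_kind == "msi_high", , drop = FALSE]
  if (nrow(msi_kb) && !is.null(profile$msi) &&
      identical(profile$msi$stratum, "high")) {
    out <- rbind(out, data.frame(
      sample_id = sid, alteration_kind = "msi_high", gene = NA_character_,
      trigger = sprintf("MSI %.1f%% unstable loci (high)",
                        profile$msi$msi_percent),
      therapy = msi_kb$therapy[1], evidence_note = msi_kb$evidence_note[1],
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}
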