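# Loss of heterozygosity at germline pathogenic variants.
#
# For carriers of a germline pathogenic variant (BRCA1/BRCA2/PALB2 in the
# breast-cancer setting), the tumor allele fraction at that variant
# indicates whether the wild-type allele was lost: a heterozygous variant
# sits near 50% in a pure tumor, and a fraction strictly above the
# threshold (default 50%) is called LOH. The evaluation reads the raw
# tumor call set, not the triaged driver set, because germline variants
# legitimately exceed the somatic VAF ceiling.

#' Evaluate loss of heterozygosity at declared germline variants
#'
#' For every germline variant declared in a sample's metadata, finds the
#' matching call in the tumor variant table (by gene plus normalized HGVS
#' protein change, falling back to the coding change) and classifies:
#' `LOH` when tumor VAF is strictly greater than `cfg$loh_vaf`, `NO_LOH`
#' otherwise, `NOT_EVALUABLE` when the variant is absent from the tumor
#' call set.
#'
#' @param meta a one-row metadata table (see [read_sample_meta()]).
#' @param tumor_variants the sample's full variant table (untriaged).
#' @param cfg a [panel_thresholds()] configuration.
#' @return a data.frame with one row per declared germline variant:
#'   `sample_id`, `gene`, `germline_hgvs_c`, `germline_hgvs_p`,
#'   `tumor_vaf`, `status`. Samples without germline variants yield zero
#'   rows.
#' @export
evaluate_loh <- function(meta, tumor_variants, cfg = panel_thresholds()) {
  if (nrow(meta) != 1L) stop_input("evaluate_loh expects one metadata row")
  germ <- germline_table(meta)
  out <- data.frame(sample_id = character(), gene = character(),
                    germline_hgvs_c = character(),
                    germline_hgvs_p = character(),
                    tumor_vaf = numeric(), status = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(germ)) return(out)
  tumor_variants <- validate_variants(tumor_variants)
  tv_p <- normalize_hgvs_p(tumor_variants$hgvs_p)
  for (i in seq_len(nrow(germ))) {
    hit <- which(
      toupper(tumor_variants$gene) == toupper(germ$gene[i]) &
        ((!is.na(tv_p) & tv_p == normalize_hgvs_p(germ$hgvs_p[i])) |
           (!is.na(tumor_variants$hgvs_c) &
              tumor_variants$hgvs_c == germ$hgvs_c[i]))
    )
    if (length(hit)) {
      vaf <- tumor_variants$vaf[hit[1]]
      status <- if (vaf > cfg$loh_vaf) "LOH" else "NO_LOH"
    } else {
      vaf <- NA_real_
      status <- "NOT_EVALUABLE"
    }
    out <- rbind(out, data.frame(
      sample_id = meta$sample_id, gene = germ$gene[i],
      germline_hgvs_c = germ$hgvs_c[i], germline_hgvs_p = germ$hgvs_p[i],
      tumor_vaf = vaf, status = status, stringsAsFactors = FALSE
    ))
  }
  out
}
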