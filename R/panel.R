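# Panel model: which genes the assay targets, which subset is eligible for
# copy-number calling, how much genome is captured, and how many
# homopolymer microsatellite loci are profiled.

# Genes with recurrent somatic driver variants in male breast cancer panels.
SOMATIC_GENES <- c("PIK3CA", "ARID1A", "EP300", "SMO", "SMARCA4", "PAX5",
                   "NCOR1", "MAP3K1", "GATA3", "CREBBP", "TRAF7", "TP53",
                   "PIK3R1", "PDGFRA", "NOTCH2", "NOTCH1", "FOXL2", "CIC",
                   "BRAF", "AXIN1", "ASXL1", "ARID2", "ABL1")

GERMLINE_GENES <- c("BRCA1", "BRCA2", "PALB2")

# The 59 genes eligible for gene-level copy-number calling.
CNV_GENES <- c("MYC", "CCND1", "FGF19", "FGF3", "FGF4", "CDK4", "MDM2",
               "ERBB2", "EGFR", "FGFR1", "CCNE1", "AKT2", "MET", "CDK6",
               "KRAS", "MYCN", "PDGFRA", "FGFR2", "FGFR3", "AR", "RAF1",
               "IGF1R", "ALK", "AKT1", "AKT3", "ATM", "BRAF", "BRCA1",
               "BRCA2", "CCND2", "CCND3", "CDKN2A", "CHEK1", "CHEK2",
               "ESR1", "ERBB3", "FGF1", "FGF2", "FGFR4", "JAK2", "KIT",
               "LAMP1", "MCL1", "MDM4", "MYCL1", "NF1", "NRAS", "NTRK1",
               "NTRK2", "NTRK3", "PDGFRB", "PIK3CA", "PIK3CB", "PTEN",
               "RB1", "RET", "RICTOR", "RPS6KB1", "TP53")

#' Define a targeted sequencing panel
#'
#' A panel is a gene list, the subset of genes eligible for copy-number
#' calling, the captured genome size in megabases (the TMB denominator) and
#' the number of homopolymer microsatellite loci profiled for MSI.
#'
#' @param genes character vector of targeted gene symbols.
#' @param cnv_genes subset of `genes` eligible for copy-number calls.
#' @param target_size_mb megabases of genome captured (default 1.94).
#' @param msi_locus_count number of homopolymer loci (default 125).
#' @return an object of class `panel_definition`.
#' @seealso [default_panel()], [panel_from_bed()]
#' @export
panel_definition <- function(genes, cnv_genes,
                             target_size_mb = 1.94,
                             msi_locus_count = 125) {
  genes <- unique(as.character(genes))
  cnv_genes <- unique(as.character(cnv_genes))
  if (!length(genes)) stop_input("panel gene list is empty")
  extra <- setdiff(cnv_genes, genes)
  if (length(extra)) {
    stop_input("cnv_genes not in the panel gene list: %s",
               paste(extra, collapse = ", "))
  }
  if (!is.numeric(target_size_mb) || target_size_mb <= 0) {
    stop_input("target_size_mb must be positive")
  }
  if (msi_locus_count <= 0) stop_input("msi_locus_count must be positive")
  structure(list(genes = genes, cnv_genes = cnv_genes,
                 target_size_mb = target_size_mb,
                 msi_locus_count = as.integer(msi_locus_count)),
            class = "panel_definition")
}

#' Default 523-gene panel
#'
#' A panel with the geometry of a large hybrid-capture oncology assay:
#' 523 genes covering 1.94 Mb, 59 genes eligible for copy-number calling
#' and 125 homopolymer MSI loci. The list contains the real cancer gene
#' symbols the pipeline logic references (driver, germline-predisposition
#' and copy-number genes) padded with synthetic placeholder symbols
#' (`PANEL_Gxxx`) to the nominal 523; the true commercial manifest is not
#' redistributed.
#'
#' @return a [panel_definition()] object with 523 genes.
#' @export
default_panel <- function() {
  named <- unique(c(SOMATIC_GENES, GERMLINE_GENES, CNV_GENES))
  filler <- sprintf("PANEL_G%03d", seq_len(523 - length(named)))
  panel_definition(c(named, filler), CNV_GENES,
                   target_size_mb = 1.94, msi_locus_count = 125)
}

#' Build a panel from a BED file of target regions
#'
#' Reads a BED file (0-based half-open starts, converted here to 1-based
#' coordinates) whose name column carries gene symbols, and derives the
#' gene list and the captured size in megabases from the targets.
#'
#' @param path BED file of panel targets; the 4th column must name the gene.
#' @param cnv_genes genes eligible for CNV calling (default: the
#'   intersection of the BED genes with the built-in copy-number gene set).
#' @param msi_locus_count number of homopolymer loci (default 125).
#' @return a [panel_definition()] object.
#' @export
panel_from_bed <- function(path, cnv_genes = NULL, msi_locus_count = 125) {
  tgt <- read_bed(path)
  if (all(is.na(tgt$name))) stop_schema("BED file has no name (gene) column")
  genes <- unique(tgt$name[!is.na(tgt$name)])
  mb <- sum(tgt$end - tgt$start + 1) / 1e6
  if (is.null(cnv_genes)) cnv_genes <- intersect(genes, CNV_GENES)
  panel_definition(genes, cnv_genes, target_size_mb = mb,
                   msi_locus_count = msi_locus_count)
}

# BED targets as a data.frame with 1-based inclusive coordinates.
# rtracklayer::import performs the 0-based half-open -> 1-based conversion;
# this wrapper is the single place panel coordinates enter the package.
read_bed <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  data.frame(
    chrom = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    name = if ("name" %in% names(df)) as.character(df$name) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("Panel: %d genes (%d CNV-eligible), %.2f Mb, %d MSI loci\n",
              length(x$genes), length(x$cnv_genes), x$target_size_mb,
              x$msi_locus_count))
  invisible(x)
}
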