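# Annotated somatic variant I/O.
#
# Variants travel as plain data.frames with one row per called ALT allele
# and a fixed column set (see `variant_record`). On disk they are VCF 4.2
# with a documented tag convention so any upstream annotator's output can
# be adapted:
#
#   INFO  GENE=<symbol>          gene symbol                      (required)
#         CSQ=<class>            consequence class, one of
#                                missense|synonymous|stop_gained|frameshift|
#                                inframe_indel|splice_site|intronic|other
#                                                                 (required)
#         PMAF=<float>           global population (gnomAD) allele
#                                frequency; omitted when the variant is
#                                unobserved in population databases
#         CGC                    flag: somatic per Cancer Gene Census
#         COSM                   flag: pathogenic per COSMIC
#         ORIGIN=<str>           somatic_candidate | known_germline
#         HGVSC=/HGVSP=<str>     transcript / protein notation
#   FORMAT AF (Number=A), DP    per-allele allele fraction, total depth
#
# Multi-allelic records are decomposed to one row per ALT with per-allele AF.

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                     "consequence", "vaf", "depth", "popmax_af",
                     "cgc_somatic", "cosmic_pathogenic", "filter_status",
                     "hgvs_c", "hgvs_p", "origin")

#' Construct annotated variant records
#'
#' Builds a one-or-more-row variant table with the package's canonical
#' columns. Arguments recycle, so a vector of positions with a scalar
#' `sample_id` yields several records. Mainly a convenience for tests,
#' examples and simulation.
#'
#' @param sample_id sample identifier.
#' @param chrom,pos,ref,alt 1-based genomic coordinates and alleles.
#' @param gene gene symbol.
#' @param consequence one of `missense`, `synonymous`, `stop_gained`,
#'   `frameshift`, `inframe_indel`, `splice_site`, `intronic`, `other`.
#' @param vaf allele fraction in \[0, 1\].
#' @param depth total read depth.
#' @param popmax_af global population allele frequency, `NA` if unobserved.
#' @param cgc_somatic,cosmic_pathogenic database flags.
#' @param filter_status caller filter string (e.g. `"PASS"`).
#' @param hgvs_c,hgvs_p HGVS transcript / protein notation, `NA` allowed.
#' @param origin `"somatic_candidate"` or `"known_germline"`.
#' @return a data.frame of annotated variants.
#' @export
variant_record <- function(sample_id, chrom = "1", pos = 1000L,
                           ref = "A", alt = "G", gene = "TP53",
                           consequence = "missense", vaf = 0.30,
                           depth = 200L, popmax_af = NA_real_,
                           cgc_somatic = TRUE, cosmic_pathogenic = TRUE,
                           filter_status = "PASS",
                           hgvs_c = NA_character_, hgvs_p = NA_character_,
                           origin = "somatic_candidate") {
  df <- data.frame(sample_id = sample_id, chrom = as.character(chrom),
                   pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
                   consequence = consequence, vaf = as.numeric(vaf),
                   depth = as.integer(depth),
                   popmax_af = as.numeric(popmax_af),
                   cgc_somatic = as.logical(cgc_somatic),
                   cosmic_pathogenic = as.logical(cosmic_pathogenic),
                   filter_status = filter_status,
                   hgvs_c = as.character(hgvs_c),
                   hgvs_p = as.character(hgvs_p),
                   origin = origin, stringsAsFactors = FALSE)
  validate_variants(df)
}

# Empty canonical variant table.
empty_variants <- function() {
  validate_variants(variant_record("x")[0, ])
}

validate_variants <- function(df) {
  check_columns(df, VARIANT_COLUMNS, "variant table")
  df <- df[, VARIANT_COLUMNS]
  if (!nrow(df)) return(df)
  if (any(is.na(df$vaf) | df$vaf < 0 | df$vaf > 1)) {
    stop_input("variant vaf must be in [0, 1]")
  }
  if (any(is.na(df$depth) | df$depth < 0)) stop_input("variant depth must be >= 0")
  if (any(is.na(df$pos) | df$pos < 1)) stop_input("variant pos must be >= 1")
  if (any(df$ref == df$alt)) stop_input("ref and alt alleles must differ")
  bad <- !df$consequence %in% CONSEQUENCES
  if (any(bad)) {
    stop_input("unknown consequence '%s'", df$consequence[bad][1])
  }
  bad <- !(is.na(df$origin) | df$origin %in% ORIGIN_LEVELS)
  if (any(bad)) stop_input("unknown origin '%s'", df$origin[bad][1])
  ok <- is.na(df$popmax_af) | (df$popmax_af >= 0 & df$popmax_af <= 1)
  if (!all(ok)) stop_input("popmax_af must be in [0, 1] or NA")
  rownames(df) <- NULL
  df
}

sanitize_info <- function(x) gsub("[;[:space:]=]", "", x)

#' Write annotated variants to a VCF file
#'
#' Writes one sample's variant table as uncompressed VCF 4.2 using the
#' package's INFO/FORMAT tag convention (see [read_variants()]). The
#' writer is deterministic: identical input produces byte-identical files.
#'
#' @param variants a variant table for a single sample.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  variants <- validate_variants(variants)
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L) {
    stop_input("write_variants expects a single sample, got %d", length(sid))
  }
  if (!length(sid)) sid <- "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oncopanel",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=PMAF,Number=1,Type=Float,Description=\"Global population allele frequency; absent if unobserved\">",
    "##INFO=<ID=CGC,Number=0,Type=Flag,Description=\"Somatic per Cancer Gene Census\">",
    "##INFO=<ID=COSM,Number=0,Type=Flag,Description=\"Pathogenic per COSMIC\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"somatic_candidate or known_germline\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS coding notation\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein notation\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sid, sep = "\t")
  )
  body <- character(0)
  if (nrow(variants)) {
    info <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      parts <- c(sprintf("GENE=%s", sanitize_info(v$gene)),
                 sprintf("CSQ=%s", v$consequence))
      if (!is.na(v$popmax_af)) {
        parts <- c(parts, sprintf("PMAF=%s", format(v$popmax_af, digits = 10,
                                                    scientific = FALSE)))
      }
      if (isTRUE(v$cgc_somatic)) parts <- c(parts, "CGC")
      if (isTRUE(v$cosmic_pathogenic)) parts <- c(parts, "COSM")
      if (!is.na(v$origin)) parts <- c(parts, sprintf("ORIGIN=%s", v$origin))
      if (!is.na(v$hgvs_c)) {
        parts <- c(parts, sprintf("HGVSC=%s", sanitize_info(v$hgvs_c)))
      }
      if (!is.na(v$hgvs_p)) {
        parts <- c(parts, sprintf("HGVSP=%s", sanitize_info(v$hgvs_p)))
      }
      paste(parts, collapse = ";")
    }, "")
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, ".", variants$filter_status, info, "AF:DP",
                  sprintf("%s:%d",
                          vapply(variants$vaf, format, "", digits = 10,
                                 scientific = FALSE),
                          variants$depth),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read annotated variants from a VCF file
#'
#' Reads a VCF 4.2 file annotated with the package's tag convention (see
#' the header written by [write_variants()]): `GENE` and `CSQ` INFO tags
#' and per-sample `AF`/`DP` FORMAT fields are mandatory; `PMAF`, `CGC`,
#' `COSM`, `ORIGIN`, `HGVSC`, `HGVSP` are optional and missing values stay
#' missing (`NA`), never silently defaulted. Multi-allelic records are
#' decomposed into one row per ALT allele with its per-allele AF; records
#' are never dropped, whatever their FILTER value (triage decides later).
#'
#' @param path VCF file (plain or gzipped).
#' @param sample_id sample identifier to assign; defaults to the sample
#'   column name in the VCF.
#' @return a variant table (data.frame), one row per ALT allele.
#' @export
read_variants <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop_format("not a readable VCF: %s (%s)",
                                    path, conditionMessage(e))
  )
  fix <- v@fix
  n <- nrow(fix)
  vcf_samples <- colnames(v@gt)
  vcf_samples <- vcf_samples[vcf_samples != "FORMAT"]
  if (is.null(sample_id)) {
    sample_id <- if (length(vcf_samples)) vcf_samples[1] else
      tools::file_path_sans_ext(basename(path))
  }
  if (n == 0L) {
    out <- empty_variants()
    return(out)
  }
  if (!length(vcf_samples)) {
    stop_schema("VCF has no sample column; FORMAT tags AF and DP are required")
  }
  gt_tag <- function(tag) {
    m <- tryCatch(vcfR::extract.gt(v, element = tag),
                  error = function(e) NULL)
    if (is.null(m)) stop_schema("missing mandatory FORMAT tag: %s", tag)
    m[, 1L]
  }
  af_raw <- gt_tag("AF")
  dp_raw <- gt_tag("DP")
  if (all(is.na(af_raw))) stop_schema("missing mandatory FORMAT tag: AF")
  if (all(is.na(dp_raw))) stop_schema("missing mandatory FORMAT tag: DP")
  info_tag <- function(tag) {
    x <- vcfR::extract.info(v, element = tag)
    if (is.null(x)) rep(NA_character_, n) else as.character(x)
  }
  gene <- info_tag("GENE")
  csq <- info_tag("CSQ")
  for (tag in c(GENE = "GENE", CSQ = "CSQ")) {
    vals <- if (tag == "GENE") gene else csq
    if (all(is.na(vals))) stop_schema("missing mandatory INFO tag: %s", tag)
    if (anyNA(vals)) {
      stop_schema("INFO tag %s missing on record %d", tag, which(is.na(vals))[1])
    }
  }
  pmaf <- suppressWarnings(as.numeric(info_tag("PMAF")))
  origin <- info_tag("ORIGIN")
  hgvs_c <- info_tag("HGVSC")
  hgvs_p <- info_tag("HGVSP")
  info_str <- fix[, "INFO"]
  cgc <- grepl("(^|;)CGC(;|$)", info_str)
  cosm <- grepl("(^|;)COSM(;|$)", info_str)

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  afs <- strsplit(af_raw, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  bad <- lengths(afs) != n_alt
  if (any(bad)) {
    stop_schema("record %d: %d ALT allele(s) but %d AF value(s)",
                which(bad)[1], n_alt[bad][1], lengths(afs)[bad][1])
  }
  idx <- rep.int(seq_len(n), n_alt)
  out <- data.frame(
    sample_id = sample_id,
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"],
    alt = unlist(alts, use.names = FALSE),
    gene = gene[idx],
    consequence = csq[idx],
    vaf = suppressWarnings(as.numeric(unlist(afs, use.names = FALSE))),
    depth = suppressWarnings(as.integer(dp_raw[idx])),
    popmax_af = pmaf[idx],
    cgc_somatic = cgc[idx],
    cosmic_pathogenic = cosm[idx],
    filter_status = fix[idx, "FILTER"],
    hgvs_c = hgvs_c[idx],
    hgvs_p = hgvs_p[idx],
    origin = origin[idx],
    stringsAsFactors = FALSE
  )
  validate_variants(out)
}
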