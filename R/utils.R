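# Shared vocabularies, numeric conventions and small helpers.

# Consequence vocabulary. Driver-eligible classes are the exonic
# non-synonymous classes plus splice sites; coding classes (used for TMB)
# additionally include synonymous.
CONSEQUENCES <- c("missense", "synonymous", "stop_gained", "frameshift",
                  "inframe_indel", "splice_site", "intronic", "other")
DRIVER_CONSEQUENCES <- c("missense", "stop_gained", "frameshift",
                         "inframe_indel", "splice_site")
CODING_CONSEQUENCES <- c(DRIVER_CONSEQUENCES, "synonymous")

STATUS_LEVELS <- c("positive", "negative")
ORIGIN_LEVELS <- c("somatic_candidate", "known_germline")

REJECTION_REASONS <- c("not_pass", "excluded_consequence", "vaf_out_of_range",
                       "low_depth", "common_in_population", "not_cgc_somatic",
                       "not_cosmic_pathogenic")

#' Round half away from zero
#'
#' Display rounding used throughout: ties round away from zero (so 86.65
#' renders as 86.7), unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Integer copy estimate from a fold-change: 2 * fc rounded half away from
# zero, so the gain boundary 1.5 maps to three copies.
copies_from_fc <- function(fold_change) {
  as.integer(floor(2 * fold_change + 0.5))
}

# --- read-length histogram encoding ------------------------------------
# Histograms travel in tables as "length:value" pairs joined by commas,
# e.g. "9:4,10:88,11:8". Values are counts for observations and
# proportions for baselines.

parse_hist <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    stop_schema("empty histogram field")
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop_schema(sprintf("malformed histogram entry '%s'", parts[bad][1]))
  }
  lens <- suppressWarnings(as.integer(vapply(kv, `[[`, "", 1L)))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  if (anyNA(lens) || anyNA(vals)) {
    stop_schema(sprintf("non-numeric histogram entry in '%s'", s))
  }
  stats::setNames(vals, lens)
}

format_hist <- function(h) {
  h <- h[order(as.integer(names(h)))]
  paste(sprintf("%s:%s", names(h), vapply(h, format, "", digits = 10)),
        collapse = ",")
}

# --- HGVS protein-change normalization ----------------------------------

AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
              Ter = "*")

#' Normalize an HGVS protein change to one-letter amino-acid codes
#'
#' Converts three-letter amino-acid codes to one-letter codes (`Ter`
#' becomes `*`), strips surrounding parentheses and whitespace, and keeps
#' positional and suffix tokens (`fs`, `del`, `dup`, `ins`) intact, so that
#' `p.His1047Arg` and `p.H1047R` compare equal.
#'
#' @param x character vector of HGVS protein notations (with or without the
#'   `p.` prefix).
#' @return normalized character vector; `NA` stays `NA`.
#' @examples
#' normalize_hgvs_p(c("p.His1047Arg", "p.(Lys662Ter)", "p.H1047R"))
#' @export
normalize_hgvs_p <- function(x) {
  out <- gsub("[()[:space:]]", "", as.character(x))
  out <- sub("^[Pp]\\.", "", out)
  for (code in names(AA3_TO_1)) {
    out <- gsub(code, AA3_TO_1[[code]], out, ignore.case = TRUE)
  }
  ifelse(is.na(x), NA_character_, paste0("p.", out))
}

# --- classed error helpers ----------------------------------------------

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oncopanel_schema_error", "oncopanel_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oncopanel_input_error", "oncopanel_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oncopanel_format_error", "oncopanel_error")))
}

# Require a set of columns in a data.frame read from disk.
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_schema("%s: missing column(s) %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
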