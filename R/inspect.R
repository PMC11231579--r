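#' Filter records by genomic region
#'
#' Keeps records on `contig` with `start <= POS <= end`, both bounds
#' 1-based and inclusive. Record order is preserved.
#'
#' @param x A `vcf`/`vcf_norm` object or records tibble.
#' @param contig Contig name (exact string match).
#' @param start,end 1-based inclusive bounds in bp.
#' @return The input shape, subset.
#' @export
filter_region <- function(x, contig, start, end) {
  if (start > end) {
    rlang::abort(paste0("Invalid interval: start (", start,
                        ") greater than end (", end, ")."),
                 class = "vcftally_invalid_interval")
  }
  records <- vcf_records(x)
  keep <- records$chrom == contig & records$pos >= start & records$pos <= end
  set_records(x, records[keep, , drop = FALSE])
}

#' Filter records by quality score
#'
#' Keeps records with `QUAL >= min_qual`. Records with missing QUAL (`.`)
#' are dropped unless `keep_missing = TRUE` — the conservative default for
#' quality filtering.
#'
#' @param x A `vcf`/`vcf_norm` object or records tibble.
#' @param min_qual Minimum quality (kept at threshold).
#' @param keep_missing Keep records whose QUAL is missing. Default `FALSE`.
#' @return The input shape, subset.
#' @export
filter_qual <- function(x, min_qual, keep_missing = FALSE) {
  stopifnot(is.finite(min_qual))
  records <- vcf_records(x)
  keep <- !is.na(records$qual) & records$qual >= min_qual
  if (keep_missing) keep <- keep | is.na(records$qual)
  set_records(x, records[keep, , drop = FALSE])
}

#' Filter records by variant class
#'
#' Keeps records whose class is in `classes`. The grouping names `snp`
#' (= transition + transversion) and `indel` (= insertion + deletion) are
#' accepted and expanded. Requires classified input; a raw `vcf` is
#' normalized first.
#'
#' @param x A `vcf_norm`, or anything [normalize_variants()] accepts.
#' @param classes Character vector of class names (case-insensitive); see
#'   [variant_classes]. Unknown names error, listing the valid ones.
#' @return A `vcf_norm`, subset.
#' @export
filter_class <- function(x, classes) {
  wanted <- expand_class_names(classes)
  norm <- normalize_variants(x)
  keep <- norm$records$class %in% wanted
  set_records(norm, norm$records[keep, , drop = FALSE])
}

#' Keyword search over a fixed VCF column
#'
#' Substring containment match on the verbatim text of one of the eight
#' fixed columns (INFO is searched as its raw string). Case-insensitive by
#' default; set `regex = TRUE` for regular-expression matching. The empty
#' pattern matches everything.
#'
#' @param x A `vcf`/`vcf_norm` object or records tibble.
#' @param column One of CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO
#'   (case-insensitive). Unknown columns error, listing the valid names.
#' @param pattern Search string.
#' @param case_insensitive Default `TRUE`.
#' @param regex Interpret `pattern` as a regular expression. Default
#'   `FALSE` (plain substring).
#' @return The input shape, subset.
#' @export
search_keyword <- function(x, column, pattern, case_insensitive = TRUE,
                           regex = FALSE) {
  fixed_cols <- c(CHROM = "chrom", POS = "pos", ID = "id", REF = "ref",
                  ALT = "alt", QUAL = "qual", FILTER = "filter", INFO = "info")
  col <- fixed_cols[toupper(column)]
  if (is.na(col)) {
    rlang::abort(paste0("Unknown column '", column, "'. Valid columns: ",
                        paste(names(fixed_cols), collapse = ", ")),
                 class = "vcftally_unknown_column")
  }
  records <- vcf_records(x)
  text <- records[[col]]
  if (col == "qual") text <- ifelse(is.na(text), ".", format_num(text))
  if (col == "pos") text <- format_num(text)
  if (!nzchar(pattern)) return(set_records(x, records))
  pat <- if (regex) {
    stringr::regex(pattern, ignore_case = case_insensitive)
  } else {
    stringr::fixed(pattern, ignore_case = case_insensitive)
  }
  keep <- stringr::str_detect(text, pat)
  set_records(x, records[keep, , drop = FALSE])
}

#' Sort records by position or quality
#'
#' Stable sort: ties preserve input order, and records with missing QUAL
#' sort last regardless of direction.
#'
#' @param x A `vcf`/`vcf_norm` object or records tibble.
#' @param by `"POS"` or `"QUAL"` (case-insensitive).
#' @param descending Default `FALSE`.
#' @return The input shape, reordered.
#' @export
sort_records <- function(x, by = c("POS", "QUAL"), descending = FALSE) {
  by <- toupper(by)
  by <- match.arg(by, c("POS", "QUAL"))
  records <- vcf_records(x)
  v <- if (by == "POS") records$pos else records$qual
  key <- if (descending) -xtfrm(v) else xtfrm(v)
  ord <- order(is.na(v), key, method = "radix")  # missing last, stable
  set_records(x, records[ord, , drop = FALSE])
}
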