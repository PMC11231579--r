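#' Read a VCF file
#'
#' Parses a Variant Call Format (v4.x) file into a `vcf` object: a list of
#' meta-information lines, header column names, and a tibble of records.
#' Compression is auto-detected from the leading magic bytes (gzip
#' `0x1f 0x8b`, which also covers bgzip), never from the file extension.
#'
#' Only the eight fixed columns (CHROM, POS, ID, REF, ALT, QUAL, FILTER,
#' INFO) are interpreted; any FORMAT/sample columns are carried verbatim in
#' the `trailing` list-column and never touched, so a read/write round trip
#' preserves them exactly.
#'
#' @param path Path to a plain, gzip- or bgzip-compressed VCF file.
#' @param skip_malformed If `FALSE` (default) a malformed data line (fewer
#'   than 8 tab-separated fields, or a POS that is not a positive integer)
#'   aborts with its line number. If `TRUE`, malformed lines are skipped and
#'   counted in the `n_skipped` field of the result.
#' @return A `vcf` object with components `meta` (tibble: `key`,
#'   `entry_id`, `description`, `raw_text`), `header_cols`, `records`
#'   (tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `filter`, `info`, `trailing`), `source_name`, and `n_skipped`.
#' @examples
#' path <- tempfile(fileext = ".vcf")
#' spec <- fixture_spec(n_transition = 2, n_transversion = 1, seed = 1)
#' write_vcf(generate_vcf(spec)$vcf, path)
#' v <- read_vcf(path)
#' v$records
#' @export
read_vcf <- function(path, skip_malformed = FALSE) {
  con <- open_vcf_connection(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  parse_vcf_lines(lines, source_name = basename(path),
                  skip_malformed = skip_malformed)
}

# gzip magic bytes 1f 8b (bgzip is a gzip variant and matches too)
open_vcf_connection <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("VCF file not found: ", path), class = "vcftally_io_error")
  }
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
}

parse_vcf_lines <- function(lines, source_name = "<stream>", skip_malformed = FALSE) {
  is_meta <- startsWith(lines, "##")
  header_at <- which(startsWith(lines, "#") & !is_meta)
  if (length(header_at) == 0L) {
    rlang::abort(
      "No #CHROM header line found; not a VCF file.",
      class = "vcftally_missing_header"
    )
  }
  header_at <- header_at[1]
  meta_lines <- lines[seq_len(header_at - 1L)]
  meta_lines <- meta_lines[startsWith(meta_lines, "##")]
  header_cols <- strsplit(sub("^#", "", lines[header_at]), "\t", fixed = TRUE)[[1]]

  body_idx <- seq.int(header_at + 1L, length.out = max(0L, length(lines) - header_at))
  body <- lines[body_idx]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_lineno <- body_idx[keep]

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  pos_txt <- vapply(fields, function(f) if (length(f) >= 2L) f[[2]] else NA_character_, "")
  pos_ok <- grepl("^[0-9]+$", pos_txt) & !is.na(pos_txt)
  bad <- nf < 8L | !pos_ok
  if (any(bad)) {
    if (!skip_malformed) {
      i <- which(bad)[1]
      reason <- if (nf[i] < 8L) {
        paste0("only ", nf[i], " tab-separated fields (8 required)")
      } else {
        paste0("POS '", pos_txt[i], "' is not a positive integer")
      }
      rlang::abort(
        paste0("Malformed VCF record at line ", body_lineno[i], ": ", reason),
        class = "vcftally_malformed_record"
      )
    }
    fields <- fields[!bad]
    body_lineno <- body_lineno[!bad]
  }
  n_skipped <- sum(bad)

  pos <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (any(pos < 1)) {
    i <- which(pos < 1)[1]
    if (!skip_malformed) {
      rlang::abort(
        paste0("Malformed VCF record at line ", body_lineno[i],
               ": POS must be >= 1"),
        class = "vcftally_malformed_record"
      )
    }
    keep2 <- pos >= 1
    n_skipped <- n_skipped + sum(!keep2)
    fields <- fields[keep2]
    pos <- pos[keep2]
  }

  qual_txt <- vapply(fields, `[[`, "", 6L)
  qual <- suppressWarnings(as.numeric(qual_txt))
  qual[qual_txt == "."] <- NA_real_

  records <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    pos = pos,
    id = vapply(fields, `[[`, "", 3L),
    ref = vapply(fields, `[[`, "", 4L),
    alt = vapply(fields, `[[`, "", 5L),
    qual = qual,
    filter = vapply(fields, `[[`, "", 7L),
    info = vapply(fields, `[[`, "", 8L),
    trailing = lapply(fields, function(f) {
      if (length(f) > 8L) f[-seq_len(8L)] else character(0)
    })
  )

  new_vcf(
    meta = parse_meta_lines(meta_lines),
    header_cols = header_cols,
    records = records,
    source_name = source_name,
    n_skipped = n_skipped
  )
}

new_vcf <- function(meta, header_cols, records, source_name,
                    n_skipped = 0L, ...) {
  structure(
    list(meta = meta, header_cols = header_cols, records = records,
         source_name = source_name, n_skipped = n_skipped, ...),
    class = "vcf"
  )
}

#' @export
print.vcf <- function(x, ...) {
  cat("<vcf> ", x$source_name, ": ", nrow(x$records), " record(s), ",
      nrow(x$meta), " meta line(s)\n", sep = "")
  print(x$records, ...)
  invisible(x)
}

# Meta lines: "##key=value"; structured values "<ID=...,Description=...>".
parse_meta_lines <- function(lines) {
  if (length(lines) == 0L) {
    return(tibble::tibble(key = character(), entry_id = character(),
                          description = character(), raw_text = character()))
  }
  body <- sub("^##", "", lines)
  eq <- regexpr("=", body, fixed = TRUE)
  key <- ifelse(eq > 0L, substr(body, 1L, eq - 1L), body)
  value <- ifelse(eq > 0L, substr(body, eq + 1L, nchar(body)), "")
  structured <- startsWith(value, "<")
  entry_id <- rep(NA_character_, length(lines))
  description <- rep(NA_character_, length(lines))
  has_id <- structured & grepl("(^<|,)ID=", value)
  m <- regmatches(value[has_id],
                  regexpr("(?<=[<,])ID=[^,>]+", value[has_id], perl = TRUE))
  entry_id[has_id] <- sub("^ID=", "", m)
  dm <- regmatches(value, regexpr('Description="[^"]*"', value))
  has_desc <- grepl('Description="', value, fixed = TRUE)
  description[has_desc] <- sub('^Description="(.*)"$', "\\1", dm)
  tibble::tibble(key = key, entry_id = entry_id,
                 description = description, raw_text = lines)
}

#' Extract VCF meta-information as a searchable table
#'
#' Returns one row per `##` meta line, in file order, with the key (the part
#' between `##` and `=`), the `ID=` entry of structured lines (INFO, FORMAT,
#' FILTER, ALT, contig), the `Description=` text, and the raw line. Any
#' column can then be searched with ordinary string tools.
#'
#' @param x A `vcf` object, or a meta tibble already extracted.
#' @param pattern Optional substring; keeps rows where any column contains it
#'   (case-insensitive).
#' @return A tibble with columns `key`, `entry_id`, `description`,
#'   `raw_text`.
#' @export
extract_metadata <- function(x, pattern = NULL) {
  meta <- if (inherits(x, "vcf")) x$meta else tibble::as_tibble(x)
  if (!is.null(pattern) && nzchar(pattern)) {
    hit <- Reduce(`|`, lapply(meta, function(col) {
      stringr::str_detect(tolower(as.character(col)), stringr::fixed(tolower(pattern))) &
        !is.na(col)
    }))
    meta <- meta[which(hit), , drop = FALSE]
  }
  meta
}

#' Write a `vcf` object to disk
#'
#' Emits meta lines, the `#CHROM` header, and tab-separated records. Missing
#' QUAL is written as `.`; trailing FORMAT/sample columns are emitted
#' verbatim. Reading the result back yields a dataset field-identical on the
#' eight fixed columns and the trailing columns.
#'
#' @param x A `vcf` object (or normalized `vcf_norm`).
#' @param path Output path. Written as plain text.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  records <- vcf_records(x)
  qual_txt <- ifelse(is.na(records$qual), ".", format_num(records$qual))
  fixed <- paste(records$chrom, format_num(records$pos), records$id,
                 records$ref, records$alt, qual_txt, records$filter,
                 records$info, sep = "\t")
  tail_txt <- vapply(records$trailing, function(tr) {
    if (length(tr) == 0L) "" else paste0("\t", paste(tr, collapse = "\t"))
  }, "")
  meta <- if (is.null(x$meta)) character(0) else x$meta$raw_text
  header_cols <- x$header_cols
  if (is.null(header_cols)) {
    header_cols <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  }
  lines <- c(meta,
             paste0("#", paste(header_cols, collapse = "\t")),
             paste0(fixed, tail_txt))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Write any result table as CSV
#'
#' RFC-4180-style CSV with a header row; fields containing commas or quotes
#' are quoted. A thin wrapper over [readr::write_csv()] that first flattens
#' `vcf` objects and list-columns to plain text.
#'
#' @param x A data frame, or a `vcf`/`vcf_norm` object (its records are
#'   written, trailing columns collapsed with tabs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(x, path) {
  if (inherits(x, "vcf")) x <- vcf_records(x)
  x <- tibble::as_tibble(x)
  is_list <- vapply(x, is.list, TRUE)
  x[is_list] <- lapply(x[is_list], function(col) {
    vapply(col, function(v) paste(as.character(v), collapse = "\t"), "")
  })
  readr::write_csv(x, path)
  invisible(path)
}

# Records tibble from a vcf/vcf_norm object or a bare data frame.
vcf_records <- function(x) {
  if (inherits(x, "vcf")) x$records else tibble::as_tibble(x)
}

# Rebuild an object of the same shape with new records.
set_records <- function(x, records) {
  if (inherits(x, "vcf")) {
    x$records <- records
    x
  } else {
    records
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.vcf <- function(x, ...) x$records

#' @export
glance.vcf <- function(x, ...) {
  tibble::tibble(
    source_name = x$source_name,
    n_records = nrow(x$records),
    n_meta = nrow(x$meta),
    n_contigs = dplyr::n_distinct(x$records$chrom),
    n_skipped = x$n_skipped
  )
}
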