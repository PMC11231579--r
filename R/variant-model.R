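#' Variant classes
#'
#' The taxonomy used throughout the package, in canonical order. `snp` and
#' `indel` are grouping names (`snp = transition + transversion`,
#' `indel = insertion + deletion`) accepted by [filter_class()] but never
#' assigned to a record.
#'
#' @export
variant_classes <- c("transition", "transversion", "insertion",
                     "deletion", "mnp", "assorted")

#' Classify a REF/ALT allele pair
#'
#' Deterministic rule ladder applied to uppercased alleles, in order:
#'
#' 1. ALT symbolic (`<...>`, a breakend containing `[` or `]`, `*`, or `.`),
#'    or either allele contains a character outside `{A,C,G,T}` (including
#'    `N`) — `assorted`.
#' 2. Both alleles single bases — a SNP: `transition` when both are purines
#'    (`A`/`G`) or both pyrimidines (`C`/`T`), else `transversion`.
#' 3. Equal lengths (both > 1) — `mnp`.
#' 4. Unequal lengths — `insertion` when ALT is longer, else `deletion`.
#'    Neither allele is required to be a prefix of the other.
#'
#' @param ref,alt Character vectors of single alleles (no commas in `alt`);
#'   recycled to a common length.
#' @return Character vector of class labels from [variant_classes].
#' @examples
#' classify_variant("A", "G")            # transition
#' classify_variant("A", c("C", "ACG"))  # transversion, insertion
#' @export
classify_variant <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    rlang::abort("Empty REF or ALT allele.", class = "vcftally_malformed_allele")
  }
  symbolic <- startsWith(alt, "<") | grepl("[][]", alt) | alt == "*" | alt == "."
  nonacgt <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  out <- rep(NA_character_, n)
  assorted <- symbolic | nonacgt
  out[assorted] <- "assorted"
  todo <- !assorted
  lr <- nchar(ref)
  la <- nchar(alt)
  snp <- todo & lr == 1L & la == 1L
  ts <- snp & ((ref %in% c("A", "G") & alt %in% c("A", "G")) |
                 (ref %in% c("C", "T") & alt %in% c("C", "T")))
  out[ts] <- "transition"
  out[snp & !ts] <- "transversion"
  out[todo & !snp & lr == la] <- "mnp"
  out[todo & la > lr] <- "insertion"
  out[todo & la < lr & !(lr == 1L & la == 1L)] <- "deletion"
  out
}

#' Signed INDEL size in bp
#'
#' `nchar(alt) - nchar(ref)`: positive for insertions, negative for
#' deletions. Calling it on alleles that do not classify as an insertion or
#' deletion is a contract violation and errors.
#'
#' @inheritParams classify_variant
#' @return Integer vector of signed sizes.
#' @export
indel_size <- function(ref, alt) {
  cls <- classify_variant(ref, alt)
  if (any(!cls %in% c("insertion", "deletion"))) {
    rlang::abort("indel_size() called on a non-INDEL allele pair.",
                 class = "vcftally_contract_violation")
  }
  nchar(toupper(alt)) - nchar(toupper(ref))
}

#' Split multiallelic sites into single-ALT records
#'
#' Each record whose ALT column lists k comma-separated alleles becomes k
#' records differing only in ALT, each flagged `from_multiallelic` when
#' k > 1. All other columns are copied verbatim; file order (and allele
#' order within a site) is preserved.
#'
#' @param x A `vcf` object or records tibble.
#' @return An object of the input's shape whose records all have a single
#'   ALT, with a `from_multiallelic` column; the number of multiallelic
#'   input sites is attached as attribute `n_multiallelic_sites` of the
#'   records tibble.
#' @export
split_multiallelic <- function(x) {
  records <- vcf_records(x)
  alts <- strsplit(records$alt, ",", fixed = TRUE)
  k <- lengths(alts)
  k[k == 0L] <- 1L  # ALT "" kept as one (malformed-ish) allele
  alts[lengths(alts) == 0L] <- list("")
  idx <- rep.int(seq_len(nrow(records)), k)
  out <- records[idx, , drop = FALSE]
  out$alt <- as.character(unlist(alts, use.names = FALSE))
  out$from_multiallelic <- rep.int(k > 1L, k)
  out <- tibble::as_tibble(out)
  attr(out, "n_multiallelic_sites") <- sum(k > 1L)
  set_records(x, out)
}

#' Remove duplicate variant keys
#'
#' The identity of a normalized variant is its key
#' `(CHROM, POS, REF, ALT)` with alleles compared case-insensitively; ID,
#' QUAL, FILTER and INFO never affect identity. The first occurrence in file
#' order is kept; later records with the same key are dropped and counted.
#'
#' @param x A `vcf` object or records tibble whose records all carry a
#'   single ALT allele (see [split_multiallelic()]).
#' @return Input shape with duplicates removed; the records tibble carries
#'   attribute `n_duplicates_removed`.
#' @export
deduplicate <- function(x) {
  records <- vcf_records(x)
  if (any(grepl(",", records$alt, fixed = TRUE))) {
    rlang::abort("deduplicate() requires single-ALT records; run split_multiallelic() first.",
                 class = "vcftally_contract_violation")
  }
  key <- variant_key(records)
  dup <- duplicated(key)
  out <- records[!dup, , drop = FALSE]
  attr(out, "n_multiallelic_sites") <- attr(records, "n_multiallelic_sites")
  attr(out, "n_duplicates_removed") <- sum(dup)
  set_records(x, out)
}

variant_key <- function(records) {
  paste(records$chrom, format_num(records$pos),
        toupper(records$ref), toupper(records$alt), sep = "\r")
}

#' Normalize a VCF dataset
#'
#' Normalization in the sense used for variant tallying: split comma-
#' separated multiallelic sites into individual single-ALT entries, then
#' remove duplicate `(CHROM, POS, REF, ALT)` keys (keep-first), and classify
#' every surviving record. Alleles are uppercased once here. No
#' left-alignment or allele trimming is performed — representation-level
#' normalization against a reference genome is out of scope.
#'
#' @param x A `vcf` object (from [read_vcf()] or [generate_vcf()]) or a
#'   records tibble.
#' @return A `vcf_norm` object: the input with records replaced by
#'   normalized records (extra columns `from_multiallelic` and `class`) and
#'   counters `n_multiallelic_sites` and `n_duplicates_removed`.
#' @examples
#' v <- generate_vcf(fixture_spec(n_transition = 3, n_multiallelic_sites = 1,
#'                                n_transversion = 2, seed = 42))$vcf
#' n <- normalize_variants(v)
#' n$n_multiallelic_sites
#' @export
normalize_variants <- function(x) {
  if (inherits(x, "vcf_norm")) return(x)
  split <- split_multiallelic(vcf_records(x))
  deduped <- deduplicate(split)
  deduped$ref <- toupper(deduped$ref)
  deduped$alt <- toupper(deduped$alt)
  deduped$class <- classify_variant(deduped$ref, deduped$alt)
  meta <- if (inherits(x, "vcf")) x$meta else parse_meta_lines(character(0))
  out <- new_vcf(
    meta = meta,
    header_cols = if (inherits(x, "vcf")) x$header_cols else
      c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
    records = tibble::as_tibble(deduped),
    source_name = if (inherits(x, "vcf")) x$source_name else "<records>",
    n_skipped = if (inherits(x, "vcf")) x$n_skipped else 0L,
    n_multiallelic_sites = attr(deduped, "n_multiallelic_sites") %||% 0L,
    n_duplicates_removed = attr(deduped, "n_duplicates_removed") %||% 0L
  )
  class(out) <- c("vcf_norm", "vcf")
  out
}

#' @export
print.vcf_norm <- function(x, ...) {
  cat("<vcf_norm> ", x$source_name, ": ", nrow(x$records),
      " normalized record(s); ", x$n_multiallelic_sites,
      " multiallelic site(s) split, ", x$n_duplicates_removed,
      " duplicate(s) removed\n", sep = "")
  print(x$records, ...)
  invisible(x)
}

#' @export
glance.vcf_norm <- function(x, ...) {
  tibble::tibble(
    source_name = x$source_name,
    n_records = nrow(x$records),
    n_multiallelic_sites = x$n_multiallelic_sites,
    n_duplicates_removed = x$n_duplicates_removed,
    n_skipped = x$n_skipped
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
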