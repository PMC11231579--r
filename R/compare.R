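#' Compare two VCF datasets by variant key
#'
#' Membership is decided purely by the normalized variant key
#' `(CHROM, POS, REF, ALT)`; ID, QUAL, FILTER and INFO never affect it.
#' Shared records carry the columns of `a` (deterministic provenance). Both
#' inputs are normalized first if they are not already.
#'
#' When the contig vocabularies of the two files are disjoint — typically a
#' `chr1` vs `1` naming mismatch — a warning is raised; set
#' `harmonize_chr_prefix = TRUE` to strip a leading `"chr"` from both sides
#' before matching (matching only; the emitted records keep their original
#' contig names).
#'
#' @param a,b `vcf`/`vcf_norm` objects or records tibbles.
#' @param harmonize_chr_prefix Strip a leading `"chr"` from contig names
#'   before matching. Default `FALSE`: exact string match.
#' @return A `vcf_cmp` object: `shared`, `unique_a`, `unique_b` (each a
#'   `vcf_norm`), `venn` (tibble `set`, `label`, `count`), `n_shared`,
#'   `n_a_only`, `n_b_only`, `pct_of_a`, `pct_of_b` (percent of each input
#'   found in the other; `NA` when that input is empty), and `summaries`
#'   (list of `vcf_summary` for the three sets).
#' @examples
#' p <- generate_pair(n_shared = 2, n_a_only = 1, n_b_only = 1, seed = 3)
#' cmp <- compare_vcf(p$a, p$b)
#' tidy(cmp)
#' @export
compare_vcf <- function(a, b, harmonize_chr_prefix = FALSE) {
  a <- normalize_variants(a)
  b <- normalize_variants(b)
  chrom_a <- a$records$chrom
  chrom_b <- b$records$chrom
  if (harmonize_chr_prefix) {
    chrom_a <- sub("^chr", "", chrom_a)
    chrom_b <- sub("^chr", "", chrom_b)
  } else if (nrow(a$records) > 0 && nrow(b$records) > 0 &&
             length(intersect(unique(chrom_a), unique(chrom_b))) == 0L) {
    rlang::warn(paste0(
      "The contig name vocabularies of the two datasets are disjoint ",
      "(e.g. '", chrom_a[1], "' vs '", chrom_b[1], "'); ",
      "this usually signals a 'chr' prefix mismatch. ",
      "Consider harmonize_chr_prefix = TRUE."),
      class = "vcftally_disjoint_contigs")
  }
  key_a <- paste(chrom_a, format_num(a$records$pos),
                 toupper(a$records$ref), toupper(a$records$alt), sep = "\r")
  key_b <- paste(chrom_b, format_num(b$records$pos),
                 toupper(b$records$ref), toupper(b$records$alt), sep = "\r")
  in_b <- key_a %in% key_b
  in_a <- key_b %in% key_a

  subset_norm <- function(x, keep, name) {
    x$records <- x$records[keep, , drop = FALSE]
    x$source_name <- name
    x
  }
  shared <- subset_norm(a, in_b, paste0("shared(", a$source_name, ")"))
  unique_a <- subset_norm(a, !in_b, paste0("unique(", a$source_name, ")"))
  unique_b <- subset_norm(b, !in_a, paste0("unique(", b$source_name, ")"))

  n_shared <- sum(in_b)
  n_a_only <- sum(!in_b)
  n_b_only <- sum(!in_a)
  venn <- tibble::tibble(
    set = c("a_only", "b_only", "shared"),
    label = c(a$source_name, b$source_name,
              paste(a$source_name, b$source_name, sep = " & ")),
    count = c(n_a_only, n_b_only, n_shared)
  )
  structure(
    list(
      shared = shared, unique_a = unique_a, unique_b = unique_b,
      venn = venn,
      n_shared = n_shared, n_a_only = n_a_only, n_b_only = n_b_only,
      pct_of_a = if (nrow(a$records) == 0) NA_real_ else
        100 * n_shared / nrow(a$records),
      pct_of_b = if (nrow(b$records) == 0) NA_real_ else
        100 * n_shared / nrow(b$records),
      summaries = list(shared = summarize_variants(shared),
                       unique_a = summarize_variants(unique_a),
                       unique_b = summarize_variants(unique_b))
    ),
    class = "vcf_cmp"
  )
}

#' Venn counts of a comparison
#'
#' The three disjoint counts (unique to A, unique to B, shared) with their
#' source labels, as a tibble ready for CSV/JSON export. Only the counts are
#' produced; area-proportional diagram geometry is out of scope.
#'
#' @param x A `vcf_cmp` object from [compare_vcf()].
#' @return A tibble with columns `set`, `label`, `count`.
#' @export
venn_counts <- function(x) {
  stopifnot(inherits(x, "vcf_cmp"))
  x$venn
}

#' @export
print.vcf_cmp <- function(x, ...) {
  cat("<vcf_cmp> shared ", x$n_shared, "; unique to A ", x$n_a_only,
      "; unique to B ", x$n_b_only, "\n", sep = "")
  cat("  overlap: ",
      if (is.na(x$pct_of_a)) "NA" else sprintf("%.2f%% of A", x$pct_of_a), ", ",
      if (is.na(x$pct_of_b)) "NA" else sprintf("%.2f%% of B", x$pct_of_b),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.vcf_cmp <- function(x, ...) x$venn

#' @export
glance.vcf_cmp <- function(x, ...) {
  tibble::tibble(
    n_a = x$n_a_only + x$n_shared,
    n_b = x$n_b_only + x$n_shared,
    n_shared = x$n_shared,
    n_a_only = x$n_a_only,
    n_b_only = x$n_b_only,
    pct_of_a = x$pct_of_a,
    pct_of_b = x$pct_of_b
  )
}
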