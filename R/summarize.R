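#' Summarize a normalized dataset
#'
#' Tallies unique (normalized) variants per contig and per class, and
#' derives the headline statistics: total count, SNP and INDEL group counts,
#' the transition/transversion ratio (Ts/Tv), per-class percentages, plus
#' the multiallelic-site and duplicates-removed counters carried over from
#' normalization. Counts are exact; percentages are rounded only when
#' printed.
#'
#' @param x A `vcf_norm` object, or anything [normalize_variants()] accepts
#'   (normalized on the fly).
#' @return A `vcf_summary` object with components `per_contig` (tibble:
#'   `contig`, one column per class, `total`; contigs in order of first
#'   appearance), `totals` (named integer vector over [variant_classes]),
#'   `n_total`, `n_snp`, `n_indel`, `ts_tv` (`NA` when there are no
#'   transversions), `percentages`, `n_multiallelic_sites`,
#'   `n_duplicates_removed`.
#' @examples
#' v <- generate_vcf(fixture_spec(n_transition = 3, n_transversion = 1,
#'                                n_insertion = 2, seed = 7))$vcf
#' s <- summarize_variants(v)
#' glance(s)
#' @export
summarize_variants <- function(x) {
  norm <- normalize_variants(x)
  records <- norm$records
  cls <- factor(records$class, levels = variant_classes)
  contig <- factor(records$chrom, levels = unique(records$chrom))
  tab <- table(contig, cls)
  per_contig <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "contig")
  per_contig$total <- rowSums(tab)
  totals <- colSums(tab)
  n_total <- sum(totals)
  ts <- totals[["transition"]]
  tv <- totals[["transversion"]]
  structure(
    list(
      source_name = norm$source_name,
      per_contig = per_contig,
      totals = totals,
      n_total = n_total,
      n_snp = ts + tv,
      n_indel = totals[["insertion"]] + totals[["deletion"]],
      ts_tv = if (tv == 0) NA_real_ else ts / tv,
      percentages = if (n_total == 0) totals * NA_real_ else 100 * totals / n_total,
      n_multiallelic_sites = norm$n_multiallelic_sites,
      n_duplicates_removed = norm$n_duplicates_removed
    ),
    class = "vcf_summary"
  )
}

#' @export
print.vcf_summary <- function(x, ...) {
  cat("<vcf_summary> ", x$source_name, "\n", sep = "")
  cat("  total variants: ", x$n_total,
      "  (SNP ", x$n_snp, ", INDEL ", x$n_indel, ")\n", sep = "")
  cat("  Ts/Tv: ", if (is.na(x$ts_tv)) "NA" else sprintf("%.2f", x$ts_tv),
      "\n", sep = "")
  cat("  multiallelic sites: ", x$n_multiallelic_sites,
      "; duplicates removed: ", x$n_duplicates_removed, "\n", sep = "")
  print(x$per_contig, ...)
  invisible(x)
}

#' @describeIn summarize_variants Long-format counts: one row per
#'   (contig, class) with `count`, ready for plotting or CSV export.
#' @param ... Unused.
#' @export
tidy.vcf_summary <- function(x, ...) {
  tidyr::pivot_longer(x$per_contig, cols = dplyr::all_of(variant_classes),
                      names_to = "class", values_to = "count") |>
    dplyr::select(dplyr::all_of(c("contig", "class", "count")))
}

#' @describeIn summarize_variants One-row digest of the headline numbers.
#' @export
glance.vcf_summary <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_snp = x$n_snp,
    n_transition = x$totals[["transition"]],
    n_transversion = x$totals[["transversion"]],
    n_indel = x$n_indel,
    n_insertion = x$totals[["insertion"]],
    n_deletion = x$totals[["deletion"]],
    n_mnp = x$totals[["mnp"]],
    n_assorted = x$totals[["assorted"]],
    ts_tv = x$ts_tv,
    pct_snp = unname(if (x$n_total == 0) NA_real_ else 100 * x$n_snp / x$n_total),
    n_multiallelic_sites = x$n_multiallelic_sites,
    n_duplicates_removed = x$n_duplicates_removed
  )
}

#' Transition/transversion ratio
#'
#' The standard variant-calling QC metric: transitions divided by
#' transversions. `NA` (never an error or `Inf`) when there are no
#' transversions; 0 when there are transversions but no transitions.
#'
#' @param x A `vcf_summary`, or anything [summarize_variants()] accepts.
#' @return A single numeric value, or `NA`.
#' @export
ts_tv_ratio <- function(x) {
  if (!inherits(x, "vcf_summary")) x <- summarize_variants(x)
  x$ts_tv
}

#' Windowed variant density
#'
#' Counts normalized variants in fixed-size genomic windows anchored at
#' position 1: window k spans `[(k-1)*window_bp + 1, k*window_bp]`, so a
#' record at position p falls in window `ceiling(p / window_bp)`. For each
#' contig, every window from 1 up to the last occupied window is emitted,
#' including zero-count windows (needed for gap detection).
#'
#' @param x A `vcf_norm`, or anything [normalize_variants()] accepts.
#' @param window_bp Window size in bp (default 1 Mbp).
#' @param class_filter Optional character vector of classes (grouping names
#'   `snp`/`indel` accepted) to restrict the counts to.
#' @return A tibble with columns `contig`, `window_index` (1-based),
#'   `start`, `end` (1-based inclusive bp), `count`.
#' @export
window_density <- function(x, window_bp = 1e6, class_filter = NULL) {
  stopifnot(window_bp >= 1)
  norm <- normalize_variants(x)
  records <- norm$records
  if (!is.null(class_filter)) {
    records <- records[records$class %in% expand_class_names(class_filter), ,
                       drop = FALSE]
  }
  contigs <- unique(norm$records$chrom)
  out <- lapply(contigs, function(ctg) {
    p <- records$pos[records$chrom == ctg]
    if (length(p) == 0L) {
      return(tibble::tibble(contig = character(), window_index = integer(),
                            start = numeric(), end = numeric(), count = integer()))
    }
    w <- ceiling(p / window_bp)
    last <- max(w)
    counts <- tabulate(w, nbins = last)
    idx <- seq_len(last)
    tibble::tibble(contig = ctg, window_index = idx,
                   start = (idx - 1) * window_bp + 1, end = idx * window_bp,
                   count = counts)
  })
  dplyr::bind_rows(out)
}

expand_class_names <- function(classes) {
  classes <- tolower(classes)
  valid <- c(variant_classes, "snp", "indel")
  bad <- setdiff(classes, valid)
  if (length(bad) > 0L) {
    rlang::abort(
      paste0("Unknown variant class: ", paste(bad, collapse = ", "),
             ". Valid names: ", paste(valid, collapse = ", ")),
      class = "vcftally_unknown_class"
    )
  }
  out <- setdiff(classes, c("snp", "indel"))
  if ("snp" %in% classes) out <- c(out, "transition", "transversion")
  if ("indel" %in% classes) out <- c(out, "insertion", "deletion")
  unique(out)
}

#' INDEL size distribution
#'
#' Histogram of signed INDEL sizes (`nchar(ALT) - nchar(REF)`) over all
#' insertion and deletion records, with the largest insertion and deletion
#' sizes.
#'
#' @param x A `vcf_norm`, or anything [normalize_variants()] accepts.
#' @return An `indel_dist` object: `sizes` (tibble `size`, `count`, sorted
#'   by size), `max_insertion` (largest positive size, `NA` if none),
#'   `max_deletion` (absolute value of the most negative size, `NA` if
#'   none), `n_indel`.
#' @export
indel_size_distribution <- function(x) {
  norm <- normalize_variants(x)
  rec <- norm$records
  ind <- rec[rec$class %in% c("insertion", "deletion"), , drop = FALSE]
  size <- nchar(ind$alt) - nchar(ind$ref)
  tab <- table(size)
  sizes <- tibble::tibble(size = as.integer(names(tab)),
                          count = as.integer(tab))
  sizes <- sizes[order(sizes$size), , drop = FALSE]
  structure(
    list(
      sizes = sizes,
      max_insertion = if (any(size > 0)) max(size) else NA_integer_,
      max_deletion = if (any(size < 0)) abs(min(size)) else NA_integer_,
      n_indel = length(size)
    ),
    class = "indel_dist"
  )
}

#' @export
print.indel_dist <- function(x, ...) {
  cat("<indel_dist> ", x$n_indel, " INDEL(s); max insertion ",
      x$max_insertion, " bp, max deletion ", x$max_deletion, " bp\n", sep = "")
  print(x$sizes, ...)
  invisible(x)
}

#' @export
tidy.indel_dist <- function(x, ...) x$sizes

#' @export
glance.indel_dist <- function(x, ...) {
  tibble::tibble(n_indel = x$n_indel,
                 max_insertion = x$max_insertion,
                 max_deletion = x$max_deletion)
}

#' Longest run of variant-free windows on a contig
#'
#' Scans a window-density table for the longest run of consecutive
#' zero-count windows strictly between the first and last occupied windows
#' of a contig (leading and trailing emptiness is indistinguishable from
#' unassembled or unplaced sequence without a reference, so it is not
#' counted).
#'
#' @param density A tibble from [window_density()] (zero windows emitted).
#' @param contig Contig name to scan.
#' @return A one-row tibble: `contig`, `gap_windows` (length of the longest
#'   zero run), `gap_bp` (its inclusive bp span; 0 when there is no gap),
#'   `gap_start`, `gap_end` (bp bounds of the longest gap, `NA` when none).
#' @export
longest_empty_gap <- function(density, contig) {
  d <- density[density$contig == contig, , drop = FALSE]
  if (nrow(d) == 0L) {
    rlang::abort(
      paste0("Contig '", contig, "' not present. Available: ",
             paste(unique(density$contig), collapse = ", ")),
      class = "vcftally_unknown_contig"
    )
  }
  d <- d[order(d$window_index), , drop = FALSE]
  occupied <- which(d$count > 0)
  if (length(occupied) < 2L) {
    return(tibble::tibble(contig = contig, gap_windows = 0L, gap_bp = 0,
                          gap_start = NA_real_, gap_end = NA_real_))
  }
  span <- seq.int(min(occupied), max(occupied))
  zero <- d$count[span] == 0
  r <- rle(zero)
  if (!any(r$values)) {
    return(tibble::tibble(contig = contig, gap_windows = 0L, gap_bp = 0,
                          gap_start = NA_real_, gap_end = NA_real_))
  }
  best <- which(r$values)[which.max(r$lengths[r$values])]
  len <- r$lengths[best]
  first_in_run <- span[sum(r$lengths[seq_len(best - 1L)]) + 1L]
  last_in_run <- first_in_run + len - 1L
  tibble::tibble(
    contig = contig,
    gap_windows = as.integer(len),
    gap_bp = d$end[last_in_run] - d$start[first_in_run] + 1,
    gap_start = d$start[first_in_run],
    gap_end = d$end[last_in_run]
  )
}
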