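#' Specify a synthetic VCF fixture
#'
#' Declares exactly what a generated VCF must contain: per-class variant
#' counts, multiallelic sites, planted duplicate lines, missing QUAL values,
#' an INDEL size range, contig lengths, and a seed. [generate_vcf()] turns
#' the spec into a dataset whose normalize/summarize output recovers these
#' counts exactly, so every downstream operation is testable offline.
#'
#' Multiallelic sites are planted as SNP pairs at one position (two ALT
#' alleles from one REF), consuming from the requested transition and
#' transversion counts — a site hosts one transition plus one transversion
#' when both remain, else two transversions (one REF base offers only a
#' single transition partner, so a transition pair at one site is
#' impossible).
#'
#' @param contigs Named numeric vector of contig lengths in bp.
#' @param n_transition,n_transversion,n_insertion,n_deletion,n_mnp,n_assorted
#'   Final per-class counts after normalization.
#' @param n_multiallelic_sites Number of two-ALT sites to plant.
#' @param n_duplicates Number of exact duplicate lines, each placed
#'   immediately after its original (exercises keep-first dedup).
#' @param n_missing_qual Number of records with QUAL `.`.
#' @param indel_size_range Length-2 integer range of |size| in bp.
#' @param seed Integer seed; same spec + seed gives byte-identical output.
#' @return A `fixture_spec` object (a validated named list).
#' @examples
#' spec <- fixture_spec(n_transition = 3, n_transversion = 1, n_insertion = 2,
#'                      n_deletion = 1, n_mnp = 1, n_multiallelic_sites = 1,
#'                      n_duplicates = 1, seed = 7)
#' glance(summarize_variants(generate_vcf(spec)$vcf))
#' @export
fixture_spec <- function(contigs = c(chr1 = 1e6, chr2 = 1e6),
                         n_transition = 0, n_transversion = 0,
                         n_insertion = 0, n_deletion = 0,
                         n_mnp = 0, n_assorted = 0,
                         n_multiallelic_sites = 0,
                         n_duplicates = 0, n_missing_qual = 0,
                         indel_size_range = c(1, 10),
                         seed = 1L) {
  counts <- c(n_transition = n_transition, n_transversion = n_transversion,
              n_insertion = n_insertion, n_deletion = n_deletion,
              n_mnp = n_mnp, n_assorted = n_assorted,
              n_multiallelic_sites = n_multiallelic_sites,
              n_duplicates = n_duplicates, n_missing_qual = n_missing_qual)
  if (any(counts < 0) || any(counts != floor(counts))) {
    rlang::abort("All fixture counts must be non-negative integers.",
                 class = "vcftally_infeasible_spec")
  }
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))) ||
      any(contigs < 1)) {
    rlang::abort("contigs must be a named vector of positive lengths.",
                 class = "vcftally_infeasible_spec")
  }
  if (length(indel_size_range) != 2L || indel_size_range[1] < 1 ||
      indel_size_range[1] > indel_size_range[2]) {
    rlang::abort("indel_size_range must be c(min, max) with 1 <= min <= max.",
                 class = "vcftally_infeasible_spec")
  }
  structure(
    list(contigs = contigs,
         n_transition = as.integer(n_transition),
         n_transversion = as.integer(n_transversion),
         n_insertion = as.integer(n_insertion),
         n_deletion = as.integer(n_deletion),
         n_mnp = as.integer(n_mnp),
         n_assorted = as.integer(n_assorted),
         n_multiallelic_sites = as.integer(n_multiallelic_sites),
         n_duplicates = as.integer(n_duplicates),
         n_missing_qual = as.integer(n_missing_qual),
         indel_size_range = as.integer(indel_size_range),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Serialize / restore a fixture spec
#'
#' Specs round-trip through a small JSON config file so a failing generated
#' case is always reproducible from the file alone.
#'
#' @param spec A `fixture_spec`.
#' @param path File path.
#' @return `write_fixture_spec()` returns `path` invisibly;
#'   `read_fixture_spec()` returns the `fixture_spec`.
#' @export
write_fixture_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  x <- unclass(spec)
  x$contigs <- as.list(x$contigs)  # keep contig names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fixture_spec
#' @export
read_fixture_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$contigs <- unlist(x$contigs)
  do.call(fixture_spec, x)
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# sample() treats a length-1 numeric vector as 1:x; this never does
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
transversion_options <- list(A = c("C", "T"), G = c("C", "T"),
                             C = c("A", "G"), T = c("A", "G"))

#' Generate a synthetic VCF with exact ground truth
#'
#' Builds a valid VCF dataset from a [fixture_spec()]: positions are unique
#' within each contig (except planted duplicate lines), QUAL values are
#' drawn uniformly in \\[0, 100\\] with `n_missing_qual` of them set to `.`,
#' records are reference-ordered (contig, then position), duplicates sit
#' immediately after their originals, and
#' `summarize_variants(normalize_variants(result))` recovers the spec's
#' class counts, multiallelic-site count and duplicates-removed count
#' exactly.
#'
#' @param spec A `fixture_spec`.
#' @return A list: `vcf` (a `vcf` object), `truth` (list of the planted
#'   counts: per-class, `n_total`, `n_multiallelic_sites`,
#'   `n_duplicates_removed`, `n_missing_qual`, `indel_sizes`).
#' @export
generate_vcf <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_rng(spec$seed, build_fixture(spec))
}

build_fixture <- function(spec) {
  # allocate SNPs to multiallelic sites
  ts_left <- spec$n_transition
  tv_left <- spec$n_transversion
  multi_kind <- character(spec$n_multiallelic_sites)
  for (i in seq_len(spec$n_multiallelic_sites)) {
    if (ts_left > 0 && tv_left > 0) {
      multi_kind[i] <- "ts_tv"; ts_left <- ts_left - 1; tv_left <- tv_left - 1
    } else if (tv_left >= 2) {
      multi_kind[i] <- "tv_tv"; tv_left <- tv_left - 2
    } else {
      rlang::abort(paste0(
        "Infeasible spec: ", spec$n_multiallelic_sites, " multiallelic ",
        "site(s) need SNP pairs (one transition + one transversion, or two ",
        "transversions) but the requested SNP counts cannot supply them."),
        class = "vcftally_infeasible_spec")
    }
  }

  site_class <- c(rep("multi", spec$n_multiallelic_sites),
                  rep("transition", ts_left),
                  rep("transversion", tv_left),
                  rep("insertion", spec$n_insertion),
                  rep("deletion", spec$n_deletion),
                  rep("mnp", spec$n_mnp),
                  rep("assorted", spec$n_assorted))
  n_sites <- length(site_class)

  total_len <- sum(spec$contigs)
  if (n_sites > total_len) {
    rlang::abort("Infeasible spec: more sites than genome positions.",
                 class = "vcftally_infeasible_spec")
  }
  if (spec$n_missing_qual > n_sites) {
    rlang::abort("Infeasible spec: n_missing_qual exceeds the site count.",
                 class = "vcftally_infeasible_spec")
  }
  n_single <- n_sites - spec$n_multiallelic_sites
  if (spec$n_duplicates > 0 && n_single == 0) {
    rlang::abort("Infeasible spec: duplicates need at least one single-ALT site.",
                 class = "vcftally_infeasible_spec")
  }

  # unique genome-wide positions, mapped back to (contig, pos)
  gpos <- sort(sample(total_len, n_sites))
  bounds <- unname(cumsum(spec$contigs))
  contig_idx <- findInterval(gpos - 1, bounds) + 1L
  chrom <- names(spec$contigs)[contig_idx]
  pos <- gpos - c(0, bounds)[contig_idx]
  site_class <- sample(site_class)  # scatter classes across the genome

  max_ins <- spec$indel_size_range[2]
  ref <- character(n_sites)
  alt <- character(n_sites)
  indel_sizes <- integer(0)
  for (i in seq_len(n_sites)) {
    switch(site_class[i],
      multi = {
        r <- rand_base(1)
        kind <- multi_kind[1]; multi_kind <- multi_kind[-1]
        alts <- if (kind == "ts_tv") {
          c(transition_partner[[r]], sample(transversion_options[[r]], 1))
        } else {
          sample(transversion_options[[r]])
        }
        ref[i] <- r; alt[i] <- paste(alts, collapse = ",")
      },
      transition = {
        r <- rand_base(1)
        ref[i] <- r; alt[i] <- transition_partner[[r]]
      },
      transversion = {
        r <- rand_base(1)
        ref[i] <- r; alt[i] <- sample(transversion_options[[r]], 1)
      },
      insertion = {
        s <- resample(seq.int(spec$indel_size_range[1], max_ins), 1)
        r <- rand_base(1)
        ref[i] <- r; alt[i] <- paste(c(r, rand_base(s)), collapse = "")
        indel_sizes <- c(indel_sizes, s)
      },
      deletion = {
        s <- resample(seq.int(spec$indel_size_range[1], max_ins), 1)
        r <- rand_base(1)
        ref[i] <- paste(c(r, rand_base(s)), collapse = ""); alt[i] <- r
        indel_sizes <- c(indel_sizes, -s)
      },
      mnp = {
        r <- rand_base(2)
        a <- vapply(r, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
      },
      assorted = {
        ref[i] <- rand_base(1)
        alt[i] <- sample(c("<DEL>", "<DUP>", "*"), 1)
      })
  }

  qual <- round(stats::runif(n_sites, 0, 100), 2)
  if (spec$n_missing_qual > 0) {
    qual[sample(n_sites, spec$n_missing_qual)] <- NA_real_
  }
  records <- tibble::tibble(
    chrom = chrom, pos = pos, id = ".", ref = ref, alt = alt, qual = qual,
    filter = "PASS",
    info = paste0("DP=", sample(10:200, n_sites, replace = TRUE)),
    trailing = rep(list(character(0)), n_sites)
  )
  # reference order: contig order as declared, then position
  ord <- order(match(records$chrom, names(spec$contigs)), records$pos,
               method = "radix")
  records <- records[ord, , drop = FALSE]

  # exact duplicate lines straight after their originals; drawn from
  # single-ALT records with a non-missing QUAL so the planted counts of
  # multiallelic sites and missing QUALs stay exact in the emitted file
  if (spec$n_duplicates > 0) {
    single <- which(!grepl(",", records$alt, fixed = TRUE) &
                      !is.na(records$qual))
    if (length(single) == 0L) {
      rlang::abort(paste0("Infeasible spec: duplicates need at least one ",
                          "single-ALT record with a non-missing QUAL."),
                   class = "vcftally_infeasible_spec")
    }
    dup_of <- sort(resample(single, spec$n_duplicates, replace = TRUE))
    reps <- tabulate(dup_of, nbins = nrow(records)) + 1L
    records <- records[rep.int(seq_len(nrow(records)), reps), , drop = FALSE]
  }

  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=vcftally synthetic fixture generator",
    "##reference=synthetic",
    paste0("##contig=<ID=", names(spec$contigs), ",length=",
           format_num(spec$contigs), ">"),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">'
  )
  vcf <- new_vcf(
    meta = parse_meta_lines(meta),
    header_cols = c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
    records = records,
    source_name = paste0("fixture_seed", spec$seed)
  )
  truth <- list(
    n_transition = spec$n_transition,
    n_transversion = spec$n_transversion,
    n_insertion = spec$n_insertion,
    n_deletion = spec$n_deletion,
    n_mnp = spec$n_mnp,
    n_assorted = spec$n_assorted,
    n_total = spec$n_transition + spec$n_transversion + spec$n_insertion +
      spec$n_deletion + spec$n_mnp + spec$n_assorted,
    n_multiallelic_sites = spec$n_multiallelic_sites,
    n_duplicates_removed = spec$n_duplicates,
    n_missing_qual = spec$n_missing_qual,
    indel_sizes = indel_sizes
  )
  list(vcf = vcf, truth = truth)
}

#' Generate a pair of VCFs with a known overlap
#'
#' Plants `n_shared + n_a_only + n_b_only` distinct SNP keys and deals them
#' into two datasets so that [compare_vcf()] of the pair yields exactly
#' `(n_a_only, n_b_only, n_shared)`. QUAL and INFO are drawn independently
#' per file, so only the variant keys agree on the shared set.
#'
#' @param n_shared,n_a_only,n_b_only Non-negative set sizes.
#' @param seed Integer seed.
#' @param contigs Named numeric vector of contig lengths in bp.
#' @return A list: `a`, `b` (`vcf` objects), `truth` (list `n_shared`,
#'   `n_a_only`, `n_b_only`).
#' @export
generate_pair <- function(n_shared, n_a_only, n_b_only, seed = 1L,
                          contigs = c(chr1 = 1e6, chr2 = 1e6)) {
  if (any(c(n_shared, n_a_only, n_b_only) < 0)) {
    rlang::abort("Set sizes must be non-negative.",
                 class = "vcftally_infeasible_spec")
  }
  n <- n_shared + n_a_only + n_b_only
  if (n > sum(contigs)) {
    rlang::abort("Infeasible spec: more keys than genome positions.",
                 class = "vcftally_infeasible_spec")
  }
  with_preserved_rng(seed, {
    gpos <- sort(sample(sum(contigs), n))
    bounds <- unname(cumsum(contigs))
    ci <- findInterval(gpos - 1, bounds) + 1L
    ref <- rand_base(n)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    keys <- tibble::tibble(chrom = names(contigs)[ci],
                           pos = gpos - c(0, bounds)[ci],
                           ref = ref, alt = alt)
    membership <- sample(rep(c("shared", "a", "b"),
                             c(n_shared, n_a_only, n_b_only)))
    mk <- function(rows, name) {
      k <- keys[rows, , drop = FALSE]
      rec <- tibble::tibble(
        chrom = k$chrom, pos = k$pos, id = ".", ref = k$ref, alt = k$alt,
        qual = round(stats::runif(nrow(k), 0, 100), 2), filter = "PASS",
        info = paste0("DP=", sample(10:200, nrow(k), replace = TRUE)),
        trailing = rep(list(character(0)), nrow(k))
      )
      ord <- order(match(rec$chrom, names(contigs)), rec$pos, method = "radix")
      meta <- c("##fileformat=VCFv4.2",
                "##source=vcftally synthetic fixture generator",
                paste0("##contig=<ID=", names(contigs), ",length=",
                       format_num(contigs), ">"))
      new_vcf(meta = parse_meta_lines(meta),
              header_cols = c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO"),
              records = rec[ord, , drop = FALSE],
              source_name = name)
    }
    list(a = mk(membership %in% c("shared", "a"), paste0("pairA_seed", seed)),
         b = mk(membership %in% c("shared", "b"), paste0("pairB_seed", seed)),
         truth = list(n_shared = as.integer(n_shared),
                      n_a_only = as.integer(n_a_only),
                      n_b_only = as.integer(n_b_only)))
  })
}
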