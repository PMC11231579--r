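# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops and base-R tallies over raw fields.

# Normalization oracle: split ALT on commas, uppercase, unique by
# (chrom, pos, ref, alt) keeping the first occurrence.
oracle_normalize_keys <- function(records) {
  seen <- character(0)
  for (i in seq_len(nrow(records))) {
    for (a in strsplit(records$alt[i], ",", fixed = TRUE)[[1]]) {
      k <- paste(records$chrom[i], records$pos[i],
                 toupper(records$ref[i]), toupper(a), sep = "|")
      if (!(k %in% seen)) seen <- c(seen, k)
    }
  }
  seen
}

# Classification oracle: an independent restatement of the rule ladder.
oracle_classify <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  mapply(function(r, a) {
    if (grepl("^<", a) || grepl("\\[|\\]", a) || a == "*" || a == "." ||
        grepl("[^ACGT]", r) || grepl("[^ACGT]", a)) return("assorted")
    if (nchar(r) == 1 && nchar(a) == 1) {
      pur <- c("A", "G")
      if ((r %in% pur) == (a %in% pur)) return("transition")
      return("transversion")
    }
    if (nchar(r) == nchar(a)) return("mnp")
    if (nchar(a) > nchar(r)) "insertion" else "deletion"
  }, ref, alt, USE.NAMES = FALSE)
}

# Window-count oracle: loop positions into bins.
oracle_window_counts <- function(pos, window_bp) {
  if (length(pos) == 0) return(integer(0))
  counts <- integer(ceiling(max(pos) / window_bp))
  for (p in pos) {
    w <- ceiling(p / window_bp)
    counts[w] <- counts[w] + 1L
  }
  counts
}

# INDEL histogram oracle over normalized single-ALT records.
oracle_indel_hist <- function(ref, alt) {
  sizes <- integer(0)
  for (i in seq_along(ref)) {
    if (oracle_classify(ref[i], alt[i]) %in% c("insertion", "deletion")) {
      sizes <- c(sizes, nchar(alt[i]) - nchar(ref[i]))
    }
  }
  sizes
}

# Venn oracle: double loop over all key pairs.
oracle_venn <- function(keys_a, keys_b) {
  shared <- 0L
  for (ka in keys_a) {
    hit <- FALSE
    for (kb in keys_b) if (ka == kb) { hit <- TRUE; break }
    if (hit) shared <- shared + 1L
  }
  b_shared <- 0L
  for (kb in keys_b) {
    hit <- FALSE
    for (ka in keys_a) if (kb == ka) { hit <- TRUE; break }
    if (hit) b_shared <- b_shared + 1L
  }
  c(n_a_only = length(keys_a) - shared,
    n_b_only = length(keys_b) - b_shared,
    n_shared = shared)
}

# Longest zero-run oracle between first and last occupied windows.
oracle_gap <- function(counts) {
  occ <- which(counts > 0)
  if (length(occ) < 2) return(0L)
  best <- 0L; run <- 0L
  for (i in seq(min(occ), max(occ))) {
    if (counts[i] == 0) { run <- run + 1L; best <- max(best, run) }
    else run <- 0L
  }
  best
}

# Build a vcf object directly from raw VCF text lines (bypasses write_vcf).
vcf_from_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small hand-rolled raw dataset with known quirks for filter tests.
toy_records <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(5, 10, 15, 7, 12),
    id = ".",
    ref = c("A", "C", "G", "AT", "T"),
    alt = c("G", "T", "T", "A", "TAA"),
    qual = c(10, 30, NA, 50, 20),
    filter = c("PASS", "PASS", "LowQual", "PASS", "PASS"),
    info = c("DP=10", "DP=20;ANN=x", "DP=5", "DP=7", "DP=99"),
    trailing = rep(list(character(0)), 5)
  )
}

# Random spec drawing used by property suites (feasibility enforced:
# multiallelic sites need SNP pairs, missing QUALs need sites, duplicates
# need a single-ALT site to copy).
random_spec <- function(seed) {
  set.seed(seed)
  ts <- sample(0:25, 1); tv <- sample(0:25, 1)
  ins <- sample(0:10, 1); del <- sample(0:10, 1)
  mnp <- sample(0:5, 1); asso <- sample(0:5, 1)
  max_multi <- min(ts, tv) + max(0, tv - min(ts, tv)) %/% 2
  multi <- if (max_multi > 0) sample(0:max_multi, 1) else 0
  n_sites <- ts + tv + ins + del + mnp + asso - multi
  n_single <- n_sites - multi
  dup <- if (n_single > 0) sample(0:5, 1) else 0
  # duplicates are copied from single-ALT, non-missing-QUAL records, so
  # when duplicates are requested leave at least one such record intact
  miss_cap <- if (dup > 0) max(0, n_single - 1) else n_sites
  fixture_spec(
    contigs = c(chrA = 5e4, chrB = 3e4),
    n_transition = ts, n_transversion = tv,
    n_insertion = ins, n_deletion = del,
    n_mnp = mnp, n_assorted = asso,
    n_multiallelic_sites = multi,
    n_duplicates = dup,
    n_missing_qual = min(sample(0:3, 1), miss_cap),
    indel_size_range = c(1, sample(1:20, 1)),
    seed = seed
  )
}
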