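test_that("summary totals reproduce generator ground truth", {
  g <- generate_vcf(fixture_spec(n_transition = 3, n_transversion = 1,
                                 n_insertion = 2, n_deletion = 1, n_mnp = 1,
                                 n_multiallelic_sites = 1, n_duplicates = 1,
                                 seed = 7))
  s <- summarize_variants(g$vcf)
  expect_equal(unname(s$totals),
               c(3, 1, 2, 1, 1, 0))
  expect_equal(s$n_total, 8)
  expect_equal(s$n_snp, 4)
  expect_equal(s$n_indel, 3)
  expect_equal(s$ts_tv, 3)
  expect_equal(s$n_multiallelic_sites, 1L)
  expect_equal(s$n_duplicates_removed, 1L)
  expect_equal(sum(s$per_contig$total), s$n_total)
  expect_equal(unname(s$percentages[["transition"]]), 100 * 3 / 8)
})

test_that("empty input gives an all-zero summary with missing Ts/Tv", {
  g <- generate_vcf(fixture_spec(seed = 1))
  s <- summarize_variants(g$vcf)
  expect_equal(s$n_total, 0)
  expect_true(all(s$totals == 0))
  expect_true(is.na(s$ts_tv))
  expect_true(all(is.na(s$percentages)))
})

test_that("Ts/Tv handles zero numerator and zero denominator", {
  mk <- function(ts, tv, seed) {
    summarize_variants(generate_vcf(fixture_spec(
      n_transition = ts, n_transversion = tv, seed = seed))$vcf)
  }
  expect_equal(mk(3, 1, 5)$ts_tv, 3)
  expect_equal(mk(0, 5, 6)$ts_tv, 0)
  expect_true(is.na(mk(4, 0, 7)$ts_tv))
  expect_true(is.finite(mk(0, 5, 6)$ts_tv))
})

test_that("window assignment is 1-anchored and inclusive at the boundary", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = c(1, 999999, 1000000, 1000001), id = ".",
    ref = "A", alt = "G", qual = 1, filter = "PASS", info = ".",
    trailing = rep(list(character(0)), 4)
  )
  d <- window_density(rec, window_bp = 1e6)
  expect_equal(d$count, c(3, 1))
  expect_equal(d$start, c(1, 1e6 + 1))
  expect_equal(d$end, c(1e6, 2e6))
  expect_equal(d$end - d$start + 1, rep(1e6, 2))
})

test_that("zero-count windows are emitted explicitly up to the last occupied window", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = c(50, 3 * 100 + 7), id = ".", ref = "A", alt = "G",
    qual = 1, filter = "PASS", info = ".",
    trailing = rep(list(character(0)), 2)
  )
  d <- window_density(rec, window_bp = 100)
  expect_equal(d$window_index, 1:4)
  expect_equal(d$count, c(1, 0, 0, 1))
})

test_that("window densities equal brute-force binning and re-aggregate under halving", {
  for (seed in c(11, 22, 33)) {
    g <- generate_vcf(random_spec(seed))
    norm <- normalize_variants(g$vcf)
    d <- window_density(norm, window_bp = 1000)
    for (ctg in unique(norm$records$chrom)) {
      expect_equal(d$count[d$contig == ctg],
                   oracle_window_counts(norm$records$pos[norm$records$chrom == ctg],
                                        1000))
    }
    # conservation per contig
    agg <- tapply(d$count, d$contig, sum)
    tallies <- table(norm$records$chrom)
    expect_equal(as.numeric(agg[names(tallies)]), as.numeric(tallies))
    # halving invariance: pairs of 500 bp windows rebuild the 1000 bp counts
    dh <- window_density(norm, window_bp = 500)
    for (ctg in unique(d$contig)) {
      h <- dh$count[dh$contig == ctg]
      if (length(h) %% 2 == 1) h <- c(h, 0L)
      paired <- h[seq(1, length(h), by = 2)] + h[seq(2, length(h), by = 2)]
      expect_equal(paired[seq_along(d$count[d$contig == ctg])],
                   d$count[d$contig == ctg])
    }
  }
})

test_that("window_density accepts class filters with grouping names", {
  g <- generate_vcf(fixture_spec(n_transition = 5, n_transversion = 3,
                                 n_insertion = 2, n_deletion = 2, seed = 13))
  d_snp <- window_density(g$vcf, window_bp = 1e4, class_filter = "snp")
  expect_equal(sum(d_snp$count), 8)
  d_indel <- window_density(g$vcf, window_bp = 1e4, class_filter = "indel")
  expect_equal(sum(d_indel$count), 4)
  expect_error(window_density(g$vcf, class_filter = "snv"),
               "Valid names", class = "vcftally_unknown_class")
})

test_that("INDEL size distribution matches planted sizes and brute force", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = c(10, 20, 30, 40), id = ".",
    ref = c("A", "C", "GTT", "A"), alt = c("ACG", "CAT", "G", "T"),
    qual = 1, filter = "PASS", info = ".",
    trailing = rep(list(character(0)), 4)
  )
  dist <- indel_size_distribution(rec)
  expect_equal(dist$sizes$size, c(-2L, 2L))
  expect_equal(dist$sizes$count, c(1L, 2L))
  expect_equal(dist$max_insertion, 2L)
  expect_equal(dist$max_deletion, 2L)
  expect_equal(dist$n_indel, 3L)

  for (seed in c(41, 42)) {
    g <- generate_vcf(random_spec(seed))
    norm <- normalize_variants(g$vcf)
    dist <- indel_size_distribution(norm)
    sizes <- oracle_indel_hist(norm$records$ref, norm$records$alt)
    expect_equal(dist$n_indel, length(sizes))
    expect_equal(sum(dist$sizes$count), length(sizes))
    expect_equal(rep(dist$sizes$size, dist$sizes$count), sort(sizes))
    expect_equal(sort(sizes), sort(g$truth$indel_sizes))
  }
})

test_that("no INDELs gives an empty histogram with missing maxima", {
  g <- generate_vcf(fixture_spec(n_transition = 3, seed = 2))
  dist <- indel_size_distribution(g$vcf)
  expect_equal(nrow(dist$sizes), 0)
  expect_true(is.na(dist$max_insertion))
  expect_true(is.na(dist$max_deletion))
})

test_that("longest empty gap scans between the first and last occupied windows", {
  mk_density <- function(counts) {
    tibble::tibble(contig = "chrY", window_index = seq_along(counts),
                   start = (seq_along(counts) - 1) * 100 + 1,
                   end = seq_along(counts) * 100, count = counts)
  }
  g <- longest_empty_gap(mk_density(c(3, 0, 0, 0, 2)), "chrY")
  expect_equal(g$gap_windows, 3L)
  expect_equal(g$gap_bp, 300)
  expect_equal(g$gap_start, 101)
  expect_equal(g$gap_end, 400)
  expect_equal(longest_empty_gap(mk_density(c(1, 2, 3)), "chrY")$gap_windows, 0L)
  # leading/trailing emptiness is not a gap
  expect_equal(longest_empty_gap(mk_density(c(0, 0, 5, 0, 1, 0, 0)), "chrY")$gap_windows, 1L)
  expect_error(longest_empty_gap(mk_density(c(1)), "chr1"), "chrY",
               class = "vcftally_unknown_contig")
  # random-run oracle
  set.seed(99)
  for (i in 1:20) {
    counts <- sample(0:2, 30, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    expect_equal(longest_empty_gap(mk_density(counts), "chrY")$gap_windows,
                 oracle_gap(counts))
  }
})

test_that("per-contig summary tallies agree with a brute-force tally", {
  g <- generate_vcf(random_spec(77))
  norm <- normalize_variants(g$vcf)
  s <- summarize_variants(norm)
  for (ctg in s$per_contig$contig) {
    sub <- norm$records[norm$records$chrom == ctg, ]
    for (cl in variant_classes) {
      expect_equal(s$per_contig[[cl]][s$per_contig$contig == ctg],
                   sum(oracle_classify(sub$ref, sub$alt) == cl))
    }
  }
})
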