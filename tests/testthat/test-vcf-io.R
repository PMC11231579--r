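basic_lines <- c(
  "##fileformat=VCFv4.2",
  "##reference=GRCh38",
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
  "chr1\t100\trs1\tA\tG\t50.5\tPASS\tDP=10\tGT\t0/1",
  "chr1\t200\t.\tC\tT,G\t.\tPASS\tDP=20\tGT\t1/1"
)

test_that("plain VCF parses with verbatim fields and trailing columns", {
  v <- read_vcf(vcf_from_text(basic_lines))
  expect_s3_class(v, "vcf")
  expect_equal(nrow(v$records), 2)
  expect_equal(v$records$chrom, c("chr1", "chr1"))
  expect_equal(v$records$pos, c(100, 200))
  expect_equal(v$records$ref, c("A", "C"))
  expect_equal(v$records$alt, c("G", "T,G"))
  expect_equal(v$records$qual, c(50.5, NA))
  expect_equal(v$records$trailing, list(c("GT", "0/1"), c("GT", "1/1")))
  expect_equal(v$header_cols[1:8],
               c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"))
})

test_that("gzip-compressed bytes yield the identical dataset", {
  plain <- vcf_from_text(basic_lines)
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  con <- gzfile(gz, "wt"); writeLines(basic_lines, con); close(con)
  expect_identical(read_vcf(gz)$records, read_vcf(plain)$records)
  expect_identical(read_vcf(gz)$meta, read_vcf(plain)$meta)
})

test_that("malformed records abort with a line number, or are counted in permissive mode", {
  bad_pos <- c(basic_lines[1:5], "chr1\tabc\t.\tA\tG\t10\tPASS\tDP=1")
  p <- vcf_from_text(bad_pos)
  expect_error(read_vcf(p), "line 6", class = "vcftally_malformed_record")
  v <- read_vcf(p, skip_malformed = TRUE)
  expect_equal(nrow(v$records), 1)
  expect_equal(v$n_skipped, 1)

  short <- c(basic_lines[1:4], "chr1\t100\t.\tA")
  expect_error(read_vcf(vcf_from_text(short)), "8 required",
               class = "vcftally_malformed_record")

  headerless <- c("##fileformat=VCFv4.2", "chr1\t1\t.\tA\tG\t1\tPASS\t.")
  expect_error(read_vcf(vcf_from_text(headerless)),
               class = "vcftally_missing_header")
})

test_that("read-write-read round trips are field-identical, missing QUAL as '.'", {
  for (seed in c(1, 2, 3)) {
    g <- generate_vcf(fixture_spec(n_transition = 5, n_transversion = 4,
                                   n_insertion = 3, n_deletion = 2, n_mnp = 1,
                                   n_assorted = 1, n_multiallelic_sites = 2,
                                   n_duplicates = 2, n_missing_qual = 3,
                                   seed = seed))
    p1 <- withr::local_tempfile(fileext = ".vcf")
    p2 <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(g$vcf, p1)
    v1 <- read_vcf(p1)
    write_vcf(v1, p2)
    v2 <- read_vcf(p2)
    expect_identical(v1$records, v2$records)
    expect_identical(v1$records[names(v1$records)], g$vcf$records)
    # missing QUAL written as "."
    raw <- readLines(p1)
    body <- raw[!startsWith(raw, "#")]
    quals <- vapply(strsplit(body, "\t"), `[[`, "", 6)
    expect_equal(sum(quals == "."), 3)
  }
})

test_that("header-only datasets read and write as valid empty VCFs", {
  v <- read_vcf(vcf_from_text(basic_lines[1:4]))
  expect_equal(nrow(v$records), 0)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, p)
  v2 <- read_vcf(p)
  expect_equal(nrow(v2$records), 0)
  expect_identical(v2$meta$raw_text, basic_lines[1:3])
})

test_that("metadata extraction handles structured, unstructured and absent lines", {
  v <- read_vcf(vcf_from_text(basic_lines))
  m <- extract_metadata(v)
  expect_equal(m$key, c("fileformat", "reference", "INFO"))
  expect_equal(m$entry_id, c(NA, NA, "DP"))
  expect_equal(m$description, c(NA, NA, "Depth"))
  expect_equal(m$raw_text[2], "##reference=GRCh38")
  # substring search over any column, case-insensitive
  expect_equal(nrow(extract_metadata(v, "grch38")), 1)
  expect_equal(nrow(extract_metadata(v, "DP")), 1)
  expect_equal(nrow(extract_metadata(v, "nothing-here")), 0)
  # no meta lines at all
  v0 <- read_vcf(vcf_from_text(basic_lines[4:5]))
  expect_equal(nrow(extract_metadata(v0)), 0)
})

test_that("CSV export round-trips cell values and quotes embedded commas", {
  s <- summarize_variants(generate_vcf(fixture_spec(
    n_transition = 3, n_transversion = 2, seed = 11))$vcf)
  p <- withr::local_tempfile(fileext = ".csv")
  write_csv_table(tidy(s), p)
  back <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_equal(back$count, tidy(s)$count)
  expect_equal(back$class, tidy(s)$class)

  tricky <- tibble::tibble(a = 'x,"y', b = 1)
  write_csv_table(tricky, p)
  expect_match(readLines(p)[2], '^"x,""y",1$')
  expect_equal(utils::read.csv(p)$a, 'x,"y')

  write_csv_table(tricky[0, ], p)
  expect_equal(readLines(p), "a,b")
})

test_that("an independent VCF reader agrees on the fixed columns", {
  skip_if_not_installed("vcfR")
  g <- generate_vcf(fixture_spec(n_transition = 8, n_transversion = 5,
                                 n_insertion = 3, n_deletion = 2,
                                 n_multiallelic_sites = 2, seed = 21))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g$vcf, p)
  ref <- suppressWarnings(vcfR::read.vcfR(p, verbose = FALSE))
  v <- read_vcf(p)
  expect_equal(v$records$chrom, unname(ref@fix[, "CHROM"]))
  expect_equal(v$records$pos, as.numeric(ref@fix[, "POS"]))
  expect_equal(v$records$ref, unname(ref@fix[, "REF"]))
  expect_equal(v$records$alt, unname(ref@fix[, "ALT"]))
})
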