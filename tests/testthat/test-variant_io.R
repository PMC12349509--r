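test_that("read_vcf parses records, flags non-SNPs, handles an empty body", {
  records <- data.frame(
    chrom = c("Chr01", "Chr01", "Chr02"), pos = c(100, 200, 300),
    ref = c("A", "AT", "G"), alt = c("T", "A", "A"),
    qual = c(50, 60, 70)
  )
  calls <- rbind(c("0/0:20", "0/1:15"),
                 c("1/1:30", "0/0:12"),
                 c("0/1:25", "0/1:11"))
  path <- write_fixture_vcf(records, calls, c("S1", "S2"))
  raw <- read_vcf(path)
  expect_equal(length(raw$pos), 3)
  expect_equal(raw$samples, c("S1", "S2"))
  expect_equal(raw$is_indel, c(FALSE, TRUE, FALSE))
  expect_equal(unname(raw$dp[1, ]), c(20, 15))

  empty <- tempfile(fileext = ".vcf")
  writeLines(vcf_header(c("S1", "S2")), empty)
  raw0 <- read_vcf(empty)
  expect_equal(length(raw0$pos), 0)
  expect_equal(raw0$samples, c("S1", "S2"))
  vs0 <- suppressWarnings(filter_variants(raw0))
  expect_equal(nrow(vs0$sites), 0)
})

test_that("filter rules drop the right sites and the ledger accounts for all", {
  raw <- read_vcf(five_site_vcf())
  vs <- filter_variants(raw, min_dp = 10, min_qual = 20)
  expect_equal(nrow(vs$sites), 2)
  expect_equal(vs$sites$pos, c(400, 500))
  led <- vs$ledger
  get <- function(rule) led$n[led$rule == rule]
  expect_equal(get("dropped_multiallelic"), 1)
  expect_equal(get("dropped_qual"), 1)
  expect_equal(get("dropped_missing"), 1)
  expect_equal(get("dropped_indel"), 0)
  expect_equal(get("input"),
               get("surviving") + get("dropped_indel") +
                 get("dropped_multiallelic") + get("dropped_qual") +
                 get("dropped_missing"))
  # genotype coding of the survivors
  expect_equal(unname(vs$geno[1, ]), c(2L, 1L))
  expect_equal(unname(vs$geno[2, ]), c(0L, 1L))
})

test_that("clean input loses nothing; no-op thresholds keep SNP-only input", {
  records <- data.frame(chrom = "Chr01", pos = 1:4 * 10, ref = "A",
                        alt = "G", qual = 99)
  calls <- matrix("0/1:30", 4, 3)
  raw <- read_vcf(write_fixture_vcf(records, calls, c("A", "B", "C")))
  expect_equal(nrow(filter_variants(raw)$sites), 4)
  expect_equal(nrow(filter_variants(raw, min_dp = 0, min_qual = 0)$sites), 4)
})

test_that("half calls and phased separators are handled; missing DP is conservative", {
  records <- data.frame(chrom = "Chr01", pos = c(10, 20), ref = "A",
                        alt = "G", qual = 99)
  calls <- rbind(c("0|1:30", "1|1:30"), c("./1:30", "0/0:30"))
  raw <- read_vcf(write_fixture_vcf(records, calls, c("S1", "S2")))
  vs <- filter_variants(raw)
  # phased site retained and coded like unphased; half-call site dropped
  expect_equal(nrow(vs$sites), 1)
  expect_equal(unname(vs$geno[1, ]), c(1L, 2L))

  # GT-only VCF: no DP at all -> all calls missing under min_dp > 0
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "S1"), collapse = "\t"),
               paste(c("Chr01", "5", ".", "A", "T", "99", ".", ".",
                       "GT", "0/1"), collapse = "\t")), path)
  raw2 <- read_vcf(path)
  expect_warning(vs2 <- filter_variants(raw2), "no sites survive")
  expect_equal(nrow(vs2$sites), 0)
  expect_equal(nrow(filter_variants(raw2, min_dp = 0)$sites), 1)
})

test_that("filtering is idempotent and write/read round-trips keys and genotypes", {
  raw <- read_vcf(five_site_vcf())
  vs <- filter_variants(raw)
  out <- tempfile(fileext = ".vcf.gz")
  write_vcf(vs, out)
  vs2 <- filter_variants(read_vcf(out), min_dp = 10, min_qual = 20)
  expect_equal(vs2$sites$key, vs$sites$key)
  expect_equal(unname(vs2$geno), unname(vs$geno))
  expect_equal(vs2$ledger$n[vs2$ledger$rule == "surviving"],
               vs2$ledger$n[vs2$ledger$rule == "input"])
})

test_that("metadata dialects convert and invariants are enforced with row numbers", {
  df <- data.frame(sample_id = c("A", "B"), country = "Canada",
                   year_acquired = c(1972, 2000),
                   year_last_regen = c(2000, 2000),
                   r_cycles = c(3, 0), rin = c(7.5, 8))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- read_metadata(path, reference_year = 2022)
  expect_s3_class(meta, "accession_metadata")
  expect_equal(meta$y_acq, c(50, 22))
  expect_equal(meta$y_last, c(22, 22))

  bad <- data.frame(sample_id = "A", country = "X", y_acq = 10, y_last = 20,
                    r_cycles = 1, rin = 7)
  expect_error(validate_metadata(bad), "y_last > y_acq.*row.*1")
  bad2 <- transform(bad, y_last = 5, rin = 11)
  expect_error(validate_metadata(bad2), "RIN")
  bad3 <- data.frame(sample_id = "A", country = "X", y_acq = 10,
                     y_last = 5, r_cycles = 0, rin = 7)
  expect_error(validate_metadata(bad3), "r_cycles = 0")
  ok <- data.frame(sample_id = "A", country = "X", y_acq = 10, y_last = 10,
                   r_cycles = 0, rin = 7)
  expect_silent(validate_metadata(ok))
})
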