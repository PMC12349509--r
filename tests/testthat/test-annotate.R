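test_that("classification combines SIFT, confidence and RS exactly as specified", {
  ann <- annotation_table(ann_df(
    5,
    sift = c(0.04, 0.04, 0.04, 0.2, 0.05),
    conf = c("normal", "normal", "low_confidence", "normal", "normal"),
    rs = c(2.5, 0.0, 2.5, 5.0, 0.1)
  ))
  d <- classify_deleterious(ann)
  expect_equal(d$pos, c(1, 5))          # RS = 0 fails the strict bound
  expect_equal(d$severity, c("mild", "weak"))
  # SIFT threshold is inclusive at 0.05
  expect_true("Chr01:5_A/T" %in% d$key)
  # low-confidence kept when exclusion is off
  d2 <- classify_deleterious(ann, exclude_low_confidence = FALSE)
  expect_true("Chr01:3_A/T" %in% d2$key)
  # missing scores are never deleterious
  ann3 <- annotation_table(ann_df(2, sift = c(NA, 0.01), rs = c(2, NA)))
  expect_equal(nrow(classify_deleterious(ann3)), 0)
  # SIFT-only screen ignores RS entirely
  expect_equal(nrow(classify_deleterious(ann3, require_rs = FALSE)), 1)
})

test_that("classifier matches a brute-force row scan on random tables", {
  set.seed(42)
  n <- 10000
  ann <- annotation_table(ann_df(
    n,
    sift = ifelse(runif(n) < 0.1, NA, round(runif(n), 3)),
    conf = sample(c("normal", "low_confidence"), n, TRUE, c(0.9, 0.1)),
    rs = ifelse(runif(n) < 0.2, NA, round(rnorm(n, 0, 2), 3))
  ))
  got <- classify_deleterious(ann)$key
  want <- character(0)
  for (i in seq_len(n)) {            # row-by-row oracle
    s <- ann$sift_score[i]; r <- ann$rs_score[i]; cf <- ann$sift_confidence[i]
    if (!is.na(s) && s <= 0.05 && identical(cf, "normal") &&
        !is.na(r) && r > 0)
      want <- c(want, ann$key[i])
  }
  expect_equal(got, want)
})

test_that("raising sift_max or lowering rs_min never shrinks the set", {
  set.seed(7)
  ann <- annotation_table(ann_df(500, sift = runif(500),
                                 rs = rnorm(500, 0, 2)))
  base <- classify_deleterious(ann, sift_max = 0.05, rs_min = 0)$key
  wider_sift <- classify_deleterious(ann, sift_max = 0.2, rs_min = 0)$key
  wider_rs <- classify_deleterious(ann, sift_max = 0.05, rs_min = -1)$key
  expect_true(all(base %in% wider_sift))
  expect_true(all(base %in% wider_rs))
})

test_that("severity bins partition positive RS with a closed mild interval", {
  expect_equal(bin_severity(c(0.5, 1.0, 3.0, 3.5)),
               c("weak", "mild", "mild", "high"))
  expect_error(bin_severity(c(1, 0)), "positive")
  set.seed(11)
  rs <- runif(2000, min = 1e-6, max = 6)
  sev <- bin_severity(rs)
  expect_equal(sum(sev == "weak") + sum(sev == "mild") + sum(sev == "high"),
               length(rs))
  expect_true(all(rs[sev == "weak"] < 1))
  expect_true(all(rs[sev == "mild"] >= 1 & rs[sev == "mild"] <= 3))
  expect_true(all(rs[sev == "high"] > 3))
})

test_that("consequence tally counts, proportions and LoF aggregate behave", {
  ann <- annotation_table(ann_df(
    6, consequence = c("missense_variant", "synonymous_variant",
                       "stop_gained", "splice_donor_variant",
                       "start_lost", "intron_variant"),
    sift = NA, conf = NA, rs = NA))
  tal <- tally_consequences(ann)
  expect_equal(tal$total, 6)
  expect_equal(sum(tal$classes$count), 6)
  expect_equal(sum(tal$classes$proportion), 1, tolerance = 1e-12)
  expect_equal(tal$lof_count, 3)

  one <- tally_consequences(annotation_table(ann_df(1)))
  expect_equal(one$classes$count[one$classes$consequence ==
                                   "missense_variant"], 1)
  expect_equal(max(one$classes$proportion), 1)

  expect_error(annotation_table(ann_df(1, consequence = "frameshift")),
               "unknown consequence class.*frameshift")
})

test_that("deleterious-set intersection follows set semantics and reports conflicts", {
  a <- deleterious_set("Chr01", 1:3, "A", "T", rs_score = c(0.5, 2, 4))
  b <- deleterious_set("Chr01", 2:4, "A", "T", rs_score = c(2, 2, 2))
  expect_equal(intersect_dsnp_sets(a, a)$key, a$key)
  expect_equal(nrow(intersect_dsnp_sets(
    deleterious_set("Chr01", 1:2, "A", "T"),
    deleterious_set("Chr02", 1:2, "A", "T"))), 0)
  shared <- intersect_dsnp_sets(a, b)
  expect_equal(shared$pos, c(2, 3))
  expect_equal(shared$severity, c("mild", "high"))  # taken from a
  expect_equal(attr(shared, "severity_conflicts"), "Chr01:3_A/T")
})
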