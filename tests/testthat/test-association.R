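test_that("OLS regression handles exact lines, sign reversal and degenerate input", {
  r <- regress(c(0, 1, 2), c(0, 1, 2))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  r2 <- regress(-c(0, 1, 2), c(0, 1, 2))
  expect_equal(r2$slope, -1)
  expect_error(regress(1:5, rep(2, 5)), "degenerate predictor")
  expect_error(regress(1:2, 1:2), "at least 3")
})

test_that("regress matches stats::lm on random data", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:80, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    r <- regress(y, x)
    fit <- summary(lm(y ~ x))
    expect_equal(r$slope, unname(fit$coefficients["x", "Estimate"]))
    expect_equal(r$p_value, unname(fit$coefficients["x", "Pr(>|t|)"]))
    expect_equal(r$r_squared, fit$r.squared)
    # bivariate identity: slope(y~x) * slope(x~y) = R^2
    expect_equal(r$slope * regress(x, y)$slope, r$r_squared,
                 tolerance = 1e-10)
  }
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(17)
  v <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  a <- anova_by_group(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(a$f, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("ANOVA group selection, degenerate and separated cases behave", {
  v <- c(1, 1, 1, 1, 1, 1)
  g <- rep(c("a", "b"), each = 3)
  a <- anova_by_group(v, g)
  expect_equal(a$f, 0)
  expect_equal(a$p_value, 1)

  set.seed(3)
  v2 <- c(rnorm(10, 0, .01), rnorm(10, 0, .01), rnorm(10, 10, .01))
  a2 <- anova_by_group(v2, rep(c("x", "y", "z"), each = 10))
  expect_lt(a2$p_value, 1e-10)

  # groups below min_group_n are excluded but reported
  v3 <- rnorm(11)
  g3 <- c(rep("big1", 5), rep("big2", 5), "single")
  a3 <- anova_by_group(v3, g3, min_group_n = 3)
  expect_equal(sort(a3$groups_used), c("big1", "big2"))
  expect_equal(a3$n, 10)
  expect_error(anova_by_group(rnorm(4), c("a", "a", "b", "b"),
                              min_group_n = 3), "fewer than 2 groups")
})

make_bundle <- function(n, ids = sprintf("ACC%03d", seq_len(n))) {
  structure(data.frame(
    sample_id = ids,
    b_tot = runif(n, 0.03, 0.07), b_het = runif(n, 0.005, 0.03),
    b_hom = runif(n, 0.02, 0.05),
    expressed_gene_count = sample(130:164, n, TRUE),
    mean_tpm = runif(n, 9, 21), rin = runif(n, 6.5, 9.6)
  ), class = c("estimate_bundle", "data.frame"))
}

make_meta <- function(ids) {
  n <- length(ids)
  validate_metadata(data.frame(
    sample_id = ids, country = sample(letters[1:5], n, TRUE),
    y_acq = sample(18:50, n, TRUE), y_last = sample(4:18, n, TRUE),
    r_cycles = sample(1:10, n, TRUE), rin = runif(n, 6.5, 9.6)
  ))
}

test_that("the battery emits exactly 9 + 15 + 9 labeled results", {
  set.seed(23)
  bundle <- make_bundle(60)
  meta <- make_meta(bundle$sample_id)
  out <- run_battery(bundle, meta)
  expect_equal(nrow(out), 33)
  expect_equal(as.integer(table(out$battery)[c("burden_feature", "pairwise",
                                               "extra_feature")]),
               c(9L, 15L, 9L))
  expect_true(all(out$n == 60))
  expect_true(all(out$r_squared >= 0 & out$r_squared <= 1))
  expect_true(all(out$signif %in% c("significant", "marginal", "ns")))
  expect_true(all(out$p_bh >= out$p_value))

  # removing one sample decrements n everywhere (with a join warning),
  # labels unchanged
  expect_warning(out2 <- run_battery(bundle[-1, ], meta), "join lost")
  expect_true(all(out2$n == 59))
  expect_equal(out2$response, out$response)
  expect_equal(out2$predictor, out$predictor)
})

test_that("paired comparison runs over the shared-sample intersection", {
  set.seed(29)
  a <- make_bundle(190)
  b_ids <- c(a$sample_id[1:66], sprintf("LEAF%02d", 1:4))
  b <- make_bundle(70, ids = b_ids)
  res <- paired_compare(a, b)
  expect_equal(nrow(res), 6)
  expect_true(all(res$n == 66))

  ident <- paired_compare(a, a)
  expect_equal(ident$slope, rep(1, 6))
  expect_equal(ident$r_squared, rep(1, 6))

  # shuffling one cohort's values destroys the association
  shuf <- a
  shuf$b_tot <- sample(shuf$b_tot)
  r <- paired_compare(a, shuf)
  expect_lt(abs(r$slope[r$response == "a.b_tot"]), 0.25)

  expect_error(paired_compare(a, make_bundle(3, ids = c("x", "y", "z"))),
               "no shared samples")
})
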