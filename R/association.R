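# Association battery: OLS regressions of burden and expression estimates on
# conservation covariates, one-way ANOVA across origin groups, the pairwise
# estimate screen, and the paired two-cohort comparison.

#' Ordinary least squares regression of one estimate on one covariate
#'
#' Closed-form simple linear regression with a two-sided t test on the slope.
#' Significance bands follow the per-test convention used throughout:
#' `p < 0.05` significant, `0.05 <= p < 0.10` marginal, otherwise ns (both
#' cutoffs configurable via `bands`).
#'
#' @param y Response vector.
#' @param x Predictor vector (same length, not constant).
#' @param response,predictor Labels carried into the result row.
#' @param bands Numeric length-2: significance and marginal p cutoffs.
#' @return One-row data.frame of class `association_result`: `response`,
#'   `predictor`, `n`, `slope`, `intercept`, `r_squared`, `p_value`,
#'   `signif`.
#' @export
regress <- function(y, x, response = "y", predictor = "x",
                    bands = c(0.05, 0.10)) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("regression needs at least 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate predictor: '", predictor, "' is constant")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  r2 <- if (syy > 0) 1 - rss / syy else 0
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  if (se > 0) {
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    # perfect fit: slope exactly determined
    p <- if (slope == 0) 1 else 0
  }
  out <- data.frame(
    response = response, predictor = predictor, n = n,
    slope = slope, intercept = intercept, r_squared = r2, p_value = p,
    signif = significance_class(p, bands),
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  out
}

significance_class <- function(p, bands = c(0.05, 0.10)) {
  ifelse(p < bands[1], "significant",
         ifelse(p < bands[2], "marginal", "ns"))
}

#' One-way fixed-effects ANOVA across groups
#'
#' Classic equal-variance one-way ANOVA (via
#' [stats::oneway.test()] with `var.equal = TRUE`) of an estimate across
#' groups, restricted to groups with at least `min_group_n` observations so
#' that singleton origins do not enter the F test. The groups actually used
#' and their means are always reported, making the selection auditable.
#'
#' @param values Numeric estimate vector.
#' @param groups Group labels (same length).
#' @param min_group_n Minimum group size to enter the test (default 3).
#' @return A list of class `anova_result`: `f`, `p_value`, `df`,
#'   `group_means` (data.frame `group`, `n`, `mean`), `groups_used`, `n`.
#' @export
anova_by_group <- function(values, groups, min_group_n = 3) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  tab <- table(groups)
  used <- names(tab)[tab >= min_group_n]
  if (length(used) < 2)
    stop("fewer than 2 groups meet min_group_n = ", min_group_n)
  keep <- groups %in% used
  v <- values[keep]; g <- factor(groups[keep])
  gmeans <- tapply(v, g, mean)
  df <- c(length(used) - 1, length(v) - length(used))
  if (max(gmeans) - min(gmeans) == 0) {
    # no between-group variance at all: F = 0 by definition
    ht <- list(statistic = 0, p.value = 1, parameter = df)
  } else {
    ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
  }
  gm <- data.frame(group = levels(g),
                   n = as.integer(table(g)),
                   mean = as.numeric(tapply(v, g, mean)),
                   row.names = NULL)
  structure(
    list(f = unname(ht$statistic), p_value = unname(ht$p.value),
         df = unname(ht$parameter), group_means = gm, groups_used = used,
         n = length(v)),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%g, %g) = %.4g, p = %.4g over %d groups (n = %d)\n",
              x$df[1], x$df[2], x$f, x$p_value, length(x$groups_used), x$n))
  invisible(x)
}

#' Assemble the six per-sample estimates into one bundle
#'
#' Joins the burden table, the expression summary and the metadata RIN on
#' sample id. Samples lost in the join are reported with a warning.
#'
#' @param burden A `burden_table`.
#' @param expr An `expression_summary`.
#' @param meta An `accession_metadata` table.
#' @return Data.frame of class `estimate_bundle` with columns `sample_id`,
#'   `b_tot`, `b_het`, `b_hom`, `expressed_gene_count`, `mean_tpm`, `rin`.
#' @export
build_estimate_bundle <- function(burden, expr, meta) {
  stopifnot(inherits(burden, "burden_table"),
            inherits(expr, "expression_summary"),
            inherits(meta, "accession_metadata"))
  ids <- Reduce(intersect, list(burden$sample_id, expr$samples$sample_id,
                                meta$sample_id))
  lost <- length(unique(c(burden$sample_id, expr$samples$sample_id,
                          meta$sample_id))) - length(ids)
  if (lost > 0)
    warning(lost, " sample(s) dropped when joining estimates")
  out <- data.frame(
    sample_id = ids,
    b_tot = burden$b_tot[match(ids, burden$sample_id)],
    b_het = burden$b_het[match(ids, burden$sample_id)],
    b_hom = burden$b_hom[match(ids, burden$sample_id)],
    expressed_gene_count =
      expr$samples$expressed_gene_count[match(ids, expr$samples$sample_id)],
    mean_tpm = expr$samples$mean_tpm[match(ids, expr$samples$sample_id)],
    rin = meta$rin[match(ids, meta$sample_id)],
    row.names = NULL
  )
  class(out) <- c("estimate_bundle", "data.frame")
  out
}

#' Run the full association battery
#'
#' Three blocks of simple regressions, labeled by block:
#' \itemize{
#'   \item `burden_feature`: the 3 burden estimates on the 3 conservation
#'     covariates (9 tests);
#'   \item `pairwise`: all 15 unordered pairs of the six estimates;
#'   \item `extra_feature`: expressed gene count, mean TPM and RIN on the 3
#'     conservation covariates (9 tests).
#' }
#' No multiple-testing correction enters the significance class (per-test
#' alpha reporting); a Benjamini-Hochberg adjusted column `p_bh` is emitted
#' alongside as a labeled extension.
#'
#' @param bundle An `estimate_bundle`.
#' @param meta An `accession_metadata` table (provides `y_last`, `y_acq`,
#'   `r_cycles`).
#' @param bands Significance bands, see [regress()].
#' @return Data.frame of 33 `association_result` rows with columns `battery`
#'   and `p_bh` added.
#' @export
run_battery <- function(bundle, meta, bands = c(0.05, 0.10)) {
  stopifnot(inherits(bundle, "estimate_bundle"),
            inherits(meta, "accession_metadata"))
  ids <- intersect(bundle$sample_id, meta$sample_id)
  if (length(ids) < length(bundle$sample_id) ||
      length(ids) < length(meta$sample_id))
    warning("join lost ",
            length(unique(c(bundle$sample_id, meta$sample_id))) - length(ids),
            " sample(s)")
  b <- bundle[match(ids, bundle$sample_id), , drop = FALSE]
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  burdens <- c("b_tot", "b_het", "b_hom")
  extras <- c("expressed_gene_count", "mean_tpm", "rin")
  features <- c("y_last", "y_acq", "r_cycles")
  rows <- list()
  for (resp in burdens)
    for (feat in features)
      rows[[length(rows) + 1]] <-
        cbind(battery = "burden_feature",
              regress(b[[resp]], m[[feat]], resp, feat, bands))
  pairs <- utils::combn(c(burdens, extras), 2)
  for (j in seq_len(ncol(pairs)))
    rows[[length(rows) + 1]] <-
      cbind(battery = "pairwise",
            regress(b[[pairs[1, j]]], b[[pairs[2, j]]],
                    pairs[1, j], pairs[2, j], bands))
  for (resp in extras)
    for (feat in features)
      rows[[length(rows) + 1]] <-
        cbind(battery = "extra_feature",
              regress(b[[resp]], m[[feat]], resp, feat, bands))
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

#' Paired comparison of shared estimates between two cohorts
#'
#' For every estimate column present in both bundles, regresses cohort `a`'s
#' values on cohort `b`'s values over the samples the two cohorts share
#' (e.g. a seed-based and a leaf-based assay of the same accessions).
#'
#' @param a,b `estimate_bundle` objects with overlapping `sample_id`s.
#' @param bands Significance bands, see [regress()].
#' @return Data.frame of `association_result` rows (one per shared
#'   estimate), each with `n` equal to the shared-sample count.
#' @export
paired_compare <- function(a, b, bands = c(0.05, 0.10)) {
  stopifnot(inherits(a, "estimate_bundle"), inherits(b, "estimate_bundle"))
  ids <- intersect(a$sample_id, b$sample_id)
  if (length(ids) == 0) stop("no shared samples between the two bundles")
  ests <- setdiff(intersect(names(a), names(b)), "sample_id")
  rows <- lapply(ests, function(e) {
    regress(a[[e]][match(ids, a$sample_id)],
            b[[e]][match(ids, b$sample_id)],
            response = paste0("a.", e), predictor = paste0("b.", e),
            bands = bands)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}
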