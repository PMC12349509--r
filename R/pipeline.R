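# One-config orchestration of the full analysis:
# filter -> classify -> burden -> expression -> associate, with a run report.

default_run_config <- function() {
  list(
    vcf = NULL, annotation = NULL, metadata = NULL, tpm = NULL,
    out_dir = NULL,
    min_dp = 10, min_qual = 20,
    sift_max = 0.05, rs_min = 0, exclude_low_confidence = TRUE,
    severity_bounds = c(1, 3),
    tpm_floor = 0, min_group_n = 3,
    bands = c(0.05, 0.10),
    reference_year = NULL,
    n_chrom = 20
  )
}

#' Load a run configuration from YAML
#'
#' Unset keys fall back to the documented defaults; unknown keys are an
#' error so typos cannot silently disable a threshold.
#'
#' @param path YAML file.
#' @return Run-config list.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline from one configuration
#'
#' Executes, in order: VCF read + quality filtering, annotation read +
#' deleterious classification (restricted to surviving sites), burden and
#' MAF/chromosome summaries, expression summarization, and the association
#' battery plus ANOVA of each burden across countries of origin. Any stage
#' error halts the run naming the stage. When `config$out_dir` is set every
#' intermediate table is written there as TSV.
#'
#' @param config A run-config list (see [load_run_config()]) with input
#'   paths `vcf`, `annotation`, `metadata`, `tpm` set. Threshold fields
#'   default as in a standard run (`min_dp` 10, `min_qual` 20, `sift_max`
#'   0.05, `rs_min` 0, `tpm_floor` 0, `min_group_n` 3).
#' @return A list of class `run_report`: the config echo, the filter ledger,
#'   consequence tally, deleterious count and severity split, burden summary
#'   (mean/sd per estimator), MAF flag counts, chromosome summary, the 33-row
#'   association battery, the per-burden country ANOVAs, and the significant
#'   association list.
#' @export
run_pipeline <- function(config) {
  cfg <- default_run_config()
  cfg[names(config)] <- config
  for (f in c("vcf", "annotation", "metadata", "tpm")) {
    if (is.null(cfg[[f]])) stop("run config must set '", f, "'")
    if (!file.exists(cfg[[f]])) stop("input not found: ", cfg[[f]])
  }

  vs <- stage("filter", {
    raw <- read_vcf(cfg$vcf)
    filter_variants(raw, min_dp = cfg$min_dp, min_qual = cfg$min_qual)
  })
  ann <- stage("classify", {
    a <- read_annotation(cfg$annotation)
    a <- a[a$key %in% vs$sites$key, , drop = FALSE]
    class(a) <- c("annotation_table", "data.frame")
    a
  })
  tally <- stage("classify", tally_consequences(ann))
  dset <- stage("classify", classify_deleterious(
    ann, sift_max = cfg$sift_max, rs_min = cfg$rs_min,
    exclude_low_confidence = cfg$exclude_low_confidence))
  burden <- stage("burden", compute_burdens(vs, dset))
  maf <- stage("burden", maf_spectrum(vs))
  dmaf <- stage("burden", maf_spectrum(vs, subset = dset$key))
  chrom <- stage("burden", chrom_distribution(vs, dset,
                                              n_chrom = cfg$n_chrom))
  meta <- stage("metadata", read_metadata(cfg$metadata,
                                          reference_year = cfg$reference_year))
  expr <- stage("expression", {
    tab <- utils::read.delim(cfg$tpm, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    summarize_expression(m, floor = cfg$tpm_floor)
  })
  bundle <- stage("associate", build_estimate_bundle(burden, expr, meta))
  battery <- stage("associate", run_battery(bundle, meta, bands = cfg$bands))
  anovas <- stage("associate", {
    lapply(stats::setNames(nm = c("b_tot", "b_het", "b_hom")), function(e)
      anova_by_group(burden[[e]][match(meta$sample_id, burden$sample_id)],
                     meta$country, min_group_n = cfg$min_group_n))
  })

  burden_summary <- data.frame(
    estimate = c("b_tot", "b_het", "b_hom"),
    mean = vapply(burden[c("b_tot", "b_het", "b_hom")], mean, numeric(1)),
    sd = vapply(burden[c("b_tot", "b_het", "b_hom")], stats::sd, numeric(1)),
    row.names = NULL
  )
  report <- structure(list(
    config = cfg,
    ledger = vs$ledger,
    tally = tally,
    n_dsnp = nrow(dset),
    severity = table(factor(dset$severity,
                            levels = c("weak", "mild", "high"))),
    burden = burden,
    burden_summary = burden_summary,
    maf_flags = data.frame(
      track = c("snp", "dsnp"),
      n = c(nrow(maf), nrow(dmaf)),
      fixed = c(sum(maf$fixed), sum(dmaf$fixed)),
      invariant_het = c(sum(maf$invariant_het), sum(dmaf$invariant_het)),
      rare = c(sum(maf$rare_band), sum(dmaf$rare_band)),
      singleton = c(sum(maf$singleton_band), sum(dmaf$singleton_band))
    ),
    chrom = chrom,
    expression = expr,
    battery = battery,
    anova = anovas,
    significant = battery[battery$signif != "ns",
                          c("battery", "response", "predictor", "slope",
                            "p_value", "signif")]
  ), class = "run_report")

  if (!is.null(cfg$out_dir)) write_run_report(report, cfg$out_dir)
  report
}

write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name)
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(report$ledger, "filter_ledger.tsv")
  wt(report$tally$classes, "consequence_tally.tsv")
  wt(report$burden, "burden.tsv")
  wt(report$burden_summary, "burden_summary.tsv")
  wt(report$maf_flags, "maf_flags.tsv")
  wt(report$chrom$per_chrom, "chrom_distribution.tsv")
  wt(report$expression$samples, "expression_samples.tsv")
  wt(report$expression$genes, "expression_genes.tsv")
  wt(report$battery, "associations.tsv")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n----------\n")
  cat("filter ledger:\n"); print(x$ledger, row.names = FALSE)
  cat("\nvariants:", x$tally$total, "; deleterious:", x$n_dsnp,
      "( weak/mild/high:", paste(as.integer(x$severity), collapse = "/"),
      ")\n")
  cat("\nburden summary:\n"); print(x$burden_summary, row.names = FALSE)
  cat("\nsignificant associations:\n")
  print(x$significant, row.names = FALSE)
  invisible(x)
}
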