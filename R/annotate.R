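# Deleterious-variant classification from SIFT and GERP++ RS scores,
# severity binning, and consequence-class tallies.

#' Closed vocabulary of most-severe consequence classes
#'
#' The sixteen VEP-style classes a variant's most severe consequence may take
#' in this package, plus the subset counted as loss-of-function (the three
#' stop classes, the three splice classes, and start_lost).
#'
#' @return Character vector of class labels.
#' @export
consequence_classes <- function() {
  c("missense_variant", "synonymous_variant",
    "splice_acceptor_variant", "splice_donor_variant", "splice_region_variant",
    "stop_gained", "stop_lost", "stop_retained_variant", "start_lost",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "non_coding_transcript_exon_variant", "intron_variant",
    "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant")
}

#' @rdname consequence_classes
#' @export
lof_classes <- function() {
  c("stop_gained", "stop_lost", "stop_retained_variant",
    "splice_acceptor_variant", "splice_donor_variant",
    "splice_region_variant", "start_lost")
}

#' Construct/validate a per-variant annotation table
#'
#' One row per variant key: gene id, most-severe consequence class, SIFT
#' score (absent for classes SIFT does not score), SIFT confidence flag, and
#' GERP++ rejected-substitution (RS) score (absent outside the constrained
#' track).
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `consequence`, `sift_score`, `sift_confidence`, `rs_score`.
#' @return The validated data.frame, with a `key` column, of class
#'   `annotation_table`.
#' @export
annotation_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "gene_id", "consequence",
            "sift_score", "sift_confidence", "rs_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(df$consequence), consequence_classes())
  if (length(unknown))
    stop("unknown consequence class label(s): ",
         paste(unknown, collapse = ", "))
  bad_conf <- !df$sift_confidence %in% c("normal", "low_confidence", NA)
  if (any(bad_conf))
    stop("sift_confidence must be 'normal' or 'low_confidence'")
  df$key <- site_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$key))
    stop("duplicate variant keys in annotation table")
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read an annotation TSV
#'
#' @param path TSV with the [annotation_table()] header.
#' @return An `annotation_table`.
#' @export
read_annotation <- function(path) {
  annotation_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                     check.names = FALSE))
}

#' Classify variants as deleterious from SIFT and RS scores
#'
#' A variant is deleterious iff its SIFT score is at most `sift_max`
#' (inclusive, the SIFT convention for "0.05 or less"), its SIFT call is not
#' flagged low-confidence (when `exclude_low_confidence`), and its RS score
#' strictly exceeds `rs_min` (a substitution at a conserved site must have
#' RS > 0). Variants lacking either score are never deleterious. Setting
#' `require_rs = FALSE` gives the SIFT-only screen (no RS condition at all),
#' e.g. to count SIFT-deleterious variants before conservation filtering.
#'
#' @param ann An [annotation_table()].
#' @param sift_max Inclusive SIFT threshold (default 0.05).
#' @param rs_min Exclusive RS threshold (default 0).
#' @param exclude_low_confidence Drop low-confidence SIFT calls (default TRUE).
#' @param require_rs Apply the RS condition (default TRUE).
#' @return A data.frame of class `deleterious_set` with columns `key`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`, `rs_score` and `severity`
#'   (`weak`/`mild`/`high`, from [bin_severity()]; NA when RS is not part of
#'   the rule or not positive).
#' @export
classify_deleterious <- function(ann, sift_max = 0.05, rs_min = 0,
                                 exclude_low_confidence = TRUE,
                                 require_rs = TRUE) {
  stopifnot(inherits(ann, "annotation_table"))
  sel <- !is.na(ann$sift_score) & ann$sift_score <= sift_max
  if (exclude_low_confidence)
    sel <- sel & !is.na(ann$sift_confidence) &
      ann$sift_confidence == "normal"
  if (require_rs)
    sel <- sel & !is.na(ann$rs_score) & ann$rs_score > rs_min
  out <- ann[sel, c("key", "chrom", "pos", "ref", "alt", "gene_id",
                    "rs_score"), drop = FALSE]
  out$severity <- rep(NA_character_, nrow(out))
  pos_rs <- !is.na(out$rs_score) & out$rs_score > 0
  if (any(pos_rs)) out$severity[pos_rs] <- bin_severity(out$rs_score[pos_rs])
  rownames(out) <- NULL
  class(out) <- c("deleterious_set", "data.frame")
  out
}

#' Construct a deleterious set directly
#'
#' Builds a `deleterious_set` from site coordinates, bypassing
#' classification -- useful when the deleterious loci are given (e.g. an
#' external list) rather than derived from scores.
#'
#' @param chrom,pos,ref,alt Site coordinate vectors.
#' @param gene_id,rs_score Optional per-site annotations.
#' @return A `deleterious_set`.
#' @export
deleterious_set <- function(chrom, pos, ref, alt, gene_id = NA,
                            rs_score = NA) {
  key <- site_key(chrom, pos, ref, alt)
  n <- length(key)
  r <- function(x) rep(x, length.out = n)
  out <- data.frame(
    key = key,
    chrom = r(chrom), pos = r(pos), ref = r(ref), alt = r(alt),
    gene_id = r(gene_id), rs_score = r(rs_score),
    stringsAsFactors = FALSE
  )
  out$severity <- rep(NA_character_, nrow(out))
  pos_rs <- !is.na(out$rs_score) & out$rs_score > 0
  if (any(pos_rs)) out$severity[pos_rs] <- bin_severity(out$rs_score[pos_rs])
  if (anyDuplicated(out$key)) stop("duplicate variant keys")
  class(out) <- c("deleterious_set", "data.frame")
  out
}

#' Bin deleterious variants by evolutionary-constraint severity
#'
#' Partitions positive RS scores into weakly (`rs < low`), mildly
#' (`low <= rs <= high`, a closed interval) and highly (`rs > high`)
#' detrimental classes.
#'
#' @param rs Numeric vector of RS scores; all must be > 0 (the classifier's
#'   contract guarantees this for deleterious variants).
#' @param low,high Bin boundaries, default 1 and 3.
#' @return Character vector in `{"weak","mild","high"}`.
#' @export
bin_severity <- function(rs, low = 1, high = 3) {
  if (any(is.na(rs)) || any(rs <= 0))
    stop("bin_severity expects strictly positive RS scores")
  ifelse(rs < low, "weak", ifelse(rs <= high, "mild", "high"))
}

#' Tally most-severe consequence classes
#'
#' Counts variants per consequence class over the exhaustive class partition,
#' derives proportions of the total, and aggregates the loss-of-function
#' classes.
#'
#' @param ann An [annotation_table()].
#' @return A list of class `consequence_tally`: `classes` (data.frame with
#'   `consequence`, `count`, `proportion` over all classes in the
#'   vocabulary), `total`, `lof_count`, `lof_proportion`.
#' @export
tally_consequences <- function(ann) {
  stopifnot(inherits(ann, "annotation_table"))
  cls <- factor(ann$consequence, levels = consequence_classes())
  counts <- as.integer(table(cls))
  total <- nrow(ann)
  classes <- data.frame(
    consequence = consequence_classes(),
    count = counts,
    proportion = if (total > 0) counts / total else rep(NA_real_,
                                                        length(counts))
  )
  lof <- sum(classes$count[classes$consequence %in% lof_classes()])
  structure(
    list(classes = classes, total = total, lof_count = lof,
         lof_proportion = if (total > 0) lof / total else NA_real_),
    class = "consequence_tally"
  )
}

#' @export
print.consequence_tally <- function(x, ...) {
  cat("consequence_tally:", x$total, "variants;",
      x$lof_count, "loss-of-function\n")
  print(x$classes[x$classes$count > 0, ], row.names = FALSE)
  invisible(x)
}

#' Intersect two deleterious sets by variant key
#'
#' Used to find deleterious variants shared by two analyses (e.g. two tissue
#' cohorts). Severity is taken from `a`; keys whose severity bins disagree
#' between the sets are reported in the `severity_conflicts` attribute.
#'
#' @param a,b `deleterious_set` objects on comparable coordinates.
#' @return A `deleterious_set` restricted to shared keys (rows from `a`).
#' @export
intersect_dsnp_sets <- function(a, b) {
  stopifnot(inherits(a, "deleterious_set"), inherits(b, "deleterious_set"))
  shared <- intersect(a$key, b$key)
  out <- a[a$key %in% shared, , drop = FALSE]
  sev_b <- b$severity[match(out$key, b$key)]
  conflicts <- out$key[!is.na(out$severity) & !is.na(sev_b) &
                         out$severity != sev_b]
  rownames(out) <- NULL
  attr(out, "severity_conflicts") <- conflicts
  class(out) <- c("deleterious_set", "data.frame")
  out
}
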