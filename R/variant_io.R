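# Genotypes are coded 0 = homozygous reference, 1 = heterozygous,
# 2 = homozygous alternate throughout the package.

#' Build a site key
#'
#' Canonical per-variant identifier used to align genotype, annotation and
#' deleterious-set tables. Chromosome labels are kept verbatim and compared
#' case-sensitively; positions are 1-based.
#'
#' @param chrom,pos,ref,alt Vectors describing each variant.
#' @return Character vector `"chrom:pos_ref/alt"`.
#' @export
site_key <- function(chrom, pos, ref, alt) {
  if (length(chrom) == 0 || length(pos) == 0)
    return(character(0))  # paste0 would recycle the separators to length 1
  paste0(chrom, ":", pos, "_", ref, "/", alt)
}

new_variant_set <- function(sites, geno, samples, dp = NULL, ledger = NULL) {
  sites <- as.data.frame(sites)
  if (nrow(sites) != nrow(geno) || length(samples) != ncol(geno))
    stop("inconsistent variant set dimensions")
  if (anyDuplicated(sites$key))
    stop("duplicate site keys in variant set")
  rownames(geno) <- sites$key
  colnames(geno) <- samples
  if (!is.null(dp)) {
    rownames(dp) <- sites$key
    colnames(dp) <- samples
  }
  structure(
    list(sites = sites, geno = geno, dp = dp, samples = samples,
         ledger = ledger),
    class = "variant_set"
  )
}

#' Construct a variant set from a genotype matrix
#'
#' Builds the filtered-genotype container directly from a coded genotype
#' matrix (0 = hom ref, 1 = het, 2 = hom alt), e.g. for simulated or
#' hand-built fixtures. Site coordinates default to consecutive positions on
#' one chromosome with A/T alleles.
#'
#' @param geno Integer matrix, sites x samples.
#' @param chrom,pos,ref,alt Optional per-site coordinate vectors.
#' @param samples Sample ids; default `colnames(geno)` or `S1..Sn`.
#' @param qual Optional per-site quality scores.
#' @return A `variant_set`.
#' @export
variant_set <- function(geno, chrom = NULL, pos = NULL, ref = NULL,
                        alt = NULL, samples = NULL, qual = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("Chr01", n)
  if (is.null(pos)) pos <- seq_len(n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  if (is.null(samples))
    samples <- if (!is.null(colnames(geno))) colnames(geno)
               else sprintf("S%d", seq_len(ncol(geno)))
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      qual = if (is.null(qual)) NA_real_ else qual,
                      key = site_key(chrom, pos, ref, alt),
                      stringsAsFactors = FALSE)
  new_variant_set(sites, geno, samples)
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  if (!is.null(x$ledger)) {
    cat("filter ledger:\n")
    print(x$ledger, row.names = FALSE)
  }
  invisible(x)
}

#' Read a multi-sample VCF into a raw variant table
#'
#' Thin wrapper over [vcfR::read.vcfR()] that extracts the fields the
#' filtering stage needs: site coordinates, alleles, site quality, per-sample
#' genotype strings and per-genotype read depth (FORMAT `DP`). Indel and
#' multi-allelic records are retained but flagged; [filter_variants()] removes
#' them. Sample order is preserved.
#'
#' @param path Path to a VCF v4.x file (plain or gzipped). The GT FORMAT
#'   field must be present.
#' @return An object of class `raw_variant_table`: a list with elements
#'   `chrom`, `pos`, `ref`, `alt`, `qual`, `is_indel`, `is_multiallelic`,
#'   `gt` (character matrix sites x samples), `dp` (numeric matrix or NULL
#'   when the VCF carries no DP), and `samples`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n <- nrow(v@fix)
  samples <- if (ncol(v@gt) > 1) colnames(v@gt)[-1] else character(0)
  if (n > 0) {
    fmt <- v@gt[, 1]
    if (!all(grepl("(^|:)GT(:|$)", fmt)))
      stop("VCF format error: GT field missing from FORMAT column")
    gt <- vcfR::extract.gt(v, element = "GT")
    has_dp <- any(grepl("(^|:)DP(:|$)", fmt))
    dp <- if (has_dp) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
          else NULL
  } else {
    gt <- matrix(character(0), 0, length(samples),
                 dimnames = list(NULL, samples))
    dp <- NULL
  }
  alt <- if (n > 0) v@fix[, "ALT"] else character(0)
  ref <- if (n > 0) v@fix[, "REF"] else character(0)
  multi <- grepl(",", alt)
  # an indel has any allele longer than one base (or symbolic/missing)
  if (n > 0) {
    longest_alt <- vapply(strsplit(ifelse(is.na(alt), "", alt), ","),
                          function(a) if (length(a)) max(nchar(a)) else 0L,
                          integer(1))
    indel <- nchar(ifelse(is.na(ref), "", ref)) != 1L | longest_alt != 1L
  } else {
    indel <- logical(0)
  }
  structure(
    list(
      chrom = if (n > 0) v@fix[, "CHROM"] else character(0),
      pos = if (n > 0) as.integer(v@fix[, "POS"]) else integer(0),
      ref = ref, alt = alt,
      qual = if (n > 0) suppressWarnings(as.numeric(v@fix[, "QUAL"]))
             else numeric(0),
      is_indel = indel, is_multiallelic = multi,
      gt = gt, dp = dp, samples = samples
    ),
    class = "raw_variant_table"
  )
}

#' @export
print.raw_variant_table <- function(x, ...) {
  cat("raw_variant_table:", length(x$pos), "records,",
      length(x$samples), "samples (",
      sum(x$is_indel), "indel,", sum(x$is_multiallelic), "multi-allelic )\n")
  invisible(x)
}

code_genotypes <- function(gt) {
  # phased and unphased treated identically; half calls and anything beyond
  # the biallelic diploid vocabulary become missing
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[g %in% c("0/0")] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% c("1/1")] <- 2L
  out
}

#' Apply site and genotype quality filters
#'
#' Reduces a raw variant table to a complete biallelic SNP genotype matrix:
#' indel and multi-allelic sites are dropped, sites with quality below
#' `min_qual` are dropped, genotype calls with depth below `min_dp` (or with
#' no DP at all, when `min_dp > 0`) are set to missing, and -- when
#' `require_complete` -- any site retaining a missing call is dropped. The
#' defaults mirror a conventional `--max-alleles 2 --min-alleles 2 --minDP 10
#' --minQ 20 --max-missing 1` invocation.
#'
#' Each dropped site is attributed to the first rule it fails, in the fixed
#' order indel, multi-allelic, quality, missing-call, so the ledger counts
#' are deterministic and sum to the input site count.
#'
#' @param raw A `raw_variant_table` from [read_vcf()].
#' @param min_dp Minimum per-genotype read depth; calls below it become
#'   missing. `0` disables the depth check (e.g. for depth-free matrices).
#' @param min_qual Minimum site QUAL; sites with missing QUAL fail.
#' @param require_complete Drop any site with a remaining missing call.
#' @return A `variant_set` (sites, genotype matrix, retained depths, sample
#'   ids) with the filter ledger stored in `$ledger`. Zero surviving sites
#'   yields an empty set with a warning, not an error.
#' @export
filter_variants <- function(raw, min_dp = 10, min_qual = 20,
                            require_complete = TRUE) {
  stopifnot(inherits(raw, "raw_variant_table"))
  n <- length(raw$pos)
  state <- rep("pass", n)
  state[raw$is_indel] <- "dropped_indel"
  state[state == "pass" & raw$is_multiallelic] <- "dropped_multiallelic"
  qual_fail <- is.na(raw$qual) | raw$qual < min_qual
  state[state == "pass" & qual_fail] <- "dropped_qual"

  geno <- code_genotypes(raw$gt)
  dp <- raw$dp
  if (min_dp > 0) {
    if (is.null(dp)) {
      geno[] <- NA_integer_  # no depth information: conservative, all missing
    } else {
      geno[is.na(dp) | dp < min_dp] <- NA_integer_
    }
  }
  incomplete <- if (n > 0) rowSums(is.na(geno)) > 0 else logical(0)
  if (require_complete)
    state[state == "pass" & incomplete] <- "dropped_missing"

  keep <- state == "pass"
  ledger <- data.frame(
    rule = c("input", "dropped_indel", "dropped_multiallelic",
             "dropped_qual", "dropped_missing", "surviving"),
    n = c(n, sum(state == "dropped_indel"),
          sum(state == "dropped_multiallelic"),
          sum(state == "dropped_qual"),
          sum(state == "dropped_missing"), sum(keep))
  )
  sites <- data.frame(
    chrom = raw$chrom[keep], pos = raw$pos[keep],
    ref = raw$ref[keep], alt = raw$alt[keep],
    qual = raw$qual[keep],
    key = site_key(raw$chrom[keep], raw$pos[keep], raw$ref[keep],
                   raw$alt[keep]),
    stringsAsFactors = FALSE
  )
  if (sum(keep) == 0)
    warning("no sites survive filtering; returning an empty variant_set")
  new_variant_set(sites, geno[keep, , drop = FALSE], raw$samples,
                  dp = if (!is.null(dp)) dp[keep, , drop = FALSE] else NULL,
                  ledger = ledger)
}

#' Write a filtered variant set back to VCF
#'
#' Emits GT (and DP when retained) through [vcfR::write.vcf()]; output is
#' gzip-compressed, so `path` should normally end in `.vcf.gz`.
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  n <- nrow(vs$sites)
  fix <- cbind(
    CHROM = vs$sites$chrom, POS = as.character(vs$sites$pos), ID = NA,
    REF = vs$sites$ref, ALT = vs$sites$alt,
    QUAL = if (!is.null(vs$sites$qual)) as.character(vs$sites$qual) else NA,
    FILTER = NA, INFO = NA
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$geno + 1L], n,
                   length(vs$samples))
  if (!is.null(vs$dp)) {
    fmt <- "GT:DP"
    dp_str <- ifelse(is.na(vs$dp), ".", as.character(vs$dp))
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), n,
                     length(vs$samples))
  } else fmt <- "GT"
  gt <- cbind(FORMAT = rep(fmt, n), gt_str)
  colnames(gt) <- c("FORMAT", vs$samples)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
  )
  obj <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read per-accession conservation metadata
#'
#' Reads a TSV of accession covariates and validates the metadata contract:
#' years since the last regeneration cannot exceed years since acquisition,
#' zero regeneration cycles implies the two coincide, and RIN lies on the
#' 1-10 scale. Two dialects are accepted: elapsed years directly
#' (`y_acq`/`y_last` columns) or calendar years (`year_acquired`/
#' `year_last_regen`) together with a `reference_year` (the assay year)
#' from which elapsed years are computed.
#'
#' @param path TSV path with header columns `sample_id`, `country`,
#'   `r_cycles`, `rin` and either `y_acq`/`y_last` or
#'   `year_acquired`/`year_last_regen`.
#' @param reference_year Assay year; required for the calendar-year dialect.
#' @return A data.frame of class `accession_metadata` with columns
#'   `sample_id`, `country`, `y_acq`, `y_last`, `r_cycles`, `rin`.
#' @export
read_metadata <- function(path, reference_year = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df, reference_year = reference_year)
}

#' Validate an accession metadata table
#'
#' @param df Data frame in either metadata dialect (see [read_metadata()]).
#' @param reference_year Assay year for the calendar-year dialect.
#' @return The validated `accession_metadata` data.frame.
#' @export
validate_metadata <- function(df, reference_year = NULL) {
  need <- c("sample_id", "country", "r_cycles", "rin")
  if (!all(need %in% names(df)))
    stop("metadata is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (all(c("year_acquired", "year_last_regen") %in% names(df))) {
    if (is.null(reference_year))
      stop("calendar-year metadata requires reference_year")
    df$y_acq <- reference_year - df$year_acquired
    df$y_last <- reference_year - df$year_last_regen
  }
  if (!all(c("y_acq", "y_last") %in% names(df)))
    stop("metadata needs y_acq/y_last or year_acquired/year_last_regen")
  num <- c("y_acq", "y_last", "r_cycles", "rin")
  for (cl in num) {
    if (!is.numeric(df[[cl]]))
      stop("metadata column '", cl, "' is not numeric")
  }
  bad_row <- function(cond, what) {
    if (any(cond))
      stop("metadata validation failed (", what, ") at row(s) ",
           paste(which(cond), collapse = ", "))
  }
  bad_row(df$y_acq < 0 | df$y_last < 0 | df$r_cycles < 0,
          "negative covariate")
  bad_row(df$y_last > df$y_acq, "y_last > y_acq")
  bad_row(df$r_cycles == 0 & df$y_last != df$y_acq,
          "r_cycles = 0 requires y_last = y_acq")
  bad_row(df$rin < 1 | df$rin > 10, "RIN outside [1, 10]")
  out <- df[, c("sample_id", "country", "y_acq", "y_last", "r_cycles", "rin")]
  class(out) <- c("accession_metadata", "data.frame")
  out
}
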