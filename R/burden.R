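# Per-sample mutation-burden estimators, minor-allele-frequency spectra,
# and per-chromosome distributions.

#' Compute per-sample mutation burdens at deleterious loci
#'
#' For each sample, counts the deleterious loci at which it is heterozygous
#' (`n_het`) or homozygous (`n_hom`) for the deleterious allele and applies
#' the three per-deleterious-locus estimators with the study-wide locus count
#' `L = nrow(dset)` as denominator:
#' \deqn{B_{het} = n_{het} / (2L), \quad B_{hom} = 2 n_{hom} / (2L), \quad
#'       B_{tot} = (n_{het} + 2 n_{hom}) / (2L) = B_{het} + B_{hom}.}
#' The deleterious allele is taken to be the alternate allele of the scored
#' substitution (no outgroup polarization); supply `deleterious_allele` as a
#' named vector (`"ref"`/`"alt"` by site key) to override per site.
#'
#' @param vs A `variant_set` with a complete genotype matrix.
#' @param dset A `deleterious_set`; all keys must be present in `vs`.
#' @param deleterious_allele `"alt"` (default) or a character vector named by
#'   site key with entries `"ref"`/`"alt"`.
#' @return A data.frame of class `burden_table`: `sample_id`, `n_het`,
#'   `n_hom`, `L`, `b_het`, `b_hom`, `b_tot`.
#' @export
compute_burdens <- function(vs, dset, deleterious_allele = "alt") {
  stopifnot(inherits(vs, "variant_set"), inherits(dset, "deleterious_set"))
  L <- nrow(dset)
  if (L == 0) stop("no deleterious loci")
  missing_keys <- setdiff(dset$key, vs$sites$key)
  if (length(missing_keys))
    stop("deleterious keys absent from variant set: ",
         paste(utils::head(missing_keys, 5), collapse = ", "),
         if (length(missing_keys) > 5) " ...")
  g <- vs$geno[match(dset$key, vs$sites$key), , drop = FALSE]
  if (anyNA(g)) stop("genotype matrix has missing calls at deleterious loci")
  if (!identical(deleterious_allele, "alt")) {
    flip <- names(deleterious_allele)[deleterious_allele == "ref"]
    rows <- match(intersect(flip, rownames(g)), rownames(g))
    g[rows, ] <- 2L - g[rows, ]
  }
  n_het <- colSums(g == 1L)
  n_hom <- colSums(g == 2L)
  out <- data.frame(
    sample_id = vs$samples,
    n_het = as.integer(n_het), n_hom = as.integer(n_hom), L = L,
    b_het = n_het / (2 * L),
    b_hom = 2 * n_hom / (2 * L),
    b_tot = (n_het + 2 * n_hom) / (2 * L),
    row.names = NULL
  )
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Minor-allele-frequency spectrum of a genotype matrix
#'
#' Per site, the alternate-allele frequency is
#' `p = (2 * n_hom_alt + n_het) / (2 * n_samples)` and the MAF is
#' `min(p, 1 - p)`. Sites fixed for the alternate allele (every sample
#' homozygous alternate) and invariant heterozygous sites (every sample
#' heterozygous, MAF 0.5) are flagged, as are the rare and singleton MAF
#' bands.
#'
#' @param vs A `variant_set` with complete genotypes.
#' @param subset Optional character vector of site keys to restrict to.
#' @param singleton_max,rare_max Band thresholds (defaults 0.01 and 0.05).
#' @param breaks Histogram breaks over `[0, 0.5]`.
#' @return A data.frame of class `maf_spectrum` (`key`, `p_alt`, `maf`,
#'   `fixed`, `invariant_het`, `singleton_band`, `rare_band`) with the
#'   histogram counts in attribute `"histogram"`.
#' @export
maf_spectrum <- function(vs, subset = NULL, singleton_max = 0.01,
                         rare_max = 0.05, breaks = seq(0, 0.5, by = 0.05)) {
  stopifnot(inherits(vs, "variant_set"))
  g <- vs$geno
  if (!is.null(subset)) {
    miss <- setdiff(subset, rownames(g))
    if (length(miss)) stop("subset keys absent from variant set")
    g <- g[match(subset, rownames(g)), , drop = FALSE]
  }
  if (anyNA(g)) stop("genotype matrix has missing calls")
  ns <- ncol(g)
  p <- (2 * rowSums(g == 2L) + rowSums(g == 1L)) / (2 * ns)
  maf <- pmin(p, 1 - p)
  out <- data.frame(
    key = rownames(g), p_alt = p, maf = maf,
    fixed = rowSums(g == 2L) == ns,
    invariant_het = rowSums(g == 1L) == ns,
    singleton_band = maf <= singleton_max,
    rare_band = maf <= rare_max,
    row.names = NULL
  )
  bins <- cut(maf, breaks = breaks, include.lowest = TRUE, right = TRUE)
  attr(out, "histogram") <- data.frame(lower = utils::head(breaks, -1),
                                       upper = breaks[-1],
                                       count = as.integer(table(bins)))
  class(out) <- c("maf_spectrum", "data.frame")
  out
}

#' Per-chromosome SNP and deleterious-SNP distribution
#'
#' Counts sites per chromosome for the full SNP track and (optionally) the
#' deleterious track, and summarizes each with min, max and the mean over
#' `n_chrom` chromosomes -- the mean divisor is the expected chromosome count
#' even when some chromosomes carry no deleterious site.
#'
#' @param x A `variant_set`, or a character vector of chromosome labels.
#' @param dset Optional `deleterious_set` (or label vector) for the second
#'   track.
#' @param n_chrom Expected number of chromosomes (default 20).
#' @param chrom_levels Optional expected chromosome label set; labels outside
#'   it are counted under `"other"` with a warning.
#' @return A list of class `chrom_distribution`: `per_chrom` (data.frame
#'   `chrom`, `n_snp`, `n_dsnp`) and `summary` (per track: total, min, max,
#'   mean).
#' @export
chrom_distribution <- function(x, dset = NULL, n_chrom = 20,
                               chrom_levels = NULL) {
  labs <- if (inherits(x, "variant_set")) x$sites$chrom else as.character(x)
  dlabs <- if (is.null(dset)) character(0)
           else if (inherits(dset, "deleterious_set")) dset$chrom
           else as.character(dset)
  if (!is.null(chrom_levels)) {
    reassign <- function(v) {
      out <- !v %in% chrom_levels
      if (any(out)) {
        warning(sum(out), " site(s) on unexpected chromosome label(s); ",
                "counted under 'other'")
        v[out] <- "other"
      }
      v
    }
    labs <- reassign(labs)
    dlabs <- reassign(dlabs)
    lev <- c(chrom_levels, if ("other" %in% c(labs, dlabs)) "other")
  } else {
    lev <- sort(unique(c(labs, dlabs)))
  }
  n_snp <- table(factor(labs, levels = lev))
  n_dsnp <- table(factor(dlabs, levels = lev))
  per_chrom <- data.frame(chrom = lev, n_snp = as.integer(n_snp),
                          n_dsnp = as.integer(n_dsnp))
  summarize <- function(counts, total) {
    present <- counts[counts > 0]
    data.frame(total = total,
               min = if (length(present)) min(present) else 0L,
               max = if (length(present)) max(present) else 0L,
               mean = total / n_chrom)
  }
  smry <- rbind(
    cbind(track = "snp", summarize(per_chrom$n_snp, length(labs))),
    cbind(track = "dsnp", summarize(per_chrom$n_dsnp, length(dlabs)))
  )
  structure(list(per_chrom = per_chrom, summary = smry, n_chrom = n_chrom),
            class = "chrom_distribution")
}

#' @export
print.chrom_distribution <- function(x, ...) {
  cat("chrom_distribution over", x$n_chrom, "chromosomes\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
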