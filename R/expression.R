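# Per-sample summaries of the deleterious-SNP-associated gene expression
# matrix, and the dSNP -> gene mapping.

#' Summarize a TPM expression matrix per sample
#'
#' A gene is "expressed" in a sample when its TPM strictly exceeds `floor`
#' (default 0, i.e. presence/absence). Per sample the summary reports the
#' expressed gene count and the mean TPM across that sample's expressed genes
#' only; a sample with no expressed gene gets count 0 and an undefined (NA)
#' mean. Per gene, the number of samples in which it is expressed is tallied.
#'
#' @param mat Numeric genes x samples matrix of TPM values (rownames = gene
#'   ids, colnames = sample ids). TPM must be non-negative.
#' @param floor Expression floor; strictly-greater comparison.
#' @return A list of class `expression_summary`: `samples` (data.frame
#'   `sample_id`, `expressed_gene_count`, `mean_tpm`) and `genes`
#'   (data.frame `gene_id`, `n_samples_expressed`).
#' @export
summarize_expression <- function(mat, floor = 0) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression matrix must be a numeric matrix")
  if (any(mat < 0)) stop("TPM values must be non-negative")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("gene and sample ids must be unique")
  expressed <- mat > floor
  count <- colSums(expressed)
  total <- colSums(mat * expressed)
  mean_tpm <- ifelse(count > 0, total / count, NA_real_)
  structure(
    list(
      samples = data.frame(sample_id = colnames(mat),
                           expressed_gene_count = as.integer(count),
                           mean_tpm = mean_tpm, row.names = NULL),
      genes = data.frame(gene_id = rownames(mat),
                         n_samples_expressed = as.integer(rowSums(expressed)),
                         row.names = NULL),
      floor = floor
    ),
    class = "expression_summary"
  )
}

#' @export
print.expression_summary <- function(x, ...) {
  cat("expression_summary:", nrow(x$genes), "genes x", nrow(x$samples),
      "samples (floor ", x$floor, ")\n", sep = "")
  cat("expressed gene count: ",
      paste(range(x$samples$expressed_gene_count), collapse = "-"),
      "; mean TPM: ",
      paste(round(range(x$samples$mean_tpm, na.rm = TRUE), 2),
            collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Map deleterious variants to their associated genes
#'
#' Collapses a deleterious set to the unique genes it hits, with per-gene
#' deleterious-variant counts. Variants without a gene id are not silently
#' dropped: their keys are returned in the `unassigned` attribute.
#'
#' @param dset A `deleterious_set` carrying `gene_id`.
#' @return Data.frame `gene_id`, `n_dsnp`, sorted by decreasing count, with
#'   attribute `unassigned` (keys lacking a gene id).
#' @export
map_genes_to_dsnps <- function(dset) {
  stopifnot(inherits(dset, "deleterious_set"))
  has_gene <- !is.na(dset$gene_id) & dset$gene_id != ""
  tab <- table(dset$gene_id[has_gene])
  out <- data.frame(gene_id = as.character(names(tab)),
                    n_dsnp = as.integer(tab), row.names = NULL)
  out <- out[order(-out$n_dsnp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- dset$key[!has_gene]
  out
}
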