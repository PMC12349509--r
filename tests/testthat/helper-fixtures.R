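# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# records: data.frame(chrom, pos, ref, alt, qual) + a calls matrix of
# "GT:DP" strings (rows = records)
write_fixture_vcf <- function(records, calls, samples,
                              path = tempfile(fileext = ".vcf")) {
  body <- apply(cbind(records$chrom, records$pos, ".", records$ref,
                      records$alt, records$qual, ".", ".", "GT:DP",
                      calls), 1, paste, collapse = "\t")
  writeLines(c(vcf_header(samples), body), path)
  path
}

# the five-site filtering example: one triallelic, one low-qual, one with a
# single low-depth call, two clean
five_site_vcf <- function() {
  records <- data.frame(
    chrom = "Chr01", pos = c(100, 200, 300, 400, 500),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("T,G", "A", "C", "G", "C"),
    qual = c(90, 15, 80, 85, 95)
  )
  calls <- rbind(
    c("0/1:20", "0/0:30"),
    c("0/1:25", "1/1:25"),
    c("0/1:8",  "0/0:30"),
    c("1/1:12", "0/1:14"),
    c("0/0:40", "0/1:22")
  )
  write_fixture_vcf(records, calls, c("S1", "S2"))
}

# random complete genotype matrix + matching deleterious set over all sites
random_burden_fixture <- function(n_sites, n_samples,
                                  probs = c(0.7, 0.2, 0.1)) {
  geno <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE,
                        prob = probs), n_sites, n_samples)
  vs <- variant_set(geno)
  dset <- deleterious_set(vs$sites$chrom, vs$sites$pos, vs$sites$ref,
                          vs$sites$alt, rs_score = 2)
  list(vs = vs, dset = dset)
}

# literal allele-by-allele counting oracle for burdens: walks every
# (site, sample) genotype and tallies deleterious allele copies
burden_oracle <- function(vs, dset) {
  g <- vs$geno[match(dset$key, vs$sites$key), , drop = FALSE]
  L <- nrow(g)
  res <- lapply(seq_len(ncol(g)), function(j) {
    n_het <- 0L; n_hom <- 0L
    for (i in seq_len(L)) {
      gt <- g[i, j]
      if (gt == 1L) n_het <- n_het + 1L
      if (gt == 2L) n_hom <- n_hom + 1L
    }
    alleles_het <- n_het          # one deleterious allele per het locus
    alleles_hom <- 2L * n_hom     # two per hom locus
    data.frame(n_het = n_het, n_hom = n_hom,
               b_het = alleles_het / (2 * L),
               b_hom = alleles_hom / (2 * L),
               b_tot = (alleles_het + alleles_hom) / (2 * L))
  })
  do.call(rbind, res)
}

# minimal annotation data.frame with sensible defaults
ann_df <- function(n, consequence = "missense_variant", sift = 0.01,
                   conf = "normal", rs = 2, gene = "G1", chrom = "Chr01",
                   pos = NULL) {
  data.frame(
    chrom = chrom, pos = if (is.null(pos)) seq_len(n) else pos,
    ref = "A", alt = "T", gene_id = gene, consequence = consequence,
    sift_score = sift, sift_confidence = conf, rs_score = rs,
    stringsAsFactors = FALSE
  )
}

small_sim_config <- function(...) {
  # expression panel and expressed-count model rescaled to the smaller
  # gene panel so counts vary inside [n_core, n_genes]
  sim_config(n_samples = 40, n_del_sites = 120, n_decoy = 150,
             n_gene_pool = 120,
             expression_model = utils::modifyList(
               sim_config()$expression_model,
               list(n_genes = 60, n_core = 30, gc_intercept = 48,
                    gc_sd = 3)),
             ...)
}
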