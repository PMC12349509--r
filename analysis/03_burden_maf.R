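#!/usr/bin/env Rscript
# Per-accession mutation burdens at the deleterious loci, the MAF spectrum of
# both tracks, and the per-chromosome distribution.

library(germburden)

vs <- filter_variants(read_vcf("scratch/simdata/genotypes.vcf.gz"))
ann <- read_annotation("scratch/simdata/annotation.tsv")
ann <- ann[ann$key %in% vs$sites$key, ]
class(ann) <- c("annotation_table", "data.frame")
dset <- classify_deleterious(ann)

burden <- compute_burdens(vs, dset)
write.table(burden, "results/burden.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("total burden: %.3f-%.3f (mean %.3f, sd %.3f)\n",
            min(burden$b_tot), max(burden$b_tot), mean(burden$b_tot),
            sd(burden$b_tot)))
cat(sprintf("heterozygous %.4f +/- %.4f; homozygous %.4f +/- %.4f\n",
            mean(burden$b_het), sd(burden$b_het),
            mean(burden$b_hom), sd(burden$b_hom)))
stopifnot(all(abs(burden$b_tot - (burden$b_het + burden$b_hom)) < 1e-15))

maf_all <- maf_spectrum(vs)
maf_d <- maf_spectrum(vs, subset = dset$key)
cat(sprintf("SNPs: %d; rare (MAF <= 0.05) %.1f%%; invariant het %.1f%%\n",
            nrow(maf_all), 100 * mean(maf_all$rare_band),
            100 * mean(maf_all$invariant_het)))
cat(sprintf("dSNPs: %d; rare %.1f%%; singleton band %.1f%%; fixed %d\n",
            nrow(maf_d), 100 * mean(maf_d$rare_band),
            100 * mean(maf_d$singleton_band), sum(maf_d$fixed)))
write.table(maf_d, "results/dsnp_maf.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cd <- chrom_distribution(vs, dset, n_chrom = 20)
print(cd)
write.table(cd$per_chrom, "results/chrom_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
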