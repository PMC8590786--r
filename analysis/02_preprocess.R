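#!/usr/bin/env Rscript
# Stage 2: genotype and expression QC plus covariate construction --
# MAF/missingness SNP filters, expressed-gene filter (median FPKM > 0),
# per-gene rank-based inverse normal transform, 20 latent expression
# factors (PC surrogate for PEER) screened for factor-QTLs, and 5
# genotype PCs.

source("analysis/00_common.R")

geno <- read_vcf_genotypes(run_path("genotypes.vcf"))
expr <- read_expression(run_path("expression_fpkm.tsv"))

n0 <- ncol(geno$dosage)
geno <- filter_snps(geno, maf_min = 0.05, miss_max = 0.2)
say("SNP filter kept", ncol(geno$dosage), "of", n0)

expr_eqtl <- filter_genes_for_eqtl(expr)
say("expressed-gene filter kept", nrow(expr_eqtl), "of", nrow(expr))

expr_norm <- normalize_expression(expr_eqtl)
gpcs <- genotype_pcs(geno, n_pcs = 5)
lf <- latent_factors(expr_norm, K = 20)
say(sprintf("20 latent factors capture %.1f%% of expression variance",
            100 * max(attr(lf, "cum_var_explained"))))
lf <- drop_genetic_factors(lf, geno, gpcs)
if (length(attr(lf, "dropped")) > 0)
  say("factor-QTL screen dropped:", paste(attr(lf, "dropped"),
                                          collapse = ", "))

write_vcf(geno, run_path("genotypes_filtered.vcf"))
write_expression(expr_norm, run_path("expression_normalized.tsv"))
covs <- cbind(lf, gpcs)
write.table(data.frame(sample_id = rownames(covs), covs),
            run_path("covariates.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
say("covariate set:", ncol(covs), "columns")
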