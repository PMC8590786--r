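#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panel with planted ground truth --
# 206 individuals in two subpopulations, 5000 SNPs, 1000 genes in three
# co-expression modules, one trans master regulator driving module 1, and
# stone-cell/lignin/cellulose traits driven by that module.

source("analysis/00_common.R")

cfg <- sim_config(seed = SEED)
d <- simulate_dataset(cfg)

write_vcf(d$genotypes, run_path("genotypes.vcf"))
write_gene_models(d$annotation, run_path("gene_models.tsv"))
cl <- attr(d$annotation, "chrom_lengths")
write.table(data.frame(chrom = names(cl), length = as.integer(cl)),
            run_path("chrom_lengths.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_expression(d$expr, run_path("expression_fpkm.tsv"))
write_expression(d$dev_expr, run_path("expression_dev.tsv"))
write_traits(d$traits, run_path("traits.tsv"))
write_proteins(d$proteins, run_path("proteins.faa"))
write_truth(d$truth, run_path("truth.txt"))

say("panel:", length(d$genotypes$sample_ids), "individuals,",
    ncol(d$genotypes$dosage), "SNPs,", nrow(d$expr), "genes")
say("planted regulator:", d$truth$regulator_gene, "at SNP",
    d$truth$regulator_snp, "driving", length(d$truth$regulated_genes),
    "module-1 genes")
say("stone-cell content spans",
    sprintf("%.1f-%.1f g/100 g (%.1f-fold)", min(d$traits$stone_cell),
            max(d$traits$stone_cell),
            max(d$traits$stone_cell) / min(d$traits$stone_cell)))
say("suggested local window from intergenic gaps:",
    derive_local_window(d$annotation, 0.90) / 1000, "kb")
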