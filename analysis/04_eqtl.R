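#!/usr/bin/env Rscript
# Stage 4: all-pairs eQTL scan -- linear model per SNP-gene pair with
# latent-factor and genotype-PC covariates, Bonferroni threshold at
# alpha = 0.05 over the full test grid, greedy leading-SNP collapse in
# 20-kb windows, local/distant classification, and permutation-based
# distant-eQTL hotspot calling in 1-Mb windows (1000 permutations,
# p <= 0.01).

source("analysis/00_common.R")

geno <- read_vcf_genotypes(run_path("genotypes_filtered.vcf"))
expr_norm <- read_expression(run_path("expression_normalized.tsv"))
covs <- read.delim(run_path("covariates.tsv"))
covs <- as.matrix(covs[, -1, drop = FALSE])
models <- read_gene_models(run_path("gene_models.tsv"))
cl <- read.delim(run_path("chrom_lengths.tsv"))
chrom_lengths <- setNames(cl$length, cl$chrom)

thr <- bonferroni_threshold(ncol(geno$dosage), nrow(expr_norm), 0.05)
say(sprintf("Bonferroni threshold: %.3g over %d x %d tests", thr,
            ncol(geno$dosage), nrow(expr_norm)))

assoc <- eqtl_scan(geno, expr_norm, covariates = covs, p_keep = thr)
say(nrow(assoc), "significant SNP-gene pairs for",
    length(unique(assoc$gene_id)), "genes")

pos <- match(assoc$snp_id, geno$snp_ids)
assoc$snp_chrom <- geno$snp_chrom[pos]
assoc$snp_pos <- geno$snp_pos[pos]
leaders <- do.call(rbind, lapply(split(assoc, assoc$gene_id),
                                 collapse_leading_snps, window = 20000))
leaders <- classify_local_distant(leaders, models, local_window = 20000)
rownames(leaders) <- NULL
say(nrow(leaders), "eQTLs after leading-SNP collapse:",
    sum(leaders$class == "local"), "local,",
    sum(leaders$class == "distant"), "distant")

hs <- hotspot_detection(leaders[leaders$class == "distant", ],
                        chrom_lengths, window_bp = 1e6, n_perm = 1000,
                        alpha = 0.01, seed = SEED + 7L)
flagged <- hs$windows[hs$windows$hotspot, ]
say("hotspot cutoff:", hs$cutoff, "eQTLs/Mb;", nrow(flagged),
    "hotspot window(s)")
if (nrow(flagged) > 0)
  say("hotspots:", paste(sprintf("%s:%d-%d (%d eQTLs)", flagged$chrom,
                                 flagged$start, flagged$end,
                                 flagged$count), collapse = "; "))

write.table(leaders, run_path("eqtls.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(hs$windows, run_path("hotspots.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
publish("eqtls.tsv")
publish("hotspots.tsv")
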