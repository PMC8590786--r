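#!/usr/bin/env Rscript
# Stage 3: co-expression module detection and trait association --
# unsigned soft-threshold adjacency (beta = 5) on log2(FPKM + 1), TOM,
# average-linkage clustering, eigengene merging at dissimilarity 0.3,
# module-trait association (p <= 0.01) against stone-cell content, and
# per-gene trait significance (p < 0.05) within the selected modules.

source("analysis/00_common.R")

expr <- read_expression(run_path("expression_fpkm.tsv"))
traits <- read_traits(run_path("traits.tsv"))

expr_mod <- filter_genes_for_modules(expr, min_mean_fpkm = 1)
say("mean-FPKM filter kept", nrow(expr_mod), "of", nrow(expr))

expr_log <- log2(expr_mod + 1)
tom <- tom_similarity(soft_adjacency(expr_log, beta = 5))
labels <- detect_modules(tom, min_module_size = 30)
labels <- merge_modules(expr_log, labels, threshold = 0.3)
sizes <- table(labels[labels > 0])
say("modules:", length(sizes), "(sizes:",
    paste(sort(as.integer(sizes), decreasing = TRUE), collapse = ", "),
    ");", sum(labels == 0), "genes unassigned")

me <- module_eigengenes(expr_log, labels)
stone <- traits$stone_cell[match(colnames(expr), traits$sample_id)]
sel <- select_trait_modules(me, stone, p_max = 0.01)
assoc <- attr(sel, "association")
say("stone-cell-associated modules (p <= 0.01):",
    paste(sel, collapse = ", "))

in_sel <- names(labels)[labels %in% sel]
gts <- gene_trait_significance(expr_log[in_sel, , drop = FALSE], stone,
                               p_max = 0.05)
say(nrow(gts), "genes in those modules are trait-significant (p < 0.05)")

write.table(data.frame(gene_id = names(labels), module = labels),
            run_path("module_assignment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_expression(me, run_path("module_eigengenes.tsv"))
write.table(assoc, run_path("module_trait.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(gts, run_path("gene_trait.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
publish("module_trait.tsv")

# sanity against the planted labels
truth <- read_truth(run_path("truth.txt"))
if (requireNamespace("mclust", quietly = TRUE)) {
  ari <- mclust::adjustedRandIndex(labels, truth$module_of_gene[names(labels)])
  say(sprintf("adjusted Rand index vs planted modules: %.3f", ari))
}
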