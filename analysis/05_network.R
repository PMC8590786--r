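#!/usr/bin/env Rscript
# Stage 5: targeted structural-gene x TF co-expression network -- merge
# the population panel with the developmental panel, TOM at soft power 9
# on log2(FPKM + 1), edges at weight >= 0.01, and permutation hub calling
# (1000 permutations, p <= 0.01).

source("analysis/00_common.R")

expr <- read_expression(run_path("expression_fpkm.tsv"))
dev <- read_expression(run_path("expression_dev.tsv"))
truth <- read_truth(run_path("truth.txt"))
gts <- read.delim(run_path("gene_trait.tsv"))

merged <- log2(merge_expression_panels(expr, dev,
                                       prefixes = c("pop", "dev")) + 1)
say("merged panel:", ncol(merged), "samples")

tf_ids <- intersect(truth$tf_ids, rownames(merged))
structural <- setdiff(intersect(gts$gene_id, truth$structural_genes),
                      tf_ids)
say(length(structural), "trait-significant structural genes,",
    length(tf_ids), "TFs")

graph <- build_targeted_network(merged, structural, tf_ids, beta = 9,
                                weight_min = 0.01)
say(nrow(graph$edges), "edges;", length(graph$excluded_structural),
    "structural gene(s) without a TF edge excluded")

hubs <- hub_detection(graph, n_perm = 1000, alpha = 0.01, seed = SEED + 8L)
say("hub degree cutoff:", hubs$cutoff, ";", length(hubs$hubs), "hub(s)")
say("planted regulator", truth$regulator_gene, "is",
    if (truth$regulator_gene %in% hubs$hubs) "a hub" else "not a hub",
    sprintf("(degree %d)", hubs$degrees[truth$regulator_gene]))

write.table(graph$nodes, run_path("network_nodes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(graph$edges, run_path("network_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(hubs$degrees),
                       degree = hubs$degrees,
                       hub = names(hubs$degrees) %in% hubs$hubs),
            run_path("network_hubs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
publish("network_hubs.tsv")
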