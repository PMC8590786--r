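#!/usr/bin/env Rscript
# Stage 6: regulator nomination -- intersect the structural genes' eQTL
# regions (leading SNP +/- 20 kb) with the co-expression network, rank
# candidates by the number of distinct regulated structural genes, and
# scan candidate TF proteins for the secondary-cell-wall NAC LP-/WQ-box
# motifs.

source("analysis/00_common.R")

leaders <- read.delim(run_path("eqtls.tsv"))
nodes <- read.delim(run_path("network_nodes.tsv"))
edges <- read.delim(run_path("network_edges.tsv"))
models <- read_gene_models(run_path("gene_models.tsv"))
truth <- read_truth(run_path("truth.txt"))

graph <- structure(list(nodes = nodes, edges = edges,
                        excluded_structural = character(0),
                        beta = 9, weight_min = 0.01),
                   class = "coexpr_graph")
structural <- nodes$gene_id[nodes$role == "structural"]
recs <- leaders[leaders$gene_id %in% structural, ]
say(nrow(recs), "eQTL records for networked structural genes (",
    sum(recs$class == "local"), "local /", sum(recs$class == "distant"),
    "distant )")

cands <- identify_regulators(recs, graph, models, region_halfwidth = 20000)
say(nrow(cands), "candidate regulator(s)")
if (nrow(cands) > 0) {
  top <- cands[1, ]
  say(sprintf("rank 1: %s (%s, support %d structural genes)",
              top$regulator_gene, top$mode, top$support))
  say("planted regulator recovered at rank 1:",
      top$regulator_gene == truth$regulator_gene)
}

prot <- read_proteins(run_path("proteins.faa"))
motifs <- scan_scw_motifs(prot)
say(nrow(motifs), "motif hit(s):",
    paste(sprintf("%s(%s@%d)", motifs$seq_id, motifs$motif, motifs$offset),
          collapse = ", "))
say("rank-1 candidate carries LP+WQ boxes:",
    nrow(cands) > 0 &&
      all(c("LP", "WQ") %in% motifs$motif[motifs$seq_id ==
                                            cands$regulator_gene[1]]))

write.table(as.data.frame(cands), run_path("candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(motifs, run_path("motif_hits.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
publish("candidates.tsv")
publish("motif_hits.tsv")
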