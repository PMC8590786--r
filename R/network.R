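#' Merge two expression panels on their shared gene set
#'
#' Column-wise concatenation on the gene intersection; sample ids are made
#' unique with panel prefixes. Used to pool the population panel with the
#' developmental panel before building the targeted network.
#'
#' @param panel_a,panel_b genes x samples matrices.
#' @param prefixes length-2 character, panel prefixes for sample ids.
#' @return merged genes x samples matrix; attribute `n_shared_genes`.
#' @export
merge_expression_panels <- function(panel_a, panel_b,
                                    prefixes = c("a", "b")) {
  shared <- intersect(rownames(panel_a), rownames(panel_b))
  if (length(shared) == 0) stop("panels share no genes")
  out <- cbind(panel_a[shared, , drop = FALSE],
               panel_b[shared, , drop = FALSE])
  ids_a <- colnames(panel_a) %||% seq_len(ncol(panel_a))
  ids_b <- colnames(panel_b) %||% seq_len(ncol(panel_b))
  colnames(out) <- c(paste(prefixes[1], ids_a, sep = "."),
                     paste(prefixes[2], ids_b, sep = "."))
  attr(out, "n_shared_genes") <- length(shared)
  out
}

#' Build the targeted structural-gene x TF co-expression network
#'
#' Computes the TOM over the union of structural and TF genes at soft
#' power `beta` and keeps edges with weight `>= weight_min`. All edge
#' types are retained internally; structural genes with no TF edge are
#' reported as excluded (they cannot participate in regulator calling).
#'
#' @param expr_merged genes x samples matrix containing all listed genes.
#' @param structural_ids,tf_ids disjoint gene id vectors, subsets of the
#'   expression rows.
#' @param beta soft power (default 9).
#' @param weight_min TOM edge threshold (default 0.01).
#' @return list of class `coexpr_graph`: `nodes` (`gene_id`, `role`),
#'   `edges` (`gene_a`, `gene_b`, `weight`, unordered unique pairs),
#'   `excluded_structural`, `beta`, `weight_min`.
#' @export
build_targeted_network <- function(expr_merged, structural_ids, tf_ids,
                                   beta = 9, weight_min = 0.01) {
  if (length(structural_ids) == 0 || length(tf_ids) == 0)
    stop("structural and TF id lists must be non-empty")
  if (length(intersect(structural_ids, tf_ids)) > 0)
    stop("structural and TF id lists must be disjoint")
  ids <- c(structural_ids, tf_ids)
  missing <- setdiff(ids, rownames(expr_merged))
  if (length(missing) > 0)
    stop("genes absent from expression: ", paste(missing, collapse = ", "))
  tom <- tom_similarity(soft_adjacency(expr_merged[ids, , drop = FALSE],
                                       beta = beta))
  ut <- which(upper.tri(tom) & tom >= weight_min, arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[ut[, 1]], gene_b = ids[ut[, 2]],
                      weight = tom[ut])
  role <- ifelse(ids %in% tf_ids, "TF", "structural")
  deg_tf <- vapply(structural_ids, function(g) {
    sum((edges$gene_a == g & edges$gene_b %in% tf_ids) |
          (edges$gene_b == g & edges$gene_a %in% tf_ids))
  }, numeric(1))
  structure(list(nodes = data.frame(gene_id = ids, role = role),
                 edges = edges,
                 excluded_structural = structural_ids[deg_tf == 0],
                 beta = beta, weight_min = weight_min),
            class = "coexpr_graph")
}

#' Node degrees of a co-expression graph
#'
#' @param graph a `coexpr_graph`.
#' @return named integer vector over all nodes (zeros included).
#' @export
graph_degrees <- function(graph) {
  nodes <- graph$nodes$gene_id
  d <- table(factor(c(graph$edges$gene_a, graph$edges$gene_b),
                    levels = nodes))
  setNames(as.integer(d), nodes)
}

#' Permutation-based hub detection
#'
#' Each observed edge is reassigned to a uniformly chosen unordered pair
#' of distinct nodes (multi-assignment allowed), `n_perm` times; node
#' degrees are pooled across permutations. The cutoff is the smallest
#' degree `d` with pooled exceedance fraction `<= alpha`; observed nodes
#' at or above it are hubs.
#'
#' @param graph a `coexpr_graph` with at least 2 nodes and 1 edge.
#' @param n_perm permutations (default 1000).
#' @param alpha exceedance level (default 0.01).
#' @param seed RNG seed.
#' @return list with `hubs` (gene ids), `cutoff`, `degrees` (observed).
#' @export
hub_detection <- function(graph, n_perm = 1000, alpha = 0.01, seed = 1) {
  nodes <- graph$nodes$gene_id
  V <- length(nodes)
  E <- nrow(graph$edges)
  stopifnot(V >= 2, E >= 1)
  obs <- graph_degrees(graph)
  null_deg <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_len(n_perm), function(i) {
      a <- sample.int(V, E, replace = TRUE)
      b <- sample.int(V - 1L, E, replace = TRUE)
      b <- ifelse(b >= a, b + 1L, b)      # second endpoint != first
      tabulate(c(a, b), nbins = V)
    }), use.names = FALSE)
  })
  cutoff <- NA_real_
  for (d in 0:(max(null_deg, obs) + 1L)) {
    if (mean(null_deg >= d) <= alpha) { cutoff <- d; break }
  }
  list(hubs = names(obs)[obs >= cutoff], cutoff = cutoff, degrees = obs)
}

# internal: unordered-pair edge-weight lookup table from a graph
.edge_weights <- function(graph) {
  key <- ifelse(graph$edges$gene_a < graph$edges$gene_b,
                paste(graph$edges$gene_a, graph$edges$gene_b),
                paste(graph$edges$gene_b, graph$edges$gene_a))
  setNames(graph$edges$weight, key)
}

#' Nominate candidate regulators from eQTL regions and co-expression
#'
#' For each eQTL record of a structural gene, the candidate region is the
#' leading SNP +/- `region_halfwidth`. Any annotated gene overlapping that
#' region which is co-expressed with (has a graph edge to) the record's
#' structural gene is a candidate; its mode is inherited from the eQTL
#' class. Candidates are aggregated across records and ranked by support
#' (number of distinct regulated structural genes), ties broken by total
#' edge weight to those genes.
#'
#' @param eqtl_records classified eQTL records (`gene_id`, `snp_id`,
#'   `snp_chrom`, `snp_pos`, `class`) restricted to structural genes.
#' @param graph a `coexpr_graph`.
#' @param gene_models gene-model `data.frame`.
#' @param region_halfwidth bp (default 20000).
#' @return `data.frame` of class `regulator_candidates`, ranked: columns
#'   `regulator_gene`, `mode`, `support`, `total_weight`,
#'   `regulated_genes` (comma-joined), `regions` (comma-joined
#'   chrom:start-end).
#' @export
identify_regulators <- function(eqtl_records, graph, gene_models,
                                region_halfwidth = 20000) {
  empty <- data.frame(regulator_gene = character(0), mode = character(0),
                      support = integer(0), total_weight = numeric(0),
                      regulated_genes = character(0), regions = character(0))
  class(empty) <- c("regulator_candidates", "data.frame")
  if (nrow(eqtl_records) == 0 || nrow(graph$edges) == 0) return(empty)
  w <- .edge_weights(graph)
  hits <- list()
  for (i in seq_len(nrow(eqtl_records))) {
    rec <- eqtl_records[i, ]
    lo <- rec$snp_pos - region_halfwidth
    hi <- rec$snp_pos + region_halfwidth
    in_region <- gene_models$chrom == rec$snp_chrom &
      gene_models$start <= hi & gene_models$end >= lo
    cand <- gene_models$gene_id[in_region]
    cand <- setdiff(cand, rec$gene_id)
    if (length(cand) == 0) next
    key <- ifelse(cand < rec$gene_id, paste(cand, rec$gene_id),
                  paste(rec$gene_id, cand))
    ew <- unname(w[key])
    linked <- !is.na(ew)
    if (!any(linked)) next
    hits[[length(hits) + 1L]] <- data.frame(
      regulator_gene = cand[linked],
      target = rec$gene_id,
      mode = rec$class,
      weight = ew[linked],
      region = sprintf("%s:%d-%d", rec$snp_chrom, as.integer(lo),
                       as.integer(hi)))
  }
  if (length(hits) == 0) return(empty)
  h <- do.call(rbind, hits)
  out <- do.call(rbind, lapply(split(h, h$regulator_gene), function(d) {
    first <- !duplicated(d$target)
    data.frame(
      regulator_gene = d$regulator_gene[1],
      mode = paste(sort(unique(d$mode)), collapse = "+"),
      support = length(unique(d$target)),
      total_weight = sum(d$weight[first]),
      regulated_genes = paste(sort(unique(d$target)), collapse = ","),
      regions = paste(sort(unique(d$region)), collapse = ","))
  }))
  out <- out[order(-out$support, -out$total_weight, out$regulator_gene), ]
  rownames(out) <- NULL
  class(out) <- c("regulator_candidates", "data.frame")
  out
}

#' Scan proteins for the LP-box and WQ-box NAC activation motifs
#'
#' Exact bracket-pattern matching of the secondary-cell-wall NAC signature
#' motifs LP-box `F[ML]QLPQLESP[KS]` and WQ-box
#' `DQ[VL]TDWRALD[KR][LF][VL]AS[QH]L[SN]Q[DE]D`; each bracket matches one
#' position. All non-overlapping hits are reported with 1-based offsets.
#' Sequences containing non-amino-acid characters trigger a warning and
#' are scanned as-is (such positions cannot match).
#'
#' @param seqs named character vector of amino-acid sequences.
#' @return `data.frame` with `seq_id`, `motif` (`"LP"` or `"WQ"`),
#'   `offset`.
#' @export
scan_scw_motifs <- function(seqs) {
  if (length(seqs) == 0) {
    return(data.frame(seq_id = character(0), motif = character(0),
                      offset = integer(0)))
  }
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)))
    warning("non-amino-acid characters present; they cannot match")
  pats <- c(LP = .LP_BOX, WQ = .WQ_BOX)
  out <- list()
  for (motif in names(pats)) {
    for (id in names(seqs)) {
      m <- gregexpr(pats[[motif]], seqs[[id]])[[1]]
      if (m[1] != -1L) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = id, motif = motif, offset = as.integer(m))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq_id = character(0), motif = character(0),
                      offset = integer(0)))
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}
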