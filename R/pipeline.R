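#' Default pipeline configuration
#'
#' One flat list of stage toggles and parameters. Defaults are the study
#' values: module soft power 5 with eigengene-merge dissimilarity 0.3,
#' network soft power 9 with TOM edge threshold 0.01, MAF > 0.05 and
#' missingness < 0.2, 20 latent factors and 5 genotype PCs, Bonferroni
#' alpha 0.05, 20-kb local/clump/region windows, 1-Mb hotspot windows,
#' 1000 permutations at p <= 0.01, gene-trait p < 0.05.
#'
#' @param out_dir run directory (created if needed).
#' @param seed integer master seed; stage substreams derive from it.
#' @param sim a [sim_config()] for the simulate stage (its seed defaults
#'   to `seed`).
#' @return a named list of class `run_config`.
#' @export
default_config <- function(out_dir = tempfile("coexqtl_run_"), seed = 1L,
                           sim = sim_config(seed = seed)) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("simulate", "preprocess", "modules", "eqtl", "network",
               "regulators"),
    maf_min = 0.05, miss_max = 0.2,
    k_factors = 20L, n_geno_pcs = 5L, screen_genetic_factors = TRUE,
    beta_modules = 5, min_module_size = 30L, merge_diss = 0.3,
    module_p = 0.01, gene_trait_p = 0.05,
    alpha = 0.05, local_window = 20000, hotspot_window = 1e6,
    n_perm = 1000L, perm_p = 0.01,
    beta_network = 9, tom_min = 0.01, region_halfwidth = 20000,
    sim = sim
  ), class = "run_config")
}

# internal: path helper + dependency check
.artifact <- function(cfg, name) file.path(cfg$out_dir, name)

.require_artifacts <- function(cfg, stage, files, produced_by) {
  missing <- files[!file.exists(vapply(files, function(f) .artifact(cfg, f),
                                       character(1)))]
  if (length(missing) > 0)
    stop("stage '", stage, "' requires outputs of stage '", produced_by,
         "' (missing: ", paste(missing, collapse = ", "), ")",
         call. = FALSE)
}

# internal: one manifest row
.manifest_row <- function(cfg, stage, params, files) {
  paths <- vapply(files, function(f) .artifact(cfg, f), character(1))
  data.frame(
    stage = stage,
    seed = cfg$seed,
    params = paste(names(params),
                   vapply(params, function(v) paste(v, collapse = ","),
                          character(1)),
                   sep = "=", collapse = ";"),
    files = paste(files, collapse = ","),
    md5 = paste(unname(tools::md5sum(paths)), collapse = ","),
    rows = paste(vapply(paths, function(p) length(readLines(p)) - 1L,
                        integer(1)), collapse = ","))
}

#' Run the systems-genetics pipeline end to end
#'
#' Executes the enabled stages in fixed order (simulate, preprocess,
#' modules, eqtl, network, regulators), writing each stage's tables under
#' `cfg$out_dir` plus a run manifest (`manifest.tsv`) recording
#' parameters, seed and output checksums. Re-running with the same
#' configuration and seed reproduces all outputs byte-identically.
#'
#' @param cfg a [default_config()] list (unknown keys are rejected).
#' @return invisibly, a list with the key in-memory results per stage and
#'   the manifest `data.frame`.
#' @export
run_pipeline <- function(cfg = default_config()) {
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  bad <- setdiff(cfg$stages, c("simulate", "preprocess", "modules", "eqtl",
                               "network", "regulators"))
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  state <- list()

  log_msg <- function(...) message("[coexqtl] ", ...)

  if ("simulate" %in% cfg$stages) {
    sim <- simulate_dataset(cfg$sim)
    write_vcf(sim$genotypes, .artifact(cfg, "genotypes.vcf"))
    write_gene_models(sim$annotation, .artifact(cfg, "gene_models.tsv"))
    cl <- attr(sim$annotation, "chrom_lengths")
    write.table(data.frame(chrom = names(cl), length = as.integer(cl)),
                .artifact(cfg, "chrom_lengths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_expression(sim$expr, .artifact(cfg, "expression_fpkm.tsv"))
    write_expression(sim$dev_expr, .artifact(cfg, "expression_dev.tsv"))
    write_traits(sim$traits, .artifact(cfg, "traits.tsv"))
    write_proteins(sim$proteins, .artifact(cfg, "proteins.faa"))
    write_truth(sim$truth, .artifact(cfg, "truth.txt"))
    state$sim <- sim
    files <- c("genotypes.vcf", "gene_models.tsv", "chrom_lengths.tsv",
               "expression_fpkm.tsv", "expression_dev.tsv", "traits.tsv",
               "proteins.faa", "truth.txt")
    manifest$simulate <- .manifest_row(cfg, "simulate", unclass(cfg$sim),
                                       files)
    log_msg("simulate: ", nrow(sim$expr), " genes, ",
            ncol(sim$genotypes$dosage), " SNPs, ",
            length(sim$genotypes$sample_ids), " individuals")
  }

  if ("preprocess" %in% cfg$stages) {
    .require_artifacts(cfg, "preprocess",
                       c("genotypes.vcf", "expression_fpkm.tsv"), "simulate")
    geno <- read_vcf_genotypes(.artifact(cfg, "genotypes.vcf"))
    expr <- read_expression(.artifact(cfg, "expression_fpkm.tsv"))
    n0 <- ncol(geno$dosage)
    geno <- filter_snps(geno, cfg$maf_min, cfg$miss_max)
    log_msg("preprocess: SNP filter kept ", ncol(geno$dosage), "/", n0)
    e0 <- nrow(expr)
    expr_eqtl <- filter_genes_for_eqtl(expr)
    log_msg("preprocess: expressed-gene filter kept ", nrow(expr_eqtl),
            "/", e0)
    expr_norm <- normalize_expression(expr_eqtl)
    gpcs <- genotype_pcs(geno, cfg$n_geno_pcs)
    lf <- latent_factors(expr_norm, cfg$k_factors)
    if (isTRUE(cfg$screen_genetic_factors)) {
      lf <- drop_genetic_factors(lf, geno, gpcs)
      if (length(attr(lf, "dropped")) > 0)
        log_msg("preprocess: dropped genetically driven factor(s): ",
                paste(attr(lf, "dropped"), collapse = ", "))
    }
    covs <- cbind(lf, gpcs)
    write_expression(expr_norm, .artifact(cfg, "expression_normalized.tsv"))
    write.table(data.frame(sample_id = rownames(covs), covs),
                .artifact(cfg, "covariates.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$geno <- geno
    state$expr <- expr
    state$expr_norm <- expr_norm
    state$covariates <- covs
    manifest$preprocess <- .manifest_row(
      cfg, "preprocess",
      list(maf_min = cfg$maf_min, miss_max = cfg$miss_max,
           k_factors = cfg$k_factors, n_geno_pcs = cfg$n_geno_pcs,
           screened = isTRUE(cfg$screen_genetic_factors)),
      c("expression_normalized.tsv", "covariates.tsv"))
  }

  if ("modules" %in% cfg$stages) {
    .require_artifacts(cfg, "modules", c("expression_fpkm.tsv", "traits.tsv"),
                       "simulate")
    expr <- state$expr %||% read_expression(.artifact(cfg, "expression_fpkm.tsv"))
    traits <- read_traits(.artifact(cfg, "traits.tsv"))
    expr_mod <- filter_genes_for_modules(expr)
    log_msg("modules: mean-FPKM filter kept ", nrow(expr_mod), "/",
            nrow(expr))
    expr_log <- log2(expr_mod + 1)   # damp the FPKM scale's heavy tail
    tom <- tom_similarity(soft_adjacency(expr_log, cfg$beta_modules))
    labels <- detect_modules(tom, cfg$min_module_size)
    labels <- merge_modules(expr_log, labels, cfg$merge_diss)
    me <- module_eigengenes(expr_log, labels)
    stone <- traits$stone_cell[match(colnames(expr), traits$sample_id)]
    sel <- select_trait_modules(me, stone, cfg$module_p)
    assoc <- attr(sel, "association")
    in_sel <- names(labels)[labels %in% sel]
    gts <- gene_trait_significance(expr_log[in_sel, , drop = FALSE], stone,
                                   cfg$gene_trait_p)
    log_msg("modules: ", max(labels), " modules, ", length(sel),
            " trait-associated, ", nrow(gts), " trait-significant genes")
    write.table(data.frame(gene_id = names(labels), module = labels),
                .artifact(cfg, "module_assignment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_expression(me, .artifact(cfg, "module_eigengenes.tsv"))
    write.table(assoc, .artifact(cfg, "module_trait.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(gts, .artifact(cfg, "gene_trait.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$module_labels <- labels
    state$trait_modules <- sel
    state$trait_genes <- gts
    manifest$modules <- .manifest_row(
      cfg, "modules",
      list(beta = cfg$beta_modules, min_module_size = cfg$min_module_size,
           merge_diss = cfg$merge_diss, module_p = cfg$module_p),
      c("module_assignment.tsv", "module_eigengenes.tsv",
        "module_trait.tsv", "gene_trait.tsv"))
  }

  if ("eqtl" %in% cfg$stages) {
    if (is.null(state$geno))
      stop("stage 'eqtl' requires outputs of stage 'preprocess'",
           call. = FALSE)
    .require_artifacts(cfg, "eqtl", c("gene_models.tsv", "chrom_lengths.tsv"),
                       "simulate")
    models <- read_gene_models(.artifact(cfg, "gene_models.tsv"))
    cl <- read.delim(.artifact(cfg, "chrom_lengths.tsv"))
    chrom_lengths <- setNames(cl$length, cl$chrom)
    thr <- bonferroni_threshold(ncol(state$geno$dosage),
                                nrow(state$expr_norm), cfg$alpha)
    assoc <- eqtl_scan(state$geno, state$expr_norm, state$covariates,
                       p_keep = thr)
    log_msg("eqtl: ", nrow(assoc), " significant pairs at p <= ",
            signif(thr, 3))
    pos <- match(assoc$snp_id, state$geno$snp_ids)
    assoc$snp_chrom <- state$geno$snp_chrom[pos]
    assoc$snp_pos <- state$geno$snp_pos[pos]
    leaders <- do.call(rbind, lapply(split(assoc, assoc$gene_id),
                                     collapse_leading_snps,
                                     window = cfg$local_window))
    leaders <- classify_local_distant(leaders, models, cfg$local_window)
    rownames(leaders) <- NULL
    log_msg("eqtl: ", nrow(leaders), " eQTLs (",
            sum(leaders$class == "local"), " local, ",
            sum(leaders$class == "distant"), " distant)")
    hs <- hotspot_detection(leaders[leaders$class == "distant", ],
                            chrom_lengths, cfg$hotspot_window, cfg$n_perm,
                            cfg$perm_p, seed = .substream(cfg$seed, 7L))
    log_msg("eqtl: hotspot cutoff ", hs$cutoff, ", ",
            sum(hs$windows$hotspot), " hotspot window(s)")
    write.table(leaders, .artifact(cfg, "eqtls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(hs$windows, .artifact(cfg, "hotspots.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$eqtls <- leaders
    state$hotspots <- hs
    manifest$eqtl <- .manifest_row(
      cfg, "eqtl",
      list(alpha = cfg$alpha, local_window = cfg$local_window,
           hotspot_window = cfg$hotspot_window, n_perm = cfg$n_perm),
      c("eqtls.tsv", "hotspots.tsv"))
  }

  if ("network" %in% cfg$stages) {
    if (is.null(state$trait_genes))
      stop("stage 'network' requires outputs of stage 'modules'",
           call. = FALSE)
    .require_artifacts(cfg, "network",
                       c("expression_dev.tsv", "truth.txt"), "simulate")
    dev <- read_expression(.artifact(cfg, "expression_dev.tsv"))
    truth <- read_truth(.artifact(cfg, "truth.txt"))
    merged <- merge_expression_panels(state$expr, dev,
                                      prefixes = c("pop", "dev"))
    merged <- log2(merged + 1)
    tf_ids <- intersect(truth$tf_ids, rownames(merged))
    structural <- setdiff(
      intersect(state$trait_genes$gene_id, truth$structural_genes), tf_ids)
    if (length(structural) == 0)
      stop("no trait-significant structural genes to network", call. = FALSE)
    graph <- build_targeted_network(merged, structural, tf_ids,
                                    cfg$beta_network, cfg$tom_min)
    hubs <- hub_detection(graph, cfg$n_perm, cfg$perm_p,
                          seed = .substream(cfg$seed, 8L))
    log_msg("network: ", nrow(graph$edges), " edges over ",
            nrow(graph$nodes), " nodes; hub cutoff ", hubs$cutoff, ", ",
            length(hubs$hubs), " hub(s)")
    write.table(graph$edges, .artifact(cfg, "network_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = names(hubs$degrees),
                           degree = hubs$degrees,
                           hub = names(hubs$degrees) %in% hubs$hubs),
                .artifact(cfg, "network_hubs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$graph <- graph
    state$hubs <- hubs
    manifest$network <- .manifest_row(
      cfg, "network",
      list(beta = cfg$beta_network, tom_min = cfg$tom_min,
           n_perm = cfg$n_perm),
      c("network_edges.tsv", "network_hubs.tsv"))
  }

  if ("regulators" %in% cfg$stages) {
    if (is.null(state$eqtls))
      stop("stage 'regulators' requires outputs of stage 'eqtl'",
           call. = FALSE)
    if (is.null(state$graph))
      stop("stage 'regulators' requires outputs of stage 'network'",
           call. = FALSE)
    models <- read_gene_models(.artifact(cfg, "gene_models.tsv"))
    structural <- state$graph$nodes$gene_id[
      state$graph$nodes$role == "structural"]
    recs <- state$eqtls[state$eqtls$gene_id %in% structural, ]
    cands <- identify_regulators(recs, state$graph, models,
                                 cfg$region_halfwidth)
    prot <- read_proteins(.artifact(cfg, "proteins.faa"))
    motifs <- scan_scw_motifs(prot)
    log_msg("regulators: ", nrow(cands), " candidate(s); top: ",
            if (nrow(cands) > 0) cands$regulator_gene[1] else "none")
    write.table(as.data.frame(cands), .artifact(cfg, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(motifs, .artifact(cfg, "motif_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$candidates <- cands
    state$motifs <- motifs
    manifest$regulators <- .manifest_row(
      cfg, "regulators",
      list(region_halfwidth = cfg$region_halfwidth),
      c("candidates.tsv", "motif_hits.tsv"))
  }

  man <- do.call(rbind, manifest)
  write.table(man, .artifact(cfg, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  state$manifest <- man
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
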