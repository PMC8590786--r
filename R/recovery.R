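#' Run the pipeline on a fresh synthetic dataset and score ground-truth
#' recovery
#'
#' Executes [run_pipeline()] on a simulated panel and compares the results
#' with the planted truth: adjusted Rand index of detected vs planted
#' module labels (unassigned genes form their own class), the fraction of
#' planted cis-eQTL pairs recovered as local leading SNPs within 20 kb,
#' whether the regulator locus's 1-Mb window is flagged as a distant-eQTL
#' hotspot, whether the regulator is the rank-1 candidate and a network
#' hub, and the realised fold-range of the stone-cell trait.
#'
#' @param seed master seed for this run.
#' @param out_dir run directory (default: a temporary directory).
#' @param cfg optional [default_config()]; its seed is overridden.
#' @return a one-row `data.frame` of recovery metrics.
#' @export
recovery_metrics <- function(seed, out_dir = tempfile("coexqtl_acc_"),
                             cfg = NULL) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("recovery_metrics needs the 'mclust' package for the ARI")
  if (is.null(cfg)) cfg <- default_config(out_dir = out_dir, seed = seed)
  cfg$seed <- as.integer(seed)
  cfg$sim$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  st <- suppressMessages(run_pipeline(cfg))
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  truth <- st$sim$truth
  geno <- st$sim$genotypes

  lab <- st$module_labels
  ari <- mclust::adjustedRandIndex(lab, truth$module_of_gene[names(lab)])

  # planted cis pair recovered as a local leader within 20 kb
  cp <- truth$cis_eqtl_pairs
  snp_pos <- geno$snp_pos[match(cp$snp_id, geno$snp_ids)]
  snp_chr <- geno$snp_chrom[match(cp$snp_id, geno$snp_ids)]
  found <- vapply(seq_len(nrow(cp)), function(i) {
    rec <- st$eqtls[st$eqtls$gene_id == cp$gene_id[i], ]
    any(rec$snp_chrom == snp_chr[i] & abs(rec$snp_pos - snp_pos[i]) <= 20000)
  }, logical(1))

  i <- match(truth$regulator_snp, geno$snp_ids)
  w <- st$hotspots$windows
  inbin <- w$chrom == geno$snp_chrom[i] & w$start <= geno$snp_pos[i] &
    w$end >= geno$snp_pos[i]
  hotspot_hit <- any(w$hotspot[inbin])

  rank1 <- nrow(st$candidates) > 0 &&
    st$candidates$regulator_gene[1] == truth$regulator_gene
  hub_hit <- truth$regulator_gene %in% st$hubs$hubs
  deg <- sort(st$hubs$degrees, decreasing = TRUE)
  top3 <- truth$regulator_gene %in% names(deg)[1:3]

  data.frame(seed = seed,
             ari = ari,
             cis_detection_rate = mean(found),
             hotspot_hit = hotspot_hit,
             regulator_rank1 = rank1,
             regulator_hub = hub_hit,
             regulator_top3_degree = top3,
             n_modules = max(lab),
             n_local = sum(st$eqtls$class == "local"),
             n_distant = sum(st$eqtls$class == "distant"),
             n_hotspots = sum(w$hotspot),
             stone_cell_fold = max(st$sim$traits$stone_cell) /
               min(st$sim$traits$stone_cell))
}
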