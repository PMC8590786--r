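#' Bonferroni-corrected genome-wide significance threshold
#'
#' `alpha / (n_snps * n_genes)` for an all-pairs SNP-by-gene scan. Counts
#' are taken as doubles so products up to 1e14 are exact.
#'
#' @param n_snps,n_genes test-grid dimensions (positive).
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test p-value threshold.
#' @export
bonferroni_threshold <- function(n_snps, n_genes, alpha = 0.05) {
  stopifnot(n_snps > 0, n_genes > 0, alpha > 0)
  alpha / (as.numeric(n_snps) * as.numeric(n_genes))
}

#' All-pairs SNP-by-gene linear association scan
#'
#' For each gene, expression and dosages are residualised once on
#' `[intercept, covariates]`; the per-SNP slope test on the residuals is
#' then algebraically identical to the full multiple regression
#' (Frisch-Waugh), with `df = n - 2 - n_covariates`. SNPs are processed in
#' blocks so only pairs with `p <= p_keep` are ever materialised. Missing
#' dosages are mean-imputed per SNP; SNPs monomorphic after imputation and
#' genes with zero residual variance are skipped and counted.
#'
#' @param geno a `genotype_matrix`.
#' @param expr_norm genes x samples matrix of rank-normalised expression.
#' @param covariates samples x q matrix (or `NULL`); must be full column
#'   rank together with the intercept.
#' @param p_keep emit only associations with `p <= p_keep` (default 1).
#' @param block_size SNPs per block (default 2000).
#' @return `data.frame` with `snp_id`, `gene_id`, `beta`, `t_stat`, `p`,
#'   plus attributes `n_skipped_snps` and `skipped_genes`.
#' @export
eqtl_scan <- function(geno, expr_norm, covariates = NULL, p_keep = 1,
                      block_size = 2000L) {
  stopifnot(inherits(geno, "genotype_matrix"), is.matrix(expr_norm))
  n <- nrow(geno$dosage)
  if (ncol(expr_norm) != n)
    stop("expression and genotypes must cover the same samples")
  if (is.null(covariates))
    covariates <- matrix(0, nrow = n, ncol = 0)
  if (nrow(covariates) != n)
    stop("covariates and genotypes must cover the same samples")
  q <- ncol(covariates)
  C <- cbind(`(intercept)` = 1, covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop("rank-deficient covariates: ", paste(bad, collapse = ", "))
  }
  Q <- qr.Q(qrC)
  resid_on_C <- function(M) M - Q %*% crossprod(Q, M)

  Y <- resid_on_C(t(expr_norm))
  yty <- colSums(Y^2)
  gene_ok <- yty > 1e-12
  skipped_genes <- rownames(expr_norm)[!gene_ok]
  Y <- Y[, gene_ok, drop = FALSE]
  yty <- yty[gene_ok]
  genes <- rownames(expr_norm)[gene_ok]
  G <- length(genes)
  df <- n - 2 - q
  if (df < 1) stop("not enough samples for the covariate set")

  m <- ncol(geno$dosage)
  n_skipped_snps <- 0L
  res <- list()
  for (b0 in seq(1L, m, by = block_size)) {
    b1 <- min(b0 + block_size - 1L, m)
    idx <- b0:b1
    X <- apply(geno$dosage[, idx, drop = FALSE], 2, function(g) {
      g <- as.numeric(g)
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      g
    })
    mono <- apply(X, 2, sd) == 0
    n_skipped_snps <- n_skipped_snps + sum(mono)
    X <- resid_on_C(X)
    xtx <- colSums(X^2)
    ok <- !mono & xtx > 1e-12
    if (!any(ok)) next
    X <- X[, ok, drop = FALSE]
    xtx <- xtx[ok]
    snp_idx <- idx[ok]

    num <- crossprod(X, Y)                       # snps x genes
    beta <- num / xtx
    rss <- pmax(outer(rep(1, length(xtx)), yty) - num^2 / xtx, 0)
    tstat <- num / sqrt(rss * xtx / df)
    p <- 2 * pt(-abs(tstat), df = df)
    hit <- which(p <= p_keep, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      res[[length(res) + 1L]] <- data.frame(
        snp_id = geno$snp_ids[snp_idx[hit[, 1]]],
        gene_id = genes[hit[, 2]],
        beta = beta[hit],
        t_stat = tstat[hit],
        p = pmax(p[hit], .Machine$double.xmin))
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(snp_id = character(0), gene_id = character(0),
               beta = numeric(0), t_stat = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped_snps") <- n_skipped_snps
  attr(out, "skipped_genes") <- skipped_genes
  out
}

#' Collapse significant SNPs of one gene to leading SNPs
#'
#' Greedy best-p clumping per chromosome: repeatedly take the remaining
#' SNP with the smallest p (ties broken by smaller coordinate), emit it as
#' a leader, and discard all remaining SNPs within `window` bp of it.
#'
#' @param assocs `data.frame` of significant associations for a single
#'   gene with columns `snp_id`, `snp_chrom`, `snp_pos`, `p` (and
#'   optionally others, carried through).
#' @param window clump half-width in bp (default 20000).
#' @return the subset of `assocs` rows that are leaders, ordered by
#'   chromosome and position.
#' @export
collapse_leading_snps <- function(assocs, window = 20000) {
  stopifnot(all(c("snp_id", "snp_chrom", "snp_pos", "p") %in% names(assocs)))
  if (nrow(assocs) == 0) return(assocs)
  keep <- logical(nrow(assocs))
  for (ch in unique(assocs$snp_chrom)) {
    idx <- which(assocs$snp_chrom == ch)
    remaining <- idx[order(assocs$p[idx], assocs$snp_pos[idx])]
    while (length(remaining) > 0) {
      lead <- remaining[1]
      keep[lead] <- TRUE
      remaining <- remaining[
        abs(assocs$snp_pos[remaining] - assocs$snp_pos[lead]) > window]
    }
  }
  out <- assocs[keep, , drop = FALSE]
  out[order(out$snp_chrom, out$snp_pos), , drop = FALSE]
}

#' Classify eQTL records as local or distant
#'
#' A record is local when the SNP lies within `local_window` bp of the
#' associated gene's interval (boundary inclusive, strand-agnostic),
#' otherwise distant. Also reports the signed distance to the nearest gene
#' boundary (0 inside the gene; `NA` on a different chromosome).
#'
#' @param records `data.frame` with `gene_id`, `snp_chrom`, `snp_pos`.
#' @param gene_models gene-model `data.frame`.
#' @param local_window half-width in bp (default 20000).
#' @return `records` with added `class` and `distance_bp` columns.
#' @export
classify_local_distant <- function(records, gene_models,
                                   local_window = 20000) {
  i <- match(records$gene_id, gene_models$gene_id)
  if (anyNA(i))
    stop("unknown gene id(s): ",
         paste(unique(records$gene_id[is.na(i)]), collapse = ", "))
  same <- records$snp_chrom == gene_models$chrom[i]
  d <- ifelse(records$snp_pos < gene_models$start[i],
              records$snp_pos - gene_models$start[i],
              ifelse(records$snp_pos > gene_models$end[i],
                     records$snp_pos - gene_models$end[i], 0L))
  records$distance_bp <- ifelse(same, d, NA_integer_)
  records$class <- ifelse(same & abs(d) <= local_window, "local", "distant")
  records
}

#' Suggest a local-eQTL window from intergenic distances
#'
#' Returns the `coverage`-quantile of adjacent intergenic gaps, rounded up
#' to the nearest kb — the empirical justification for a 20-kb local
#' window when ~90% of adjacent genes are closer than that.
#'
#' @param gene_models gene-model `data.frame`.
#' @param coverage gap-distribution quantile (default 0.90).
#' @return window size in bp; falls back to 20000 (with a warning) when no
#'   adjacent pair exists.
#' @export
derive_local_window <- function(gene_models, coverage = 0.90) {
  gaps <- unlist(lapply(split(gene_models, gene_models$chrom), function(d) {
    if (nrow(d) < 2) return(numeric(0))
    d <- d[order(d$start), ]
    d$start[-1] - d$end[-nrow(d)]
  }), use.names = FALSE)
  if (length(gaps) == 0) {
    warning("no adjacent gene pairs; returning the default 20-kb window")
    return(20000)
  }
  as.numeric(ceiling(quantile(gaps, coverage, names = FALSE) / 1000) * 1000)
}

#' Permutation-based distant-eQTL hotspot detection
#'
#' Counts distant eQTLs in non-overlapping 1-Mb windows, then builds a
#' null by randomly reassigning all records uniformly across windows
#' `n_perm` times. The cutoff is the smallest count `c` whose pooled null
#' exceedance fraction (windows with count `>= c`) is `<= alpha`; observed
#' windows at or above the cutoff are hotspots.
#'
#' @param records `data.frame` of distant eQTL records with `snp_chrom`,
#'   `snp_pos`.
#' @param chrom_lengths named chromosome lengths in bp, covering all
#'   record positions.
#' @param window_bp window width (default 1e6; chromosome tails shorter).
#' @param n_perm number of permutations (default 1000).
#' @param alpha exceedance level (default 0.01).
#' @param seed RNG seed for the permutations.
#' @return list with `windows` (`data.frame`: chrom, start, end, count,
#'   hotspot) and `cutoff` (`NA` when there are no records).
#' @export
hotspot_detection <- function(records, chrom_lengths, window_bp = 1e6,
                              n_perm = 1000, alpha = 0.01, seed = 1) {
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    start <- seq(1, L, by = window_bp)
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_bp - 1, L))
  }))
  wins$count <- 0L
  if (nrow(records) == 0) {
    wins$hotspot <- FALSE
    return(list(windows = wins, cutoff = NA_real_))
  }
  if (!all(records$snp_chrom %in% names(chrom_lengths)))
    stop("records on chromosomes absent from chrom_lengths")
  bad <- records$snp_pos > chrom_lengths[records$snp_chrom]
  if (any(bad)) stop("record positions beyond chromosome length")

  bin_of <- paste(records$snp_chrom,
                  floor((records$snp_pos - 1) / window_bp), sep = ":")
  win_key <- paste(wins$chrom, floor((wins$start - 1) / window_bp), sep = ":")
  counts <- table(factor(bin_of, levels = win_key))
  wins$count <- as.integer(counts)

  B <- nrow(wins)
  N <- nrow(records)
  null_counts <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_len(n_perm), function(i) {
      tabulate(sample.int(B, N, replace = TRUE), nbins = B)
    }), use.names = FALSE)
  })
  cutoff <- NA_real_
  for (cc in 0:(max(null_counts, wins$count) + 1L)) {
    if (mean(null_counts >= cc) <= alpha) { cutoff <- cc; break }
  }
  wins$hotspot <- wins$count >= cutoff
  list(windows = wins, cutoff = cutoff)
}
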