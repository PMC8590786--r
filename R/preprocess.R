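#' Filter SNPs on minor allele frequency and missingness
#'
#' Keeps SNPs with MAF strictly above `maf_min` and missing fraction
#' strictly below `miss_max`, the standard panel-level genotype filters.
#'
#' @param geno a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum missing fraction (default 0.2).
#' @return the filtered `genotype_matrix`, with attribute `n_removed`.
#' @export
filter_snps <- function(geno, maf_min = 0.05, miss_max = 0.2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  af <- colMeans(geno$dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  miss <- colMeans(is.na(geno$dosage))
  keep <- which(!is.na(maf) & maf > maf_min & miss < miss_max)
  out <- structure(list(dosage = geno$dosage[, keep, drop = FALSE],
                        snp_ids = geno$snp_ids[keep],
                        snp_chrom = geno$snp_chrom[keep],
                        snp_pos = geno$snp_pos[keep],
                        sample_ids = geno$sample_ids,
                        subpop = geno$subpop),
                   class = "genotype_matrix")
  attr(out, "n_removed") <- ncol(geno$dosage) - length(keep)
  out
}

#' Filter genes for module detection (mean FPKM)
#'
#' Removes genes with mean FPKM strictly below the threshold; a gene whose
#' mean equals the threshold is kept. Row order is preserved.
#'
#' @param expr genes x samples FPKM matrix.
#' @param min_mean_fpkm threshold (default 1).
#' @return the filtered matrix (possibly with zero rows, with a warning).
#' @export
filter_genes_for_modules <- function(expr, min_mean_fpkm = 1) {
  stopifnot(is.matrix(expr), nrow(expr) > 0)
  keep <- rowMeans(expr) >= min_mean_fpkm
  if (!any(keep)) warning("no genes pass the mean-FPKM filter")
  expr[keep, , drop = FALSE]
}

#' Filter genes for eQTL mapping (median FPKM)
#'
#' Keeps genes whose median FPKM across samples is strictly greater than
#' `min_median_fpkm` (the expressed-gene definition). Row order preserved.
#'
#' @param expr genes x samples FPKM matrix.
#' @param min_median_fpkm threshold (default 0).
#' @return the filtered matrix.
#' @export
filter_genes_for_eqtl <- function(expr, min_median_fpkm = 0) {
  stopifnot(is.matrix(expr), nrow(expr) > 0)
  med <- apply(expr, 1, median)
  keep <- med > min_median_fpkm
  if (!any(keep)) warning("no genes pass the median-FPKM filter")
  expr[keep, , drop = FALSE]
}

#' Rank-based inverse normal transform
#'
#' Maps a sample vector to normal scores `qnorm((r - a) / (n + 1 - 2a))`
#' with the classic plotting-position offset `a = 3/8` for `n <= 10` and
#' `a = 1/2` otherwise; ties receive average ranks and hence identical
#' scores. A constant input returns an all-zero vector flagged with
#' attribute `degenerate = TRUE`.
#'
#' @param x numeric vector with at least 2 non-missing values.
#' @return the normal-scores vector (same length and names as `x`).
#' @export
rank_normalize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(x))
  n <- sum(ok)
  if (sd(x[ok]) == 0) {
    out[ok] <- 0
    names(out) <- names(x)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  a <- if (n <= 10L) 3 / 8 else 0.5
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - a) / (n + 1 - 2 * a))
  names(out) <- names(x)
  out
}

#' Rank-normalise every gene of an expression matrix
#'
#' @param expr genes x samples matrix.
#' @return matrix of per-gene normal scores; degenerate (constant) genes
#'   become all-zero rows, listed in attribute `degenerate_genes`.
#' @export
normalize_expression <- function(expr) {
  out <- t(apply(expr, 1, rank_normalize))
  dimnames(out) <- dimnames(expr)
  degen <- rownames(expr)[apply(expr, 1, function(x) sd(x, na.rm = TRUE) == 0)]
  attr(out, "degenerate_genes") <- degen
  out
}

#' Latent expression factors (principal-component surrogate)
#'
#' Computes the top-`K` principal components of the samples x genes
#' rank-normalised expression matrix. These stand in for PEER factors as
#' nuisance covariates in the eQTL scan: both estimate the dominant
#' latent structure, and the scan only needs nuisance-variance removal.
#'
#' @param expr_norm genes x samples rank-normalised matrix.
#' @param K number of factors (default 20; `K = 0` yields an empty block).
#' @return samples x K matrix of mean-centred factor scores with attribute
#'   `cum_var_explained` (cumulative fraction of variance).
#' @export
latent_factors <- function(expr_norm, K = 20) {
  n <- ncol(expr_norm)
  if (K >= n) stop("K must be smaller than the number of samples")
  if (K == 0) {
    out <- matrix(0, nrow = n, ncol = 0,
                  dimnames = list(colnames(expr_norm), NULL))
    attr(out, "cum_var_explained") <- numeric(0)
    return(out)
  }
  pc <- prcomp(t(expr_norm), center = TRUE, scale. = FALSE)
  out <- pc$x[, seq_len(K), drop = FALSE]
  out <- scale(out, center = TRUE, scale = FALSE)
  colnames(out) <- paste0("LF", seq_len(K))
  attr(out, "cum_var_explained") <-
    cumsum(pc$sdev^2)[seq_len(K)] / sum(pc$sdev^2)
  out
}

#' Genotype principal components
#'
#' Mean-imputes missing dosages per SNP, centres, and returns the top
#' principal components as population-structure covariates.
#'
#' @param geno a `genotype_matrix` (after MAF/missingness filtering).
#' @param n_pcs number of components (default 5; 0 yields an empty block).
#' @return samples x n_pcs matrix of mean-centred PC scores.
#' @export
genotype_pcs <- function(geno, n_pcs = 5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosage)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of individuals")
  if (n_pcs == 0) {
    return(matrix(0, nrow = n, ncol = 0, dimnames = list(geno$sample_ids, NULL)))
  }
  X <- apply(geno$dosage, 2, function(g) {
    g <- as.numeric(g)
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  X <- scale(X, center = TRUE, scale = FALSE)
  pc <- prcomp(X, center = FALSE)
  out <- pc$x[, seq_len(n_pcs), drop = FALSE]
  out <- scale(out, center = TRUE, scale = FALSE)
  rownames(out) <- geno$sample_ids
  colnames(out) <- paste0("gPC", seq_len(n_pcs))
  out
}

#' Drop latent factors that are themselves under strong genetic control
#'
#' Latent expression factors estimated by PCA (or PEER) can absorb the very
#' trans-regulatory signal a hotspot analysis is looking for: a master
#' regulator that moves a whole module becomes a top expression component.
#' This screen scans each factor against all SNPs (with genotype PCs as
#' covariates) and excludes factors with a Bonferroni-significant QTL from
#' the nuisance-covariate set.
#'
#' @param factors samples x K latent-factor matrix.
#' @param geno a `genotype_matrix` aligned on samples.
#' @param geno_pcs samples x P genotype-PC matrix (may have 0 columns).
#' @param alpha family-wise level for the factor-QTL screen (default 0.05,
#'   Bonferroni-corrected over SNPs x factors).
#' @return the factor matrix without genetically driven columns; attribute
#'   `dropped` lists the excluded column names.
#' @export
drop_genetic_factors <- function(factors, geno, geno_pcs, alpha = 0.05) {
  K <- ncol(factors)
  if (K == 0) {
    attr(factors, "dropped") <- character(0)
    return(factors)
  }
  thr <- alpha / (ncol(geno$dosage) * K)
  scan <- eqtl_scan(geno, t(factors), covariates = geno_pcs, p_keep = thr)
  hit <- unique(scan$gene_id)
  keep <- setdiff(colnames(factors), hit)
  out <- factors[, keep, drop = FALSE]
  attr(out, "dropped") <- setdiff(colnames(factors), keep)
  attr(out, "cum_var_explained") <- attr(factors, "cum_var_explained")
  out
}
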