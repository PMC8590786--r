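#' Soft-thresholded (unsigned) adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` across samples, with unit diagonal.
#' Correlations involving a constant gene are treated as 0.
#'
#' @param expr genes x samples matrix (at least 3 samples).
#' @param beta soft-thresholding power (default 5).
#' @return genes x genes adjacency matrix with entries in `[0, 1]`.
#' @export
soft_adjacency <- function(expr, beta = 5) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  r <- suppressWarnings(cor(t(expr)))
  r[is.na(r)] <- 0
  a <- abs(r)^beta
  diag(a) <- 1
  dimnames(a) <- list(rownames(expr), rownames(expr))
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu` and unit diagonal; the adjacency diagonal is
#' ignored. Shared-neighbour structure damps spurious pairwise similarity.
#'
#' @param adjacency symmetric genes x genes adjacency matrix.
#' @return the TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules by hierarchical clustering of 1 - TOM
#'
#' Average-linkage clustering on TOM dissimilarity with a static cut at
#' `cut_height_frac` of the maximum merge height; clusters smaller than
#' `min_module_size` are labelled 0 (unassigned), remaining modules are
#' relabelled 1, 2, ... in decreasing size order.
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size smallest retained cluster (default 30).
#' @param cut_height_frac static cut as a fraction of the tallest merge
#'   (default 0.99).
#' @return named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height_frac = 0.99) {
  stopifnot(nrow(tom) >= min_module_size)
  d <- as.dist(1 - tom)
  h <- hclust(d, method = "average")
  cl <- cutree(h, h = cut_height_frac * max(h$height))
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  if (length(big) == 0) {
    lab <- setNames(rep(0L, nrow(tom)), rownames(tom))
    warning("no cluster reaches min_module_size; all genes unassigned")
    return(lab)
  }
  if (length(big) == 1 && length(sizes) == 1)
    warning("all genes fall in a single module")
  ord <- big[order(sizes[big], decreasing = TRUE)]
  lab <- integer(nrow(tom))
  for (i in seq_along(ord)) lab[cl == as.integer(ord[i])] <- i
  setNames(lab, rownames(tom))
}

#' Module eigengene
#'
#' First principal component of the standardised genes x samples block,
#' scaled to unit variance and sign-oriented so it correlates positively
#' with the module's mean standardised expression profile. A singular
#' block falls back to the mean profile (flagged via attribute
#' `fallback = TRUE`).
#'
#' @param expr_subset genes x samples block of one module (>= 2 genes).
#' @return numeric eigengene vector across samples.
#' @export
module_eigengene <- function(expr_subset) {
  stopifnot(is.matrix(expr_subset), nrow(expr_subset) >= 2)
  sds <- apply(expr_subset, 1, sd)
  ok <- sds > 0
  if (!any(ok)) {
    out <- colMeans(expr_subset)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  z <- t(scale(t(expr_subset[ok, , drop = FALSE])))
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  mp <- colMeans(z)
  if (cor(e, mp) < 0) e <- -e
  e <- as.numeric(scale(e))
  names(e) <- colnames(expr_subset)
  e
}

#' Compute eigengenes for all modules of a partition
#'
#' @param expr genes x samples matrix covering the partitioned genes.
#' @param labels named module labels from [detect_modules()] (0 skipped).
#' @return modules x samples matrix, rows named `ME<label>`.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  out <- t(vapply(mods, function(m) {
    module_eigengene(expr[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(expr))))
  rownames(out) <- paste0("ME", mods)
  colnames(out) <- colnames(expr)
  out
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules with the smallest eigengene
#' dissimilarity `1 - cor` while it is below `threshold`, recomputing
#' eigengenes after each merge; labels are then re-ordered by size.
#'
#' @param expr genes x samples matrix.
#' @param labels module labels (0 = unassigned, untouched).
#' @param threshold eigengene dissimilarity below which modules merge
#'   (default 0.3).
#' @return named integer vector of merged module labels.
#' @export
merge_modules <- function(expr, labels, threshold = 0.3) {
  lab <- labels
  repeat {
    mods <- sort(unique(lab[lab > 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, lab)
    cc <- cor(t(me))
    diss <- 1 - cc
    diag(diss) <- Inf
    ij <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[ij[1], ij[2]] >= threshold) break
    from <- mods[max(ij)]
    to <- mods[min(ij)]
    lab[lab == from] <- to
  }
  # relabel by size, descending
  mods <- sort(unique(lab[lab > 0]))
  sizes <- vapply(mods, function(m) sum(lab == m), integer(1))
  ord <- mods[order(sizes, decreasing = TRUE)]
  out <- integer(length(lab))
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  setNames(out, names(labels))
}

#' Pearson correlation with Student asymptotic p-value
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with a two-sided p-value on
#' `n - 2` degrees of freedom; the standard correlation test behind
#' module- and gene-trait association heatmaps. Collinear inputs
#' (`|r| = 1`) return the smallest representable p, flagged; constant
#' inputs return `r = 0, p = 1`, flagged.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r`, `p`, `n`, and `degenerate` flag.
#' @export
cor_pvalue_student <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = 0, p = 1, n = n, degenerate = TRUE))
  r <- cor(x, y)
  if (abs(r) >= 1)
    return(list(r = r, p = .Machine$double.xmin, n = n, degenerate = TRUE))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), df = n - 2)
  list(r = r, p = max(p, .Machine$double.xmin), n = n, degenerate = FALSE)
}

#' Select trait-associated modules
#'
#' Modules whose eigengene-trait correlation has `p <= p_max`.
#'
#' @param eigengenes modules x samples matrix (rows `ME<label>`).
#' @param trait numeric trait vector aligned on samples.
#' @param p_max significance cut (default 0.01).
#' @return integer vector of selected module labels, with attribute
#'   `association` (per-module `data.frame` of r, p, n).
#' @export
select_trait_modules <- function(eigengenes, trait, p_max = 0.01) {
  stats <- lapply(seq_len(nrow(eigengenes)), function(i) {
    cor_pvalue_student(eigengenes[i, ], trait)
  })
  assoc <- data.frame(
    module = as.integer(sub("^ME", "", rownames(eigengenes))),
    r = vapply(stats, `[[`, numeric(1), "r"),
    p = vapply(stats, `[[`, numeric(1), "p"),
    n = vapply(stats, `[[`, numeric(1), "n"))
  sel <- assoc$module[assoc$p <= p_max]
  attr(sel, "association") <- assoc
  sel
}

#' Per-gene trait significance
#'
#' Correlates each gene's expression with a trait and keeps genes with
#' `p < p_max` (strict), the gene-level analogue of module-trait
#' association.
#'
#' @param expr_subset genes x samples matrix (may have zero rows).
#' @param trait numeric trait vector.
#' @param p_max significance cut (default 0.05).
#' @return `data.frame` of selected genes with `gene_id`, `r`, `p`, `n`.
#' @export
gene_trait_significance <- function(expr_subset, trait, p_max = 0.05) {
  if (nrow(expr_subset) == 0) {
    return(data.frame(gene_id = character(0), r = numeric(0),
                      p = numeric(0), n = integer(0)))
  }
  stats <- lapply(seq_len(nrow(expr_subset)), function(i) {
    cor_pvalue_student(expr_subset[i, ], trait)
  })
  d <- data.frame(gene_id = rownames(expr_subset),
                  r = vapply(stats, `[[`, numeric(1), "r"),
                  p = vapply(stats, `[[`, numeric(1), "p"),
                  n = vapply(stats, `[[`, numeric(1), "n"))
  d[d$p < p_max, , drop = FALSE]
}
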