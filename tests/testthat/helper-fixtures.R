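# Shared fixtures: a reduced panel for fast unit tests, plus constructors
# for vectors with an exactly known Pearson correlation.

small_cfg <- function(seed = 1L, ...) {
  sim_config(n_individuals = 60L, n_genes = 150L, n_snps = 400L,
             n_modules = 2L, module_sizes = c(30L, 25L),
             n_cis_genes = 10L, n_tf_decoys = 8L, n_structural = 15L,
             frac_low_expressed = 0.08, frac_silent = 0.04,
             seed = seed, ...)
}

small_dataset <- local({
  cache <- new.env()
  function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) cache[[key]] <- simulate_dataset(small_cfg(seed))
    cache[[key]]
  }
})

# two unit-norm vectors with cor(x, y) exactly r (up to float arithmetic)
pair_with_cor <- function(n, r, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    e <- rnorm(n)
    x <- x - mean(x)
    e <- e - mean(e)
    e <- e - x * sum(x * e) / sum(x^2)   # orthogonalise
    x <- x / sd(x)
    e <- e / sd(e)
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  })
}

# planted-block expression: k blocks of given sizes driven by independent
# factors, plus pure-noise genes
block_expression <- function(sizes, n_noise, n_samples, loading = 0.9,
                             noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    total <- sum(sizes) + n_noise
    f <- matrix(rnorm(n_samples * length(sizes)), ncol = length(sizes))
    x <- matrix(rnorm(total * n_samples, sd = noise_sd), nrow = total)
    labels <- integer(total)
    at <- 1L
    for (k in seq_along(sizes)) {
      idx <- at:(at + sizes[k] - 1L)
      x[idx, ] <- x[idx, ] + tcrossprod(rep(loading, sizes[k]), f[, k])
      labels[idx] <- k
      at <- at + sizes[k]
    }
    rownames(x) <- sprintf("b%03d", seq_len(total))
    colnames(x) <- sprintf("s%03d", seq_len(n_samples))
    list(expr = x, labels = setNames(labels, rownames(x)), factors = f)
  })
}

# independent O(n^3) TOM oracle (triple loop, no matrix algebra)
tom_bruteforce <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}
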