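test_that("soft adjacency follows |cor|^beta with unit diagonal", {
  pc <- pair_with_cor(40, 0.5, seed = 2)
  expr <- rbind(a = pc$x, b = pc$y, c = -pc$x)
  colnames(expr) <- paste0("s", 1:40)
  a5 <- soft_adjacency(expr, beta = 5)
  expect_equal(a5["a", "b"], 0.5^5, tolerance = 1e-12)  # 0.03125
  expect_equal(a5["a", "c"], 1, tolerance = 1e-12)      # perfect |cor|
  expect_identical(unname(diag(a5)), rep(1, 3))

  x <- matrix(rnorm(10 * 20), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  a <- soft_adjacency(x, beta = 5)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))

  # constant gene: correlations treated as zero
  x[1, ] <- 3
  a0 <- soft_adjacency(x, beta = 5)
  expect_true(all(a0[1, -1] == 0))
})

test_that("TOM matches closed forms and the brute-force oracle", {
  # 2 nodes: no shared neighbours, TOM reduces to the adjacency
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.4, tolerance = 1e-12)

  # 3 nodes, a12 = a13 = 0.5, a23 = 0: TOM23 = 0.25 / 1.5
  a3 <- matrix(c(1, 0.5, 0.5,
                 0.5, 1, 0,
                 0.5, 0, 1), 3, byrow = TRUE)
  expect_equal(tom_similarity(a3)[2, 3], 0.25 / 1.5, tolerance = 1e-12)

  withr::with_seed(99, {
    for (i in 1:5) {
      r <- matrix(runif(400), 20)
      a <- (r + t(r)) / 2
      diag(a) <- 1
      expect_equal(unname(tom_similarity(a)), tom_bruteforce(a),
                   tolerance = 1e-12)
    }
  })
  expect_error(tom_similarity(matrix(1, 2, 3)), "square")
})

test_that("module detection recovers planted blocks and rejects noise", {
  ari <- vapply(1:5, function(s) {
    bl <- block_expression(c(50, 50, 50), n_noise = 0, n_samples = 100,
                           seed = s)
    tom <- tom_similarity(soft_adjacency(bl$expr, 5))
    lab <- detect_modules(tom, min_module_size = 30)
    mclust::adjustedRandIndex(lab, bl$labels)
  }, numeric(1))
  expect_true(all(ari >= 0.95))

  frac0 <- vapply(1:5, function(s) {
    noise <- block_expression(integer(0), n_noise = 40, n_samples = 100,
                              seed = s + 10)
    tom <- tom_similarity(soft_adjacency(noise$expr, 5))
    lab <- suppressWarnings(detect_modules(tom, min_module_size = 30))
    mean(lab == 0)
  }, numeric(1))
  expect_true(all(frac0 >= 0.9))

  bl <- block_expression(40, n_noise = 10, n_samples = 100, seed = 3)
  tom <- tom_similarity(soft_adjacency(bl$expr, 5))
  lab <- detect_modules(tom, min_module_size = 30)
  expect_true(all(lab[bl$labels == 0] == 0))
  expect_true(all(lab[bl$labels == 1] == 1))
})

test_that("module eigengene summarises and orients correctly", {
  f <- rnorm(50)
  same <- matrix(rep(f, 6), nrow = 6, byrow = TRUE) +
    matrix(rnorm(300, sd = 1e-8), nrow = 6)
  colnames(same) <- paste0("s", 1:50)
  e <- module_eigengene(same)
  expect_gt(abs(cor(e, f)), 0.9999)

  # flipping all genes leaves the orientation contract intact
  e2 <- module_eigengene(-same)
  expect_gt(cor(e2, colMeans(t(scale(t(-same))))), 0)

  # variance explained >= best single standardised gene
  bl <- block_expression(20, 0, 60, seed = 8)
  z <- t(scale(t(bl$expr)))
  e3 <- module_eigengene(bl$expr)
  ve <- function(v) mean(cor(v, t(z))^2)
  expect_gte(ve(e3) + 1e-12, max(vapply(seq_len(nrow(z)),
                                        function(i) ve(z[i, ]), numeric(1))))
})

test_that("eigengene-based merging respects the dissimilarity threshold", {
  mk <- function(rho, seed) {
    withr::with_seed(seed, {
      f1 <- rnorm(80)
      f2 <- rho * f1 + sqrt(1 - rho^2) * rnorm(80)
      x <- rbind(
        tcrossprod(rep(1, 40), f1) + matrix(rnorm(40 * 80, sd = 0.1), 40),
        tcrossprod(rep(1, 40), f2) + matrix(rnorm(40 * 80, sd = 0.1), 40))
      dimnames(x) <- list(paste0("g", 1:80), paste0("s", 1:80))
      list(x = x, lab = setNames(rep(1:2, each = 40), rownames(x)))
    })
  }
  hi <- mk(0.95, 1)   # dissimilarity ~0.05 < 0.3 -> merged
  merged <- merge_modules(hi$x, hi$lab, threshold = 0.3)
  expect_identical(length(unique(merged[merged > 0])), 1L)

  lo <- mk(0.6, 2)    # dissimilarity ~0.4 -> kept apart
  kept <- merge_modules(lo$x, lo$lab, threshold = 0.3)
  expect_identical(length(unique(kept[kept > 0])), 2L)

  # threshold 0 never merges
  none <- merge_modules(hi$x, hi$lab, threshold = 0)
  expect_identical(length(unique(none[none > 0])), 2L)
})

test_that("merging is order-independent for disjoint merge pairs", {
  withr::with_seed(5, {
    f <- matrix(rnorm(100 * 2), ncol = 2)
    mkmod <- function(fv) tcrossprod(rep(1, 20), fv) +
      matrix(rnorm(20 * 100, sd = 0.1), 20)
    x <- rbind(mkmod(f[, 1]), mkmod(f[, 1]), mkmod(f[, 2]), mkmod(f[, 2]))
    dimnames(x) <- list(paste0("g", 1:80), paste0("s", 1:100))
    lab1 <- setNames(rep(1:4, each = 20), rownames(x))
    lab2 <- setNames(rep(c(3L, 1L, 4L, 2L), each = 20), rownames(x))
    m1 <- merge_modules(x, lab1, 0.3)
    m2 <- merge_modules(x, lab2, 0.3)
    expect_equal(mclust::adjustedRandIndex(m1, m2), 1)
    expect_identical(length(unique(m1[m1 > 0])), 2L)
  })
})

test_that("correlation p-values agree with the Student-t closed form", {
  n <- 206
  pc <- pair_with_cor(n, 0.3, seed = 3)
  out <- cor_pvalue_student(pc$x, pc$y)
  expect_equal(out$r, 0.3, tolerance = 1e-10)
  t <- 0.3 * sqrt(n - 2) / sqrt(1 - 0.09)
  expect_equal(out$p, 2 * (1 - pt(t, n - 2)), tolerance = 1e-10)

  orth <- pair_with_cor(50, 0, seed = 4)
  expect_equal(cor_pvalue_student(orth$x, orth$y)$p, 1, tolerance = 1e-10)

  col <- cor_pvalue_student(1:30, 2 * (1:30) + 5)
  expect_lte(col$p, 1e-300)
  expect_true(col$degenerate)
  expect_identical(cor_pvalue_student(rep(1, 10), rnorm(10))$p, 1)
})

test_that("trait-module selection keeps true and rejects null modules", {
  bl <- block_expression(c(40, 40), 0, 120, seed = 6)
  lab <- bl$labels
  me <- module_eigengenes(bl$expr, lab)
  trait <- me[1, ] + rnorm(120, sd = 0.3)
  sel <- select_trait_modules(me, trait, p_max = 0.01)
  expect_true(1L %in% sel)
  expect_length(select_trait_modules(me, trait, p_max = 0), 0)

  # Monte-Carlo false-selection rate under independent traits
  withr::with_seed(11, {
    hits <- vapply(1:200, function(i) {
      length(select_trait_modules(me, rnorm(120), p_max = 0.01))
    }, numeric(1))
  })
  expect_lte(mean(hits) / nrow(me), 0.025)
})

test_that("gene-trait significance calibrates near its nominal level", {
  withr::with_seed(21, {
    expr <- matrix(rnorm(1000 * 100), nrow = 1000,
                   dimnames = list(paste0("g", 1:1000), paste0("s", 1:100)))
    trait <- rnorm(100)
    frac <- nrow(gene_trait_significance(expr, trait, 0.05)) / 1000
  })
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)

  # genes of the trait-driving module are enriched
  bl <- block_expression(60, 100, 120, seed = 9)
  trait <- bl$factors[, 1] + rnorm(120, sd = 0.5)
  sel <- gene_trait_significance(bl$expr, trait, 0.05)
  in_mod <- mean(names(bl$labels)[bl$labels == 1] %in% sel$gene_id)
  in_noise <- mean(names(bl$labels)[bl$labels == 0] %in% sel$gene_id)
  expect_gt(in_mod, in_noise)
  expect_gt(in_mod, 0.9)

  empty <- gene_trait_significance(bl$expr[0, , drop = FALSE], trait)
  expect_identical(nrow(empty), 0L)
})
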