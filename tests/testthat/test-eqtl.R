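mk_geno <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  structure(list(
    dosage = dosage,
    snp_ids = colnames(dosage) %||% sprintf("s%03d", seq_len(m)),
    snp_chrom = chrom %||% rep("chr1", m),
    snp_pos = pos %||% as.integer(seq_len(m) * 1000),
    sample_ids = rownames(dosage) %||% sprintf("i%03d", seq_len(nrow(dosage))),
    subpop = NULL), class = "genotype_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Bonferroni threshold is alpha over the test-grid size", {
  expect_identical(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(100, 10, 0.05), 5e-5, tolerance = 1e-15)
  expect_equal(bonferroni_threshold(1e7, 1e7, 0.05), 5e-16)
})

test_that("scan matches the closed-form OLS oracle", {
  withr::with_seed(31, {
    n <- 50
    x <- rbinom(n, 2, 0.4)
    y <- 0.4 * x + rnorm(n)
    covs <- cbind(c1 = rnorm(n), c2 = runif(n))
    geno <- mk_geno(matrix(x, ncol = 1))
    expr <- matrix(y, nrow = 1, dimnames = list("gene1", NULL))

    # no covariates: textbook simple regression
    res <- eqtl_scan(geno, expr)
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(res$beta, fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(res$t_stat, fit["x", "t value"], tolerance = 1e-10)
    expect_equal(res$p, fit["x", "Pr(>|t|)"], tolerance = 1e-10)

    # with covariates: residualised slope equals the full multiple fit
    res2 <- eqtl_scan(geno, expr, covariates = covs)
    fit2 <- summary(lm(y ~ x + covs))$coefficients
    expect_equal(res2$beta, fit2["x", "Estimate"], tolerance = 1e-10)
    expect_equal(res2$t_stat, fit2["x", "t value"], tolerance = 1e-10)
    expect_equal(res2$p, fit2["x", "Pr(>|t|)"], tolerance = 1e-10)
  })
})

test_that("orthogonal genotype gives zero slope and p = 1", {
  y <- rnorm(40)
  y <- y - mean(y)
  x <- rnorm(40)
  x <- x - mean(x)
  x <- x - y * sum(x * y) / sum(y^2)
  geno <- mk_geno(matrix(x, ncol = 1))
  res <- eqtl_scan(geno, matrix(y, nrow = 1,
                                dimnames = list("g", NULL)))
  expect_equal(res$beta, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-10)
})

test_that("scan rejects rank-deficient covariates and skips degenerates", {
  withr::with_seed(32, {
    n <- 30
    geno <- mk_geno(cbind(a = rbinom(n, 2, 0.5), mono = rep(1L, n)))
    expr <- matrix(rnorm(2 * n), nrow = 2,
                   dimnames = list(c("g1", "gconst"), NULL))
    expr["gconst", ] <- 5
    en <- normalize_expression(expr)
    covs <- cbind(u = rnorm(n), v = 0)
    expect_error(eqtl_scan(geno, en, covariates = covs), "v")
    res <- eqtl_scan(geno, en)
    expect_identical(attr(res, "n_skipped_snps"), 1L)
    expect_identical(attr(res, "skipped_genes"), "gconst")
    expect_false("mono" %in% res$snp_id)
  })
})

test_that("null scan p-values are uniform", {
  withr::with_seed(33, {
    n <- 100
    geno <- mk_geno(matrix(rbinom(n * 1000, 2, 0.3), nrow = n))
    expr <- matrix(rnorm(100 * n), nrow = 100,
                   dimnames = list(paste0("g", 1:100), NULL))
    res <- eqtl_scan(geno, normalize_expression(expr), p_keep = 1)
  })
  expect_identical(nrow(res), 100L * 1000L)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("leading-SNP collapse follows the greedy best-p rule", {
  a <- data.frame(snp_id = c("s1", "s2", "s3"),
                  snp_chrom = "chr1",
                  snp_pos = c(1000, 5000, 30000),
                  p = c(1e-20, 1e-15, 1e-18),
                  gene_id = "g")
  out <- collapse_leading_snps(a, window = 20000)
  expect_identical(out$snp_id, c("s1", "s3"))

  one <- collapse_leading_snps(a[2, ], window = 20000)
  expect_identical(one$snp_id, "s2")

  tie <- data.frame(snp_id = c("hi", "lo"), snp_chrom = "chr1",
                    snp_pos = c(4000, 2000), p = c(1e-9, 1e-9),
                    gene_id = "g")
  expect_identical(collapse_leading_snps(tie, 20000)$snp_id, "lo")
})

test_that("collapse satisfies the exhaustive leader-coverage oracle", {
  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(2:60, 1)
      a <- data.frame(
        snp_id = sprintf("s%02d", 1:n),
        snp_chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        snp_pos = sample.int(3e5, n),
        p = 10^runif(n, -30, -8),
        gene_id = "g")
      out <- collapse_leading_snps(a, window = 20000)
      lead <- a$snp_id %in% out$snp_id
      # no two leaders within 20 kb on the same chromosome
      for (ch in unique(out$snp_chrom)) {
        pos <- sort(out$snp_pos[out$snp_chrom == ch])
        if (length(pos) > 1) expect_true(all(diff(pos) > 20000))
      }
      # every discarded SNP is within 20 kb of a better-or-equal leader
      for (j in which(!lead)) {
        cover <- out$snp_chrom == a$snp_chrom[j] &
          abs(out$snp_pos - a$snp_pos[j]) <= 20000 &
          out$p <= a$p[j]
        expect_true(any(cover))
      }
    }
  })
})

test_that("local/distant classification uses an inclusive 20-kb window", {
  models <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                       start = c(50000L, 1000L), end = c(60000L, 2000L),
                       strand = "+")
  rec <- data.frame(gene_id = rep("g1", 4),
                    snp_chrom = c("chr1", "chr1", "chr1", "chr2"),
                    snp_pos = c(55000L, 80000L, 80001L, 55000L))
  out <- classify_local_distant(rec, models, 20000)
  expect_identical(out$class, c("local", "local", "distant", "distant"))
  expect_identical(out$distance_bp[1:3], c(0L, 20000L, 20001L))
  expect_true(is.na(out$distance_bp[4]))
  expect_error(classify_local_distant(
    data.frame(gene_id = "nope", snp_chrom = "chr1", snp_pos = 1L),
    models), "unknown gene")
})

test_that("eQTL classes partition the record set", {
  d <- small_dataset(1)
  g <- d$genotypes
  withr::with_seed(55, {
    rec <- data.frame(gene_id = sample(d$annotation$gene_id, 200,
                                       replace = TRUE),
                      snp_chrom = sample(g$snp_chrom, 200),
                      snp_pos = sample(g$snp_pos, 200))
  })
  out <- classify_local_distant(rec, d$annotation, 20000)
  expect_identical(sum(out$class == "local") + sum(out$class == "distant"),
                   200L)
})

test_that("intergenic-gap quantile suggests the local window", {
  # uniform 10-kb gaps: gene i spans [i*15000, i*15000 + 4999]
  models <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                       start = as.integer((1:10) * 15000),
                       end = as.integer((1:10) * 15000 + 5000), strand = "+")
  expect_identical(derive_local_window(models, 0.9), 10000)
  expect_identical(derive_local_window(models, 1.0), 10000)

  ann <- simulate_annotation(sim_config(seed = 1))
  w <- derive_local_window(ann, 0.9)
  expect_gte(w, 10000)
  expect_lte(w, 30000)

  single <- models[1, ]
  expect_warning(w1 <- derive_local_window(single), "default")
  expect_identical(w1, 20000)
})

test_that("hotspot detection flags concentrated bins and stays calibrated", {
  cl <- c(chr1 = 5e6, chr2 = 5e6)
  rec1 <- data.frame(snp_chrom = rep("chr1", 80),
                     snp_pos = as.integer(runif(80, 2e6, 2.9e6)))
  hs <- hotspot_detection(rec1, cl, n_perm = 500, seed = 2)
  flagged <- hs$windows[hs$windows$hotspot, ]
  expect_identical(nrow(flagged), 1L)
  expect_identical(flagged$chrom, "chr1")
  expect_identical(flagged$start, 2e6 + 1)

  empty <- hotspot_detection(rec1[0, ], cl)
  expect_false(any(empty$windows$hotspot))
  expect_true(is.na(empty$cutoff))

  # cutoff grows with the number of records
  cuts <- vapply(c(50, 200, 800), function(N) {
    withr::with_seed(3, {
      rec <- data.frame(snp_chrom = sample(names(cl), N, replace = TRUE),
                        snp_pos = as.integer(runif(N, 1, 5e6)))
    })
    hotspot_detection(rec, cl, n_perm = 300, seed = 4)$cutoff
  }, numeric(1))
  expect_true(all(diff(cuts) >= 0))

  # near-null false-flag rate stays near the nominal level
  rates <- vapply(1:30, function(s) {
    withr::with_seed(100 + s, {
      rec <- data.frame(snp_chrom = sample(names(cl), 40, replace = TRUE),
                        snp_pos = as.integer(runif(40, 1, 5e6)))
    })
    hs <- hotspot_detection(rec, cl, n_perm = 200, seed = 200 + s)
    mean(hs$windows$hotspot)
  }, numeric(1))
  expect_lte(mean(rates), 0.02)
})
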