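test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_individuals = 5), "at least 10")
  expect_error(sim_config(n_snps = 5), "at least 10")
  expect_error(sim_config(missing_rate = 0.25), "missing_rate")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(sim_config(module_sizes = c(100, 100), n_modules = 2,
                          n_genes = 150), "exceeds")
  expect_error(sim_config(module_sizes = c(10, 10)), "length")
})

test_that("genotype simulation honours missingness and MAF constraints", {
  g0 <- simulate_genotypes(small_cfg(seed = 3, missing_rate = 0))
  expect_false(anyNA(g0$dosage))

  g <- small_dataset(1)$genotypes
  expect_true(anyNA(g$dosage))
  af <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  expect_true(all(maf >= 0.05))
  expect_true(all(colMeans(is.na(g$dosage)) < 0.2))
  expect_true(all(g$dosage %in% c(0L, 1L, 2L) | is.na(g$dosage)))
  # positions sorted within chromosome
  for (ch in unique(g$snp_chrom))
    expect_false(is.unsorted(g$snp_pos[g$snp_chrom == ch]))
})

test_that("identical config and seed reproduce identical genotypes", {
  a <- simulate_genotypes(small_cfg(seed = 7))
  b <- simulate_genotypes(small_cfg(seed = 7))
  expect_identical(a, b)
})

test_that("population divergence shows up on genotype PC1", {
  cfg <- sim_config(n_individuals = 200L, n_snps = 800L, n_genes = 100L,
                    module_sizes = c(20L, 15L, 10L),
                    fst_divergence = 0.3, seed = 5)
  g <- simulate_genotypes(cfg)
  pcs <- genotype_pcs(g, 2)
  sil <- cluster::silhouette(g$subpop, dist(pcs[, 1, drop = FALSE]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("gene models are sorted, non-overlapping, with mostly short gaps", {
  ann <- simulate_annotation(sim_config(seed = 1))
  expect_true(all(ann$start <= ann$end))
  gaps <- c()
  for (ch in unique(ann$chrom)) {
    d <- ann[ann$chrom == ch, ]
    expect_false(is.unsorted(d$start))
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    gaps <- c(gaps, d$start[-1] - d$end[-nrow(d)])
  }
  q90 <- quantile(gaps, 0.9, names = FALSE)
  expect_gte(q90, 10000)
  expect_lte(q90, 30000)
})

test_that("a single gene yields a valid degenerate annotation", {
  ann <- simulate_annotation(sim_config(n_genes = 1L, n_chromosomes = 1L,
                                        module_sizes = 1L, n_modules = 1L,
                                        seed = 2))
  expect_equal(nrow(ann), 1L)
})

test_that("expression truth is internally consistent", {
  d <- small_dataset(1)
  tr <- d$truth
  expect_true(all(d$expr >= 0))
  expect_identical(unname(tr$module_of_gene[tr$regulator_gene]), 1L)
  expect_true(all(tr$module_of_gene[tr$regulated_genes] == 1L))
  expect_true(all(tr$structural_genes %in% tr$regulated_genes))
  # regulator SNP within the regulator gene body +/- 20 kb
  ann <- d$annotation
  i <- match(tr$regulator_gene, ann$gene_id)
  j <- match(tr$regulator_snp, d$genotypes$snp_ids)
  expect_identical(d$genotypes$snp_chrom[j], ann$chrom[i])
  expect_gte(d$genotypes$snp_pos[j], ann$start[i] - 20000)
  expect_lte(d$genotypes$snp_pos[j], ann$end[i] + 20000)
  # every cis pair's SNP within 20 kb of its gene
  cp <- tr$cis_eqtl_pairs
  gi <- match(cp$gene_id, ann$gene_id)
  si <- match(cp$snp_id, d$genotypes$snp_ids)
  expect_true(all(d$genotypes$snp_chrom[si] == ann$chrom[gi]))
  expect_true(all(d$genotypes$snp_pos[si] >= ann$start[gi] - 20000 &
                    d$genotypes$snp_pos[si] <= ann$end[gi] + 20000))
})

test_that("disabling the trans effect removes the regulator association", {
  d <- simulate_dataset(small_cfg(seed = 4, trans_effect_sd = 0))
  z <- d$genotypes$dosage[, match(d$truth$regulator_snp,
                                  d$genotypes$snp_ids)]
  z[is.na(z)] <- mean(z, na.rm = TRUE)
  f <- d$truth$factors[, 1]
  # partial correlation given the module factor, averaged over targets
  pr <- vapply(d$truth$regulated_genes, function(g) {
    y <- log2(d$expr[g, ] + 1)
    cor(resid(lm(y ~ f)), resid(lm(z ~ f)))
  }, numeric(1))
  expect_lt(abs(mean(pr)), 0.1)
})

test_that("regulator expression correlates with its targets", {
  rs <- vapply(1:3, function(s) {
    d <- simulate_dataset(small_cfg(seed = s))
    reg <- d$expr[d$truth$regulator_gene, ]
    mean(vapply(d$truth$regulated_genes,
                function(g) cor(reg, d$expr[g, ]), numeric(1)))
  }, numeric(1))
  expect_gt(mean(rs), 0.2)
})

test_that("traits are positive, positively correlated, ~7-fold in range", {
  d <- small_dataset(1)
  tw <- d$traits
  expect_gte(min(tw$stone_cell), 0)
  cc <- cor(tw[, c("stone_cell", "lignin", "cellulose")])
  expect_true(all(cc > 0))
  ratio <- max(tw$stone_cell) / min(tw$stone_cell)
  expect_gte(ratio, 5)
  expect_lte(ratio, 9)

  d0 <- simulate_trait(d$expr, d$truth, small_cfg(seed = 1,
                                                  trait_noise_sd = 0))
  cc0 <- cor(d0[, c("stone_cell", "lignin", "cellulose")])
  expect_equal(unname(cc0), matrix(1, 3, 3), tolerance = 1e-12)
})

test_that("protein simulation plants motifs only in the regulator", {
  d <- small_dataset(1)
  prot <- d$proteins
  reg <- d$truth$regulator_gene
  hits <- scan_scw_motifs(prot)
  reg_lp <- hits[hits$seq_id == reg & hits$motif == "LP", ]
  expect_identical(nrow(reg_lp), 1L)
  expect_identical(reg_lp$offset, attr(prot, "lp_offset"))
  expect_identical(
    nrow(hits[hits$seq_id == reg & hits$motif == "WQ", ]), 1L)
  # independent regex scan (PCRE engine) finds nothing elsewhere
  others <- setdiff(names(prot), reg)
  for (p in c("F[ML]QLPQLESP[KS]",
              "DQ[VL]TDWRALD[KR][LF][VL]AS[QH]L[SN]Q[DE]D")) {
    expect_false(any(grepl(p, prot[others], perl = TRUE)))
  }
  expect_length(simulate_proteins(character(0)), 0)
})
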