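#' Simulation configuration for the synthetic systems-genetics panel
#'
#' Builds a validated configuration describing a population expression panel
#' with planted genetic and co-expression structure: two diverged
#' subpopulations genotyped at biallelic SNPs, genes laid out with mostly
#' short intergenic gaps, expression driven by a handful of module latent
#' factors plus planted cis effects and one trans master regulator, and a
#' quantitative trait (stone-cell content) driven by the regulated module.
#'
#' @param n_individuals number of individuals in the panel (default 206).
#' @param n_subpops number of subpopulations (default 2).
#' @param fst_divergence Balding-Nichols divergence between subpopulation
#'   allele frequencies, in `[0, 1)` (default 0.1).
#' @param n_chromosomes number of chromosomes (default 3).
#' @param n_genes number of gene models (default 1000).
#' @param n_snps number of biallelic SNPs (default 5000).
#' @param maf_range admissible minor-allele-frequency range (default
#'   `c(0.05, 0.5)`), enforced on the realised sample frequencies.
#' @param missing_rate per-genotype missingness rate, `< 0.2` (default 0.05).
#' @param n_modules number of planted co-expression modules (default 3).
#' @param module_sizes gene counts per module (default `c(150, 100, 80)`).
#' @param cis_effect_sd planted cis-eQTL effect, in residual-SD units per
#'   standardised dosage (default 1).
#' @param trans_effect_sd planted trans effect of the regulator locus on the
#'   regulated module's genes (default 1).
#' @param noise_sd gene-level residual SD on the latent log2 scale
#'   (default 0.7); see the methods vignette for the rationale.
#' @param trait_noise_sd trait residual SD in latent-factor units
#'   (default 0.3).
#' @param n_cis_genes number of background genes given a planted cis-eQTL
#'   (default 50).
#' @param n_tf_decoys number of background genes labelled as transcription
#'   factors alongside the planted regulator (default 30).
#' @param n_structural number of module-1 genes designated as pathway
#'   ("structural") genes for the targeted network (default 45).
#' @param frac_low_expressed fraction of background genes with mean FPKM
#'   below 1, exercising the module-stage filter (default 0.10).
#' @param frac_silent fraction of background genes zeroed in most samples,
#'   exercising the expressed-gene filter (default 0.03).
#' @param seed integer seed; all `simulate_*` functions derive deterministic
#'   substreams from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 206L, n_subpops = 2L,
                       fst_divergence = 0.1, n_chromosomes = 3L,
                       n_genes = 1000L, n_snps = 5000L,
                       maf_range = c(0.05, 0.5), missing_rate = 0.05,
                       n_modules = 3L, module_sizes = c(150L, 100L, 80L),
                       cis_effect_sd = 1.0, trans_effect_sd = 1.0,
                       noise_sd = 0.7, trait_noise_sd = 0.3,
                       n_cis_genes = 50L, n_tf_decoys = 30L,
                       n_structural = 45L,
                       frac_low_expressed = 0.10, frac_silent = 0.03,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_subpops = as.integer(n_subpops),
    fst_divergence = fst_divergence,
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    missing_rate = missing_rate,
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    cis_effect_sd = cis_effect_sd,
    trans_effect_sd = trans_effect_sd,
    noise_sd = noise_sd,
    trait_noise_sd = trait_noise_sd,
    n_cis_genes = as.integer(n_cis_genes),
    n_tf_decoys = as.integer(n_tf_decoys),
    n_structural = as.integer(n_structural),
    frac_low_expressed = frac_low_expressed,
    frac_silent = frac_silent,
    seed = as.integer(seed)
  )
  counts <- c("n_individuals", "n_subpops", "n_chromosomes", "n_genes",
              "n_snps", "n_modules")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("'", f, "' must be a single positive count", call. = FALSE)
  }
  if (cfg$n_individuals < 10L || cfg$n_snps < 10L)
    stop("need at least 10 individuals and 10 SNPs for downstream ",
         "covariance estimation", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.2)
    stop("'missing_rate' must be in [0, 0.2)", call. = FALSE)
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] >= cfg$maf_range[2])
    stop("'maf_range' must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  if (cfg$fst_divergence < 0 || cfg$fst_divergence >= 1)
    stop("'fst_divergence' must be in [0, 1)", call. = FALSE)
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("'module_sizes' must have length 'n_modules'", call. = FALSE)
  if (any(cfg$module_sizes <= 0L))
    stop("'module_sizes' must be positive", call. = FALSE)
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("'module_sizes' sum exceeds 'n_genes'", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate gene models with mostly short intergenic gaps
#'
#' Lays genes end to end on each chromosome with non-overlapping 1-based
#' inclusive intervals. Adjacent intergenic distances are drawn from a
#' mixture (90% short, capped below 20 kb; 10% long) so the empirical 90th
#' percentile of gaps sits near 20 kb, matching the genome organisation the
#' local/distant eQTL window is derived from.
#'
#' @param cfg a [sim_config()].
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, sorted by chromosome and start, with attribute
#'   `chrom_lengths` (named vector of chromosome lengths in bp).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(.substream(cfg$seed, 1L), {
    per_chrom <- diff(round(seq(0, cfg$n_genes,
                                length.out = cfg$n_chromosomes + 1L)))
    out <- vector("list", cfg$n_chromosomes)
    lens <- numeric(cfg$n_chromosomes)
    gid <- 0L
    for (ch in seq_len(cfg$n_chromosomes)) {
      n <- per_chrom[ch]
      if (n == 0L) {
        lens[ch] <- 1e6
        out[[ch]] <- data.frame(gene_id = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0))
        next
      }
      glen <- round(runif(n, 1000, 5000))
      short <- runif(n) < 0.9
      gap <- ifelse(short,
                    pmin(200 + round(rexp(n, rate = 1 / 6000)), 19500),
                    20000 + round(rexp(n, rate = 1 / 30000)))
      start <- cumsum(gap) + cumsum(c(0, glen[-n])) + 1
      end <- start + glen - 1
      ids <- sprintf("g%05d", gid + seq_len(n))
      gid <- gid + n
      out[[ch]] <- data.frame(gene_id = ids,
                              chrom = paste0("chr", ch),
                              start = as.integer(start),
                              end = as.integer(end),
                              strand = sample(c("+", "-"), n, replace = TRUE))
      lens[ch] <- end[n] + 6000
    }
    ann <- do.call(rbind, out)
    rownames(ann) <- NULL
    attr(ann, "chrom_lengths") <-
      setNames(lens, paste0("chr", seq_len(cfg$n_chromosomes)))
    ann
  })
}

#' Simulate biallelic genotypes for a structured panel
#'
#' Draws a Balding-Nichols two-level allele-frequency model: an ancestral
#' frequency per SNP, subpopulation frequencies with between-population
#' variance set by `fst_divergence`, and binomial dosages per individual.
#' SNPs whose realised minor-allele frequency falls outside `maf_range`
#' (or whose missingness reaches 20%) are redrawn so the panel satisfies
#' the downstream SNP filters by construction.
#'
#' @param cfg a [sim_config()].
#' @param chrom_lengths optional named chromosome lengths (bp); defaults to
#'   the lengths implied by [simulate_annotation()] under the same seed.
#' @return a list of class `genotype_matrix` with elements `dosage`
#'   (individuals x SNPs, values 0/1/2 and `NA` for missing), `snp_ids`,
#'   `snp_chrom`, `snp_pos`, `sample_ids`, `subpop`.
#' @export
simulate_genotypes <- function(cfg, chrom_lengths = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(chrom_lengths))
    chrom_lengths <- attr(simulate_annotation(cfg), "chrom_lengths")
  withr::with_seed(.substream(cfg$seed, 2L), {
    n <- cfg$n_individuals
    m <- cfg$n_snps
    subpop <- rep(seq_len(cfg$n_subpops), length.out = n)
    subpop <- sort(subpop)
    f <- cfg$fst_divergence

    draw_snp <- function() {
      for (attempt in seq_len(200L)) {
        p_anc <- runif(1, max(cfg$maf_range[1] + 0.05, 0.1), cfg$maf_range[2])
        pk <- if (f > 0) {
          rbeta(cfg$n_subpops, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
        } else rep(p_anc, cfg$n_subpops)
        g <- rbinom(n, 2L, pk[subpop])
        if (cfg$missing_rate > 0) {
          miss <- runif(n) < cfg$missing_rate
          if (mean(miss) >= 0.2) next
          g[miss] <- NA_integer_
        }
        af <- mean(g, na.rm = TRUE) / 2
        maf <- min(af, 1 - af)
        if (maf >= cfg$maf_range[1] && maf <= cfg$maf_range[2]) return(g)
      }
      stop("failed to draw a SNP within the requested MAF range",
           call. = FALSE)
    }
    dosage <- matrix(NA_integer_, nrow = n, ncol = m)
    for (j in seq_len(m)) dosage[, j] <- draw_snp()

    chroms <- names(chrom_lengths)
    snp_chrom <- sample(chroms, m, replace = TRUE,
                        prob = chrom_lengths / sum(chrom_lengths))
    snp_pos <- integer(m)
    for (ch in chroms) {
      idx <- which(snp_chrom == ch)
      snp_pos[idx] <- sort(sample.int(as.integer(chrom_lengths[[ch]]),
                                      length(idx)))
    }
    ord <- order(match(snp_chrom, chroms), snp_pos)
    dosage <- dosage[, ord, drop = FALSE]
    snp_chrom <- snp_chrom[ord]
    snp_pos <- snp_pos[ord]
    snp_ids <- sprintf("snp%06d", seq_len(m))
    sample_ids <- sprintf("ind%03d", seq_len(n))
    dimnames(dosage) <- list(sample_ids, snp_ids)
    structure(list(dosage = dosage, snp_ids = snp_ids, snp_chrom = snp_chrom,
                   snp_pos = snp_pos, sample_ids = sample_ids,
                   subpop = subpop),
              class = "genotype_matrix")
  })
}

# internal: standardised, mean-imputed dosage vector for one SNP
.std_dosage <- function(g) {
  g <- as.numeric(g)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  s <- sd(g)
  if (s == 0) return(rep(0, length(g)))
  (g - mean(g)) / s
}

# internal: SNP indices within [start - window, end + window] of a gene
.snps_near <- function(geno, chrom, start, end, window = 20000L) {
  which(geno$snp_chrom == chrom &
          geno$snp_pos >= start - window &
          geno$snp_pos <= end + window)
}

#' Simulate expression with planted modules, cis effects and one trans
#' master regulator
#'
#' Gene expression is generated on a latent log2 scale as
#' `loading * module factor + cis dosage effect + trans regulator effect +
#' noise`, then exponentiated to non-negative FPKM-like values. The planted
#' regulator belongs to module 1; its expression is driven by a SNP inside
#' its own body (so the locus is a local eQTL for the regulator and a
#' distant eQTL source for every regulated gene). Module-1 members are
#' chosen away from the regulator's 40-kb neighbourhood so the planted
#' ground truth is identifiable by the candidate-region rule.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param annotation output of [simulate_annotation()].
#' @param cfg the same [sim_config()] that produced both.
#' @return a list with `expr` (genes x samples FPKM matrix) and `truth`
#'   (class `sim_truth`): module assignment, cis pairs, regulator gene/SNP,
#'   regulated genes, trait loadings, TF id list, and the latent module
#'   factors used downstream by [simulate_trait()].
#' @export
simulate_expression <- function(genotypes, annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  if (sum(cfg$module_sizes) > nrow(annotation))
    stop("module sizes exceed the number of genes", call. = FALSE)
  withr::with_seed(.substream(cfg$seed, 3L), {
    n <- cfg$n_individuals
    genes <- annotation$gene_id
    G <- length(genes)

    # regulator: a gene with >= 1 SNP within its body +/- 20 kb
    has_snp <- vapply(seq_len(G), function(i) {
      length(.snps_near(genotypes, annotation$chrom[i], annotation$start[i],
                        annotation$end[i])) > 0
    }, logical(1))
    reg_idx <- sample(which(has_snp), 1L)
    reg_gene <- genes[reg_idx]
    reg_snps <- .snps_near(genotypes, annotation$chrom[reg_idx],
                           annotation$start[reg_idx],
                           annotation$end[reg_idx])
    reg_snp_idx <- reg_snps[sample.int(length(reg_snps), 1L)]
    reg_snp <- genotypes$snp_ids[reg_snp_idx]

    # module assignment; module 1 avoids the regulator's 40-kb neighbourhood
    near_reg <- which(annotation$chrom == annotation$chrom[reg_idx] &
                        annotation$start <= annotation$end[reg_idx] + 40000 &
                        annotation$end >= annotation$start[reg_idx] - 40000)
    module <- setNames(integer(G), genes)
    pool1 <- setdiff(seq_len(G), near_reg)
    m1 <- c(reg_idx, sample(pool1, cfg$module_sizes[1] - 1L))
    module[m1] <- 1L
    taken <- m1
    if (cfg$n_modules > 1L) {
      for (m in 2:cfg$n_modules) {
        mm <- sample(setdiff(seq_len(G), taken), cfg$module_sizes[m])
        module[mm] <- m
        taken <- c(taken, mm)
      }
    }
    background <- setdiff(seq_len(G), taken)

    # planted cis pairs among well-expressed background genes
    bg_has_snp <- background[has_snp[background]]
    n_cis <- min(cfg$n_cis_genes, length(bg_has_snp))
    cis_idx <- sample(bg_has_snp, n_cis)
    cis_snp_idx <- vapply(cis_idx, function(i) {
      cand <- .snps_near(genotypes, annotation$chrom[i], annotation$start[i],
                         annotation$end[i])
      cand[sample.int(length(cand), 1L)]
    }, integer(1))

    # decoy TFs: background genes, neither cis genes nor the regulator
    tf_pool <- setdiff(background, cis_idx)
    tf_idx <- sample(tf_pool, min(cfg$n_tf_decoys, length(tf_pool)))

    # low-expressed / silent background genes exercise the filters
    rest <- setdiff(background, c(cis_idx, tf_idx))
    n_low <- round(cfg$frac_low_expressed * G)
    n_sil <- round(cfg$frac_silent * G)
    low_idx <- if (n_low > 0) sample(rest, min(n_low, length(rest))) else integer(0)
    rest2 <- setdiff(rest, low_idx)
    sil_idx <- if (n_sil > 0) sample(rest2, min(n_sil, length(rest2))) else integer(0)

    factors <- matrix(rnorm(n * cfg$n_modules), nrow = n,
                      dimnames = list(genotypes$sample_ids,
                                      paste0("factor", seq_len(cfg$n_modules))))
    loading <- runif(G, 0.8, 1.0)
    z_reg <- .std_dosage(genotypes$dosage[, reg_snp_idx])

    latent <- matrix(rnorm(G * n, sd = cfg$noise_sd), nrow = G)
    for (m in seq_len(cfg$n_modules)) {
      idx <- which(module == m)
      latent[idx, ] <- latent[idx, ] +
        tcrossprod(loading[idx], factors[, m])
    }
    regulated <- setdiff(which(module == 1L), reg_idx)
    structural <- sample(regulated, min(cfg$n_structural, length(regulated)))
    latent[regulated, ] <- latent[regulated, ] +
      matrix(cfg$trans_effect_sd * z_reg, nrow = length(regulated),
             ncol = n, byrow = TRUE)
    latent[reg_idx, ] <- latent[reg_idx, ] + cfg$cis_effect_sd * z_reg
    for (k in seq_along(cis_idx)) {
      z <- .std_dosage(genotypes$dosage[, cis_snp_idx[k]])
      latent[cis_idx[k], ] <- latent[cis_idx[k], ] + cfg$cis_effect_sd * z
    }

    base_mean <- runif(G, 2, 6)
    base_mean[low_idx] <- runif(length(low_idx), -6, -1)
    base_mean[sil_idx] <- runif(length(sil_idx), -2, 0)
    expr <- 2^(latent + base_mean)
    for (i in sil_idx) {
      z0 <- sample.int(n, ceiling(0.6 * n))
      expr[i, z0] <- 0
    }
    dimnames(expr) <- list(genes, genotypes$sample_ids)

    truth <- structure(list(
      module_of_gene = module,
      cis_eqtl_pairs = data.frame(
        snp_id = genotypes$snp_ids[cis_snp_idx],
        gene_id = genes[cis_idx],
        effect = rep(cfg$cis_effect_sd, n_cis)),
      regulator_gene = reg_gene,
      regulator_snp = reg_snp,
      regulated_genes = genes[regulated],
      structural_genes = genes[sort(structural)],
      trait_loadings = setNames(c(1, rep(0, cfg$n_modules - 1L)),
                                paste0("module", seq_len(cfg$n_modules))),
      tf_ids = c(reg_gene, genes[tf_idx]),
      factors = factors,
      loadings = setNames(loading, genes)
    ), class = "sim_truth")
    list(expr = expr, truth = truth)
  })
}

#' Simulate stone-cell, lignin and cellulose traits from the regulated
#' module's latent factor
#'
#' All three traits are positive affine maps of module 1's latent factor
#' plus independent noise, so they are mutually positively correlated.
#' Stone-cell content is min-max rescaled to span 3.2-22.6 g/100 g (about a
#' 7-fold range); lignin and cellulose get their own plausible ranges.
#'
#' @param expression FPKM matrix from [simulate_expression()] (used for
#'   sample ids only).
#' @param truth the matching `sim_truth`.
#' @param cfg the matching [sim_config()].
#' @return a `data.frame` with columns `sample_id`, `stone_cell`, `lignin`,
#'   `cellulose`.
#' @export
simulate_trait <- function(expression, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  withr::with_seed(.substream(cfg$seed, 4L), {
    signal <- truth$factors[, 1]
    n <- length(signal)
    rescale <- function(x, lo, hi) {
      r <- range(x)
      if (r[1] == r[2]) return(rep((lo + hi) / 2, length(x)))
      lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
    }
    mk <- function(lo, hi) {
      rescale(signal + cfg$trait_noise_sd * rnorm(n), lo, hi)
    }
    data.frame(sample_id = colnames(expression),
               stone_cell = mk(3.2, 22.6),
               lignin = mk(5, 25),
               cellulose = mk(10, 35))
  })
}

#' Simulate a small developmental expression panel
#'
#' Emulates fruit-development time-course samples (default 7 stages in 3
#' cultivars) in which the module programmes swing strongly, as secondary
#' cell wall pathways do across development. Used only to augment the
#' expression panel before building the targeted co-expression network.
#'
#' @param annotation gene models from [simulate_annotation()].
#' @param truth `sim_truth` from [simulate_expression()].
#' @param cfg the matching [sim_config()].
#' @param n_stages,n_cultivars panel layout (defaults 7 and 3).
#' @return genes x samples FPKM matrix with `dev_s<stage>_c<cultivar>`
#'   column names.
#' @export
simulate_dev_panel <- function(annotation, truth, cfg,
                               n_stages = 7L, n_cultivars = 3L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  withr::with_seed(.substream(cfg$seed, 5L), {
    genes <- annotation$gene_id
    G <- length(genes)
    n <- n_stages * n_cultivars
    stage <- rep(seq_len(n_stages), times = n_cultivars)
    traj <- scale(seq_len(n_stages))[, 1]
    amp <- runif(cfg$n_modules, 1.5, 3)
    fac <- vapply(seq_len(cfg$n_modules), function(m) {
      amp[m] * traj[stage] * (-1)^(m + 1) + rnorm(n, sd = 0.3)
    }, numeric(n))
    latent <- matrix(rnorm(G * n, sd = cfg$noise_sd), nrow = G)
    for (m in seq_len(cfg$n_modules)) {
      idx <- which(truth$module_of_gene == m)
      latent[idx, ] <- latent[idx, ] +
        tcrossprod(truth$loadings[idx], fac[, m])
    }
    base_mean <- runif(G, 2, 6)
    expr <- 2^(latent + base_mean)
    dimnames(expr) <- list(genes,
                           sprintf("dev_s%d_c%d", stage,
                                   rep(seq_len(n_cultivars), each = n_stages)))
    expr
  })
}

# motif patterns for secondary-cell-wall NAC activation domains
.LP_BOX <- "F[ML]QLPQLESP[KS]"
.WQ_BOX <- "DQ[VL]TDWRALD[KR][LF][VL]AS[QH]L[SN]Q[DE]D"

# internal: one concrete instance of a bracket pattern
.motif_instance <- function(pattern) {
  toks <- regmatches(pattern,
                     gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  paste(vapply(toks, function(t) {
    if (startsWith(t, "[")) {
      ch <- strsplit(gsub("\\[|\\]", "", t), "")[[1]]
      sample(ch, 1L)
    } else t
  }, character(1)), collapse = "")
}

#' Simulate protein sequences with planted NAC activation-domain motifs
#'
#' Generates random amino-acid sequences for a set of genes; the planted
#' regulator's protein carries exactly one LP-box and one WQ-box instance at
#' recorded offsets, all other proteins carry neither motif (verified by
#' rejection sampling).
#'
#' @param gene_ids character vector of protein/gene ids (may be empty).
#' @param regulator_gene id of the regulator, or `NA` for none.
#' @param cfg a [sim_config()] (seed source).
#' @return named character vector of sequences with attributes `lp_offset`
#'   and `wq_offset` (1-based offsets in the regulator's sequence, `NA` if
#'   no regulator is present).
#' @export
simulate_proteins <- function(gene_ids, regulator_gene = NA_character_,
                              cfg = sim_config()) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(.substream(cfg$seed, 6L), {
    seqs <- character(length(gene_ids))
    names(seqs) <- gene_ids
    lp_off <- NA_integer_
    wq_off <- NA_integer_
    for (i in seq_along(gene_ids)) {
      repeat {
        len <- sample(250:400, 1L)
        s <- paste(sample(aa, len, replace = TRUE), collapse = "")
        if (!grepl(.LP_BOX, s) && !grepl(.WQ_BOX, s)) break
      }
      seqs[i] <- s
    }
    if (!is.na(regulator_gene) && regulator_gene %in% gene_ids) {
      s <- seqs[[regulator_gene]]
      lp <- .motif_instance(.LP_BOX)
      wq <- .motif_instance(.WQ_BOX)
      lp_off <- as.integer(round(nchar(s) * 0.55))
      substr(s, lp_off, lp_off + nchar(lp) - 1L) <- lp
      wq_off <- as.integer(lp_off + nchar(lp) + 10L)
      substr(s, wq_off, wq_off + nchar(wq) - 1L) <- wq
      seqs[[regulator_gene]] <- s
    }
    structure(seqs, lp_offset = lp_off, wq_offset = wq_off)
  })
}

#' Simulate a complete synthetic dataset with recorded ground truth
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_genotypes()], [simulate_expression()], [simulate_trait()],
#' [simulate_dev_panel()] and [simulate_proteins()] under one configuration.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `annotation`, `genotypes`, `expr`, `truth`,
#'   `traits`, `dev_expr`, `proteins`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  geno <- simulate_genotypes(cfg, attr(ann, "chrom_lengths"))
  ex <- simulate_expression(geno, ann, cfg)
  traits <- simulate_trait(ex$expr, ex$truth, cfg)
  dev <- simulate_dev_panel(ann, ex$truth, cfg)
  prot <- simulate_proteins(ex$truth$tf_ids, ex$truth$regulator_gene, cfg)
  list(annotation = ann, genotypes = geno, expr = ex$expr,
       truth = ex$truth, traits = traits, dev_expr = dev,
       proteins = prot, cfg = cfg)
}
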