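#' Write genotypes as VCF 4.2
#'
#' Emits a minimal biallelic-SNP VCF with a GT-only FORMAT; missing dosages
#' become `./.`. REF/ALT are fixed placeholder alleles (A/G) since only the
#' additive dosage is modelled.
#'
#' @param geno a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=coexqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$sample_ids), collapse = "\t")),
             con)
  m <- ncol(geno$dosage)
  body <- character(m)
  for (j in seq_len(m)) {
    g <- geno$dosage[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[as.character(g)])
    body[j] <- paste(c(geno$snp_chrom[j], geno$snp_pos[j], geno$snp_ids[j],
                       "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t")
  }
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a biallelic-SNP VCF via [vcfR::read.vcfR()] and converts GT calls
#' to additive dosages (count of ALT alleles; `NA` for missing).
#'
#' @param path VCF file path.
#' @return a `genotype_matrix` (without subpopulation labels).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alle <- strsplit(x[ok], "[/|]")
    out[ok] <- vapply(alle, function(a) sum(a == "1"), integer(1))
    out
  }
  dos <- apply(gt, 2, count_alt)
  dosage <- t(matrix(as.integer(dos), nrow = nrow(gt),
                     dimnames = dimnames(gt)))
  fix <- vcfR::getFIX(v)
  structure(list(dosage = dosage,
                 snp_ids = unname(fix[, "ID"]),
                 snp_chrom = unname(fix[, "CHROM"]),
                 snp_pos = as.integer(fix[, "POS"]),
                 sample_ids = rownames(dosage),
                 subpop = NULL),
            class = "genotype_matrix")
}

#' Read/write gene models as a 5-column TSV
#'
#' Columns: `chrom`, `start`, `end`, `strand`, `gene_id`; coordinates are
#' 1-based inclusive.
#'
#' @param ann gene-model `data.frame` (see [simulate_annotation()]).
#' @param path file path.
#' @return `write_gene_models()` returns `path` invisibly;
#'   `read_gene_models()` returns the gene-model `data.frame`.
#' @export
write_gene_models <- function(ann, path) {
  write.table(ann[, c("chrom", "start", "end", "strand", "gene_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id") %in%
                  names(d)),
            all(d$start <= d$end), !anyDuplicated(d$gene_id))
  d[, c("gene_id", "chrom", "start", "end", "strand")]
}

#' Read/write an expression matrix as TSV (genes x samples)
#'
#' The header row carries sample ids; the first column carries gene ids.
#'
#' @param expr numeric matrix, genes in rows.
#' @param path file path.
#' @return `write_expression()` returns `path` invisibly;
#'   `read_expression()` returns the numeric matrix.
#' @export
write_expression <- function(expr, path) {
  # 17 significant digits so doubles survive the text round trip exactly
  txt <- format(expr, digits = 17, trim = TRUE, scientific = TRUE)
  d <- data.frame(gene_id = rownames(expr), txt, check.names = FALSE)
  colnames(d) <- c("gene_id", colnames(expr))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Read/write the trait table (samples x traits TSV)
#'
#' @param traits `data.frame` with a `sample_id` column.
#' @param path file path.
#' @return `write_traits()` returns `path` invisibly; `read_traits()` the
#'   `data.frame`.
#' @export
write_traits <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read/write protein sequences as FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] and
#' [Biostrings::writeXStringSet()] keeping sequences as a named character
#' vector on the R side.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param path FASTA file path.
#' @return `write_proteins()` returns `path` invisibly; `read_proteins()`
#'   the named character vector.
#' @export
write_proteins <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_proteins
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' Write/read planted ground truth as a flat key-value text file
#'
#' Scalars are stored as `key=value`, vectors as comma-joined values, and
#' the per-gene module map as `module_of_gene=g1:0,g2:1,...`.
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a
#'   `sim_truth` (without the latent factor matrix, which is not part of
#'   the on-disk contract).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  lines <- c(
    paste0("regulator_gene=", truth$regulator_gene),
    paste0("regulator_snp=", truth$regulator_snp),
    paste0("regulated_genes=", paste(truth$regulated_genes, collapse = ",")),
    paste0("structural_genes=", paste(truth$structural_genes, collapse = ",")),
    paste0("tf_ids=", paste(truth$tf_ids, collapse = ",")),
    paste0("trait_loadings=",
           paste(names(truth$trait_loadings), truth$trait_loadings,
                 sep = ":", collapse = ",")),
    paste0("module_of_gene=",
           paste(names(truth$module_of_gene), truth$module_of_gene,
                 sep = ":", collapse = ",")),
    paste0("cis_pairs=",
           paste(truth$cis_eqtl_pairs$snp_id, truth$cis_eqtl_pairs$gene_id,
                 truth$cis_eqtl_pairs$effect, sep = ":", collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                          character(1)),
                   vapply(kv, `[[`, character(1), 1L))
  split_pairs <- function(s) strsplit(strsplit(s, ",")[[1]], ":")
  mog <- split_pairs(vals[["module_of_gene"]])
  cis <- split_pairs(vals[["cis_pairs"]])
  tl <- split_pairs(vals[["trait_loadings"]])
  structure(list(
    module_of_gene = setNames(
      as.integer(vapply(mog, `[[`, character(1), 2L)),
      vapply(mog, `[[`, character(1), 1L)),
    cis_eqtl_pairs = data.frame(
      snp_id = vapply(cis, `[[`, character(1), 1L),
      gene_id = vapply(cis, `[[`, character(1), 2L),
      effect = as.numeric(vapply(cis, `[[`, character(1), 3L))),
    regulator_gene = unname(vals[["regulator_gene"]]),
    regulator_snp = unname(vals[["regulator_snp"]]),
    regulated_genes = strsplit(vals[["regulated_genes"]], ",")[[1]],
    structural_genes = strsplit(vals[["structural_genes"]], ",")[[1]],
    trait_loadings = setNames(
      as.numeric(vapply(tl, `[[`, character(1), 2L)),
      vapply(tl, `[[`, character(1), 1L)),
    tf_ids = strsplit(vals[["tf_ids"]], ",")[[1]]
  ), class = "sim_truth")
}
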