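#' Construct a genotype matrix
#'
#' Bundles a samples x SNPs matrix of minor-allele counts (0/1/2, `NA` for
#' missing) with per-SNP genomic metadata.  The minor allele is defined
#' cohort-relative: any SNP whose stored counts imply an allele frequency
#' above 0.5 is recoded as `2 - count` so that counts always refer to the
#' less frequent allele.  Per-SNP minor allele frequency (MAF) is recomputed
#' from the counts and stored in the `snps` tibble.
#'
#' @param counts Numeric matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param snps Tibble with one row per SNP: `snp_id`, `chrom`, `pos` (1-based)
#'   and optionally `category` (one of `"exon"`, `"tf"`, `"both"`, `"other"`).
#' @param samples Character vector of sample IDs, one per row of `counts`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts`, `snps` (including recomputed `maf`) and `samples`.
#' @export
genotype_matrix <- function(counts, snps, samples) {
  counts <- as.matrix(counts)
  snps <- tibble::as_tibble(snps)
  samples <- as.character(samples)
  stopifnot(nrow(counts) == length(samples), ncol(counts) == nrow(snps))
  if (anyDuplicated(snps$snp_id) > 0) {
    stop("duplicate snp_id in genotype metadata", call. = FALSE)
  }
  if (anyDuplicated(samples) > 0) {
    stop("duplicate sample IDs in genotype matrix", call. = FALSE)
  }
  bad <- !(counts %in% c(0, 1, 2) | is.na(counts))
  if (any(bad)) {
    stop("genotype counts must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (!"category" %in% names(snps)) snps$category <- "other"
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1 (1-based)", call. = FALSE)
  g <- structure(
    list(counts = counts, snps = snps, samples = samples),
    class = "genotype_matrix"
  )
  recompute_minor_allele(g)
}

# Flip counts so the stored allele is the cohort-minor one, then refresh maf.
recompute_minor_allele <- function(geno) {
  freq <- colMeans(geno$counts, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    geno$counts[, flip] <- 2 - geno$counts[, flip]
    freq[flip] <- 1 - freq[flip]
  }
  geno$snps$maf <- unname(freq)
  colnames(geno$counts) <- geno$snps$snp_id
  rownames(geno$counts) <- geno$samples
  geno
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (MAF %.3f-%.3f)\n",
    length(x$samples), nrow(x$snps),
    suppressWarnings(min(x$snps$maf)), suppressWarnings(max(x$snps$maf))
  ))
  cat("  categories:", paste(sprintf(
    "%s=%d", names(table(x$snps$category)), table(x$snps$category)
  ), collapse = " "), "\n")
  invisible(x)
}

#' Construct an expression matrix
#'
#' Bundles a samples x genes matrix of (already normalized) expression values
#' with per-gene span metadata.  Values must be complete; genes with missing
#' values should be dropped at load time.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param genes Tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive span).
#' @param samples Character vector of sample IDs, one per row of `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, samples) {
  values <- as.matrix(values)
  genes <- tibble::as_tibble(genes)
  samples <- as.character(samples)
  stopifnot(nrow(values) == length(samples), ncol(values) == nrow(genes))
  if (anyDuplicated(genes$gene_id) > 0) {
    stop("duplicate gene_id in expression metadata", call. = FALSE)
  }
  if (anyDuplicated(samples) > 0) {
    stop("duplicate sample IDs in expression matrix", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression values must be complete; drop genes with missing values at load",
         call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    stop("gene spans must satisfy start <= end", call. = FALSE)
  }
  colnames(values) <- genes$gene_id
  rownames(values) <- samples
  structure(
    list(values = values, genes = genes, samples = samples),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d samples x %d genes\n",
    length(x$samples), nrow(x$genes)
  ))
  invisible(x)
}

# Chromosome names compared after stripping any "chr" prefix.
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)
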