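#' Read a BED file of genomic intervals
#'
#' BED input is 0-based half-open; intervals are converted to the package's
#' internal 1-based inclusive convention (the VCF convention, since VCF is the
#' genotype source of truth).
#'
#' @param path Path to a 3+ column BED file (chrom, start, end, optional name).
#' @return Tibble with columns `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` (empty string if absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3) {
    stop("BED file must have >= 3 columns: ", path, call. = FALSE)
  }
  tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,  # 0-based half-open -> 1-based inclusive
    end   = as.integer(raw[[3]]),
    name  = if (ncol(raw) >= 4) as.character(raw[[4]]) else ""
  )
}

# TRUE for each (chrom, pos) lying inside at least one interval of `bed`
# (1-based inclusive).  IRanges does the overlap work per chromosome.
positions_in_intervals <- function(chrom, pos, bed) {
  hit <- logical(length(pos))
  if (is.null(bed) || nrow(bed) == 0) return(hit)
  chrom <- norm_chrom(chrom)
  bed_chrom <- norm_chrom(bed$chrom)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    j <- which(bed_chrom == ch)
    if (length(j) == 0) next
    q <- IRanges::IRanges(start = pos[i], width = 1L)
    s <- IRanges::IRanges(start = bed$start[j], end = bed$end[j])
    hit[i] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Assign annotation categories to SNPs
#'
#' A SNP inside an exon interval and a TF gene span is `"both"`; inside only
#' one kind, `"exon"` or `"tf"`; outside all intervals, `"other"`.  SNPs in
#' the `"other"` category are retained but excluded from source candidacy in
#' association scans.
#'
#' @param snps Tibble with `chrom` and `pos`.
#' @param exon_bed,tf_bed Interval tibbles as returned by [read_bed()], or
#'   `NULL` for none.
#' @return Character vector of categories, one per SNP.
#' @export
snp_categories <- function(snps, exon_bed = NULL, tf_bed = NULL) {
  in_exon <- positions_in_intervals(snps$chrom, snps$pos, exon_bed)
  in_tf <- positions_in_intervals(snps$chrom, snps$pos, tf_bed)
  dplyr::case_when(
    in_exon & in_tf ~ "both",
    in_exon ~ "exon",
    in_tf ~ "tf",
    TRUE ~ "other"
  )
}

is_vcf_file <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) return(TRUE)
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE), error = function(e) "")
  length(first) == 1 && grepl("^##fileformat=VCF", first)
}

read_genotypes_tsv <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = c("NA", ".", "")),
    error = function(e) stop("malformed genotype TSV ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(raw)[1:3])) {
    stop("genotype TSV must start with columns snp_id, chrom, pos: ", path,
         call. = FALSE)
  }
  sample_ids <- names(raw)[-(1:3)]
  counts <- t(as.matrix(raw[, -(1:3), drop = FALSE]))
  mode(counts) <- "numeric"
  bad <- which(!(counts %in% c(0, 1, 2) | is.na(counts)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("genotype TSV %s: non-dosage value at data line %d",
                 path, bad[1, 2]), call. = FALSE)
  }
  list(
    counts = counts,
    snps = tibble::tibble(snp_id = as.character(raw$snp_id),
                          chrom = as.character(raw$chrom),
                          pos = as.integer(raw$pos)),
    samples = sample_ids
  )
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 & alt != "."
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    warning(sprintf("skipping %d non-biallelic VCF record(s)", n_skip),
            call. = FALSE)
  }
  if (!any(biallelic)) stop("no biallelic records in VCF: ", path, call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # Count ALT alleles per genotype call; "./." and malformed calls -> NA.
  g <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  cnt <- rep(NA_real_, length(g))
  ok <- !is.na(g)
  cnt[ok] <- vapply(strsplit(g[ok], "/", fixed = TRUE), function(x) {
    if (length(x) != 2 || any(x == ".")) return(NA_real_)
    sum(x == "1")
  }, numeric(1))
  counts <- t(matrix(cnt, nrow = nrow(gt), dimnames = dimnames(gt)))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  list(
    counts = counts,
    snps = tibble::tibble(snp_id = as.character(ids),
                          chrom = as.character(fix[, "CHROM"]),
                          pos = as.integer(fix[, "POS"])),
    samples = colnames(gt)
  )
}

# Iterate MAF / missingness filters until both hold simultaneously.  Strict
# inequalities throughout: MAF > maf_min, missingness < missing_max.
apply_genotype_filters <- function(geno, maf_min = 0.05,
                                   snp_missing_max = 0.1,
                                   sample_missing_max = 0.1) {
  repeat {
    geno <- recompute_minor_allele(geno)
    snp_miss <- colMeans(is.na(geno$counts))
    keep_snp <- !is.na(geno$snps$maf) & geno$snps$maf > maf_min &
      snp_miss < snp_missing_max
    dropped <- sum(!keep_snp)
    if (dropped > 0) {
      geno$counts <- geno$counts[, keep_snp, drop = FALSE]
      geno$snps <- geno$snps[keep_snp, , drop = FALSE]
    }
    samp_miss <- if (ncol(geno$counts) > 0) rowMeans(is.na(geno$counts)) else
      rep(0, nrow(geno$counts))
    keep_samp <- samp_miss < sample_missing_max
    dropped <- dropped + sum(!keep_samp)
    if (any(!keep_samp)) {
      geno$counts <- geno$counts[keep_samp, , drop = FALSE]
      geno$samples <- geno$samples[keep_samp]
    }
    if (dropped == 0) break
  }
  if (ncol(geno$counts) == 0) {
    stop("no SNPs survive the MAF/missingness filters", call. = FALSE)
  }
  recompute_minor_allele(geno)
}

#' Load a genotype matrix from VCF or dosage TSV
#'
#' Accepts either a VCF (GT field; biallelic SNVs only, multiallelic records
#' skipped with a warning) or a dosage TSV whose first three columns are
#' `snp_id`, `chrom`, `pos` and whose remaining columns are per-sample
#' minor-allele counts.  After loading, the minor allele is redefined
#' cohort-relative, SNPs are annotated with exon/TF categories, and the
#' standard quality filters are applied to a fixed point: MAF > `maf_min`
#' (strict), per-SNP missingness < `snp_missing_max`, per-sample missingness
#' < `sample_missing_max`.
#'
#' @param path VCF or TSV path.
#' @param exon_bed_path,tf_bed_path Optional BED files (0-based half-open) of
#'   exon intervals and TF gene spans (including introns).
#' @param maf_min,snp_missing_max,sample_missing_max Filter thresholds.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, exon_bed_path = NULL, tf_bed_path = NULL,
                           maf_min = 0.05, snp_missing_max = 0.1,
                           sample_missing_max = 0.1) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  parsed <- if (is_vcf_file(path)) read_genotypes_vcf(path) else
    read_genotypes_tsv(path)
  exon_bed <- if (!is.null(exon_bed_path)) read_bed(exon_bed_path) else NULL
  tf_bed <- if (!is.null(tf_bed_path)) read_bed(tf_bed_path) else NULL
  parsed$snps$category <- snp_categories(parsed$snps, exon_bed, tf_bed)
  geno <- genotype_matrix(parsed$counts, parsed$snps, parsed$samples)
  apply_genotype_filters(geno, maf_min = maf_min,
                         snp_missing_max = snp_missing_max,
                         sample_missing_max = sample_missing_max)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of the TSV branch of [read_genotypes()]: columns `snp_id`, `chrom`,
#' `pos`, then one column per sample.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  out <- cbind(
    geno$snps[, c("snp_id", "chrom", "pos")],
    as.data.frame(t(geno$counts), check.names = FALSE)
  )
  names(out)[-(1:3)] <- geno$samples
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an expression matrix from TSV
#'
#' Orientation (genes on rows vs samples on rows) is auto-detected by matching
#' row/column names against the genotype sample IDs when `geno` is supplied;
#' ambiguity (both orientations match, or neither) is an error.  Without
#' `geno`, genes are assumed to be on rows.  Genes without a span in the gene
#' BED are dropped with a message; genes with any missing value are dropped
#' with a message.
#'
#' @param path TSV with gene IDs on one axis and sample IDs on the other.
#' @param gene_bed_path BED file (0-based half-open) of gene spans.
#' @param geno Optional [genotype_matrix()] used for orientation detection.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, gene_bed_path, geno = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  mode(m) <- "numeric"
  if (!is.null(geno)) {
    row_match <- mean(rownames(m) %in% geno$samples)
    col_match <- mean(colnames(m) %in% geno$samples)
    if (row_match > 0 && col_match > 0) {
      stop("expression TSV orientation ambiguous: sample IDs found on both axes",
           call. = FALSE)
    }
    if (row_match == 0 && col_match == 0) {
      stop("no sample IDs shared with the genotype matrix on either axis",
           call. = FALSE)
    }
    genes_on_rows <- col_match > 0
  } else {
    genes_on_rows <- TRUE
  }
  if (genes_on_rows) m <- t(m)  # -> samples x genes
  spans <- read_bed(gene_bed_path)
  gene_ids <- colnames(m)
  has_span <- gene_ids %in% spans$name
  if (any(!has_span)) {
    message(sum(!has_span), " gene(s) without a span in ", gene_bed_path,
            " dropped")
    m <- m[, has_span, drop = FALSE]
    gene_ids <- gene_ids[has_span]
  }
  complete <- colSums(is.na(m)) == 0
  if (any(!complete)) {
    message(sum(!complete), " gene(s) with missing values dropped")
    m <- m[, complete, drop = FALSE]
    gene_ids <- gene_ids[complete]
  }
  if (length(gene_ids) == 0) stop("no genes retained from ", path, call. = FALSE)
  spans <- spans[match(gene_ids, spans$name), ]
  genes <- tibble::tibble(gene_id = gene_ids, chrom = spans$chrom,
                          start = spans$start, end = spans$end)
  expression_matrix(m, genes, rownames(m))
}

#' Restrict genotype and expression matrices to their shared samples
#'
#' Both matrices are subset to the intersection of their sample IDs in one
#' canonical (sorted) order.  The genotype minor allele and MAF are recomputed
#' on the intersected cohort and the quality filters re-applied, so that the
#' filter invariants hold for the samples actually analysed.
#'
#' @param geno A [genotype_matrix()].
#' @param expr An [expression_matrix()].
#' @param min_shared Minimum number of shared samples (conditional regressions
#'   need residual degrees of freedom).
#' @return List with elements `geno` and `expr`.
#' @export
intersect_samples <- function(geno, expr, min_shared = 10) {
  shared <- sort(intersect(geno$samples, expr$samples))
  if (length(shared) < min_shared) {
    stop(sprintf("only %d shared sample(s); need >= %d", length(shared),
                 min_shared), call. = FALSE)
  }
  gi <- match(shared, geno$samples)
  ei <- match(shared, expr$samples)
  geno$counts <- geno$counts[gi, , drop = FALSE]
  geno$samples <- shared
  geno <- apply_genotype_filters(geno)
  expr$values <- expr$values[ei, , drop = FALSE]
  expr$samples <- shared
  list(geno = geno, expr = expr)
}
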