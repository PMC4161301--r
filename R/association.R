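#' Single SNP / single gene additive association test
#'
#' Ordinary least squares of an expression level on the per-sample minor
#' allele count with an intercept (the additive model behind PLINK's
#' quantitative-trait association test).  The p-value is two-sided from the t
#' distribution with `n_used - 2` degrees of freedom; no large-sample normal
#' approximation is used, since cohorts of ~50 samples are the target regime.
#'
#' Samples missing the genotype are dropped pairwise.  A perfect fit (zero
#' residual sum of squares) is reported with the smallest positive normal
#' double as the p-value and flagged `perfect_fit`.  A constant expression
#' vector yields `beta = 0`, `p_value = 1`.  A constant genotype after the
#' missing-drop is a degenerate predictor and an error.
#'
#' @param snp_counts Numeric vector of minor-allele counts in `{0, 1, 2, NA}`.
#' @param expr Numeric expression vector of the same length.
#' @param snp_id,gene_id Optional identifiers carried into the result.
#' @return One-row tibble: `snp_id`, `gene_id`, `n_used`, `beta`, `t_stat`,
#'   `p_value`, `direction` (`"up"` iff `beta > 0`), `perfect_fit`.
#' @export
assoc_test <- function(snp_counts, expr, snp_id = NA_character_,
                       gene_id = NA_character_) {
  stopifnot(length(snp_counts) == length(expr))
  obs <- !is.na(snp_counts) & !is.na(expr)
  x <- as.numeric(snp_counts[obs])
  y <- as.numeric(expr[obs])
  n <- length(x)
  if (n < 4) stop("need >= 4 pairwise-complete samples", call. = FALSE)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate predictor: genotype constant on complete samples",
                     call. = FALSE)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) {
    return(tibble::tibble(snp_id = snp_id, gene_id = gene_id, n_used = n,
                          beta = 0, t_stat = 0, p_value = 1,
                          direction = "down", perfect_fit = FALSE))
  }
  sxy <- sum(xc * yc)
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  perfect <- rss <= .Machine$double.eps * syy * n
  if (perfect) {
    t_stat <- sign(beta) * Inf
    p <- .Machine$double.xmin
  } else {
    se <- sqrt(rss / ((n - 2) * sxx))
    t_stat <- beta / se
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    if (p == 0) p <- .Machine$double.xmin
  }
  tibble::tibble(
    snp_id = snp_id, gene_id = gene_id, n_used = n, beta = beta,
    t_stat = t_stat, p_value = p,
    direction = if (beta > 0) "up" else "down",
    perfect_fit = perfect
  )
}

#' Genome-wide SNP x gene association scan
#'
#' Tests every candidate source SNP (category in `source_categories`; the
#' default restricts sources to SNPs inside exons or TF gene spans) against
#' every gene with the additive model of [assoc_test()], and keeps records
#' with `p_value < p_threshold`.  The scan is vectorized per SNP across all
#' genes.  Degenerate tests (constant genotype on the complete samples) are
#' skipped.
#'
#' @param geno A [genotype_matrix()].
#' @param expr A sample-aligned [expression_matrix()].
#' @param p_threshold Retention threshold on the two-sided p-value (an
#'   "association pair" is a record below this threshold).
#' @param source_categories SNP annotation categories eligible as sources.
#' @return Tibble of association records sorted by `p_value` ascending:
#'   `snp_id`, `gene_id`, `chrom_snp`, `pos_snp`, `chrom_gene`, `n_used`,
#'   `beta`, `t_stat`, `p_value`, `direction`, `cis_trans`.
#' @export
associate_all <- function(geno, expr, p_threshold = 1e-4,
                          source_categories = c("exon", "tf", "both")) {
  stopifnot(identical(geno$samples, expr$samples))
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold <= 1)
  snp_idx <- which(geno$snps$category %in% source_categories)
  E <- expr$values
  n_genes <- ncol(E)
  res <- vector("list", length(snp_idx))
  for (k in seq_along(snp_idx)) {
    j <- snp_idx[k]
    x <- geno$counts[, j]
    obs <- !is.na(x)
    n <- sum(obs)
    if (n < 4) next
    xs <- x[obs]
    xc <- xs - mean(xs)
    sxx <- sum(xc^2)
    if (sxx == 0) next
    Y <- E[obs, , drop = FALSE]
    Yc <- sweep(Y, 2, colMeans(Y))
    sxy <- as.numeric(crossprod(xc, Yc))
    syy <- colSums(Yc^2)
    beta <- sxy / sxx
    rss <- pmax(syy - beta * sxy, 0)
    const_gene <- syy == 0
    perfect <- !const_gene & rss <= .Machine$double.eps * syy * n
    se <- sqrt(rss / ((n - 2) * sxx))
    t_stat <- ifelse(se > 0, beta / se, 0)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    p[perfect] <- .Machine$double.xmin
    p[p == 0] <- .Machine$double.xmin
    beta[const_gene] <- 0
    t_stat[const_gene] <- 0
    p[const_gene] <- 1
    t_stat[perfect] <- sign(beta[perfect]) * Inf
    keep <- which(p < p_threshold)
    if (length(keep) == 0) next
    res[[k]] <- tibble::tibble(
      snp_id = geno$snps$snp_id[j],
      gene_id = expr$genes$gene_id[keep],
      chrom_snp = geno$snps$chrom[j],
      pos_snp = geno$snps$pos[j],
      chrom_gene = expr$genes$chrom[keep],
      n_used = n,
      beta = beta[keep],
      t_stat = t_stat[keep],
      p_value = p[keep],
      direction = ifelse(beta[keep] > 0, "up", "down"),
      perfect_fit = perfect[keep]
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      snp_id = character(), gene_id = character(), chrom_snp = character(),
      pos_snp = integer(), chrom_gene = character(), n_used = integer(),
      beta = numeric(), t_stat = numeric(), p_value = numeric(),
      direction = character(), perfect_fit = logical(), cis_trans = character()
    ))
  }
  # cis: SNP inside the target gene's span on the same chromosome
  gi <- match(out$gene_id, expr$genes$gene_id)
  cis <- norm_chrom(out$chrom_snp) == norm_chrom(expr$genes$chrom[gi]) &
    out$pos_snp >= expr$genes$start[gi] & out$pos_snp <= expr$genes$end[gi]
  out$cis_trans <- ifelse(cis, "cis", "trans")
  dplyr::arrange(out, .data$p_value, .data$snp_id, .data$gene_id)
}
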