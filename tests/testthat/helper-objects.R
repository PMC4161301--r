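# Build small in-memory containers for tests.

make_geno <- function(counts, chrom = NULL, pos = NULL, category = "exon",
                      samples = NULL) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  snps <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(p)),
    chrom = if (is.null(chrom)) rep("1", p) else rep_len(chrom, p),
    pos = if (is.null(pos)) 1000L + seq_len(p) * 100L else as.integer(pos),
    category = rep_len(category, p)
  )
  if (is.null(samples)) samples <- sprintf("ind%03d", seq_len(nrow(counts)))
  genotype_matrix(counts, snps, samples)
}

make_expr <- function(values, chrom = NULL, start = NULL, end = NULL,
                      samples = NULL) {
  values <- as.matrix(values)
  g <- ncol(values)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(g)),
    chrom = if (is.null(chrom)) rep("1", g) else rep_len(chrom, g),
    start = if (is.null(start)) 1000000L + seq_len(g) * 100000L else as.integer(start),
    end = if (is.null(end)) 1000000L + seq_len(g) * 100000L + 9999L else as.integer(end)
  )
  if (is.null(samples)) samples <- sprintf("ind%03d", seq_len(nrow(values)))
  expression_matrix(values, genes, samples)
}

# Independent closed-form oracle for the marginal association t statistic:
# t = r * sqrt(n - 2) / sqrt(1 - r^2) with r the Pearson correlation.
cor_t_oracle <- function(x, y) {
  r <- stats::cor(x, y)
  n <- length(x)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(t = t, p = 2 * stats::pt(-abs(t), n - 2),
       beta = r * stats::sd(y) / stats::sd(x))
}

# Full hypergeometric enumeration oracle for the two-sided Fisher exact test
# on a 2x2 table (row margins r1, r2; first column margin c1; observed a).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force interval containment: is pos inside any [start, end] on the
# same chromosome? (1-based inclusive)
contained_brute <- function(chrom, pos, bed) {
  vapply(seq_along(pos), function(i) {
    any(bed$chrom == chrom[i] & bed$start <= pos[i] & bed$end >= pos[i])
  }, logical(1))
}

write_bed <- function(df, path) {
  # df has 1-based inclusive start/end; BED is 0-based half-open
  utils::write.table(
    data.frame(df$chrom, df$start - 1L, df$end, df$name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  path
}
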