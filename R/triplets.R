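# Two-predictor OLS y ~ 1 + x1 + x2 via residualization; returns coefficient
# tests for both slopes with exact finite-sample df (n - 3).
ols2 <- function(y, x1, x2) {
  obs <- !is.na(y) & !is.na(x1) & !is.na(x2)
  y <- y[obs]; x1 <- x1[obs]; x2 <- x2[obs]
  n <- length(y)
  if (n < 5) stop("need >= 5 pairwise-complete samples", call. = FALSE)
  yc <- y - mean(y); a <- x1 - mean(x1); b <- x2 - mean(x2)
  saa <- sum(a^2); sbb <- sum(b^2)
  if (saa == 0 || sbb == 0) {
    return(list(degenerate = TRUE, reason = "constant predictor"))
  }
  r2_ab <- sum(a * b)^2 / (saa * sbb)
  if (r2_ab >= 1 - 1e-12) {
    return(list(degenerate = TRUE, reason = "collinear predictors"))
  }
  # residualize each predictor on the other
  a_r <- a - sum(a * b) / sbb * b
  b_r <- b - sum(a * b) / saa * a
  beta1 <- sum(a_r * yc) / sum(a_r^2)
  beta2 <- sum(b_r * yc) / sum(b_r^2)
  fitted <- beta1 * a + beta2 * b
  rss <- sum((yc - fitted)^2)
  syy <- sum(yc^2)
  if (syy == 0) {
    return(list(degenerate = TRUE, reason = "constant response"))
  }
  df <- n - 3
  sigma2 <- rss / df
  if (sigma2 <= .Machine$double.eps * syy) {
    # perfect fit: coefficient p-values collapse to the smallest normal double
    p1 <- p2 <- .Machine$double.xmin
    t1 <- sign(beta1) * Inf; t2 <- sign(beta2) * Inf
  } else {
    se1 <- sqrt(sigma2 / sum(a_r^2))
    se2 <- sqrt(sigma2 / sum(b_r^2))
    t1 <- beta1 / se1; t2 <- beta2 / se2
    p1 <- 2 * stats::pt(-abs(t1), df)
    p2 <- 2 * stats::pt(-abs(t2), df)
    p1 <- max(p1, .Machine$double.xmin)
    p2 <- max(p2, .Machine$double.xmin)
  }
  list(degenerate = FALSE, n_used = n,
       beta1 = beta1, t1 = t1, p1 = p1,
       beta2 = beta2, t2 = t2, p2 = p2)
}

#' Conditional association p-value of a SNP given a covariate gene
#'
#' P-value of the SNP coefficient in the joint model
#' `target ~ intercept + snp + covariate`.  This is the conditioning step of
#' triplet classification: a SNP-gene association that survives conditioning
#' on the other gene of the triplet is "nominally significant given" that
#' gene.  The joint-model coefficient test is used (rather than a two-step
#' residual regression) for exact finite-sample degrees of freedom.
#'
#' @param snp_counts Minor-allele counts (`NA` allowed, dropped pairwise).
#' @param target_expr Expression of the gene being tested.
#' @param covariate_expr Expression of the conditioning gene.
#' @return Two-sided p-value of the SNP coefficient.
#' @export
conditional_p <- function(snp_counts, target_expr, covariate_expr) {
  if (isTRUE(all.equal(as.numeric(target_expr), as.numeric(covariate_expr)))) {
    stop("degenerate conditioning: covariate identical to target", call. = FALSE)
  }
  fit <- ols2(target_expr, snp_counts, covariate_expr)
  if (isTRUE(fit$degenerate)) {
    stop("degenerate conditional regression: ", fit$reason, call. = FALSE)
  }
  fit$p1
}

#' Build and classify SNP-gene-gene triplets
#'
#' For every SNP associated with two or more genes, every gene pair forms a
#' candidate triplet.  Each association is re-tested conditioning on the
#' respective other gene; a triplet is *mutually independent* when both
#' conditional SNP coefficients stay below `alpha`, *directionally
#' independent* when exactly one does (the surviving gene is the
#' `directional_target`).  Candidates where neither association survives are
#' excluded from the output.  Gene pairs are canonicalized so
#' `gene1_id < gene2_id`.
#'
#' @param assoc Association tibble from [associate_all()] (already filtered at
#'   the association threshold).
#' @param geno,expr Sample-aligned matrices.
#' @param alpha Nominal significance level for "nominally significant given
#'   the other gene" (two-sided).
#' @return Tibble with columns `snp_id`, `gene1_id`, `gene2_id`, `p1`, `p2`,
#'   `p1_given_g2`, `p2_given_g1`, `kind` (`"mutual"`/`"directional"`),
#'   `directional_target`, `chrom_snp`.
#' @export
build_triplets <- function(assoc, geno, expr, alpha = 0.05) {
  stopifnot(identical(geno$samples, expr$samples))
  empty <- tibble::tibble(
    snp_id = character(), gene1_id = character(), gene2_id = character(),
    p1 = numeric(), p2 = numeric(), p1_given_g2 = numeric(),
    p2_given_g1 = numeric(), kind = character(),
    directional_target = character(), chrom_snp = character()
  )
  if (nrow(assoc) == 0) return(empty)
  by_snp <- split(assoc, assoc$snp_id)
  by_snp <- by_snp[vapply(by_snp, nrow, 1L) >= 2]
  if (length(by_snp) == 0) return(empty)
  E <- expr$values
  rows <- list()
  for (snp in names(by_snp)) {
    recs <- by_snp[[snp]]
    x <- geno$counts[, match(snp, geno$snps$snp_id)]
    genes <- sort(recs$gene_id)
    pr <- utils::combn(genes, 2)
    for (q in seq_len(ncol(pr))) {
      g1 <- pr[1, q]; g2 <- pr[2, q]
      p1 <- recs$p_value[match(g1, recs$gene_id)]
      p2 <- recs$p_value[match(g2, recs$gene_id)]
      f1 <- tryCatch(ols2(E[, g1], x, E[, g2]), error = function(e) NULL)
      f2 <- tryCatch(ols2(E[, g2], x, E[, g1]), error = function(e) NULL)
      if (is.null(f1) || is.null(f2) ||
          isTRUE(f1$degenerate) || isTRUE(f2$degenerate)) {
        message("skipping degenerate triplet candidate (", snp, "; ", g1,
                ", ", g2, ")")
        next
      }
      s1 <- f1$p1 < alpha
      s2 <- f2$p1 < alpha
      if (!s1 && !s2) next  # neither survives conditioning: excluded
      rows[[length(rows) + 1L]] <- tibble::tibble(
        snp_id = snp, gene1_id = g1, gene2_id = g2,
        p1 = p1, p2 = p2, p1_given_g2 = f1$p1, p2_given_g1 = f2$p1,
        kind = if (s1 && s2) "mutual" else "directional",
        directional_target = if (s1 && s2) NA_character_ else if (s1) g1 else g2,
        chrom_snp = geno$snps$chrom[match(snp, geno$snps$snp_id)]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$snp_id, .data$gene1_id, .data$gene2_id)
}

#' Match the real-data triplet count to a permutation null
#'
#' Given per-permutation triplet counts at the base association threshold,
#' returns the p-value cutoff at which the real data retains the same number
#' of top triplets as the rounded permutation mean.  Triplets are ranked by
#' their *worse* marginal p-value (`max(p1, p2)` — the binding constraint
#' defining a triplet), ties broken lexicographically by
#' `(snp_id, gene1_id, gene2_id)`; the cutoff is the worse marginal p of the
#' last retained triplet.  If the real data has fewer triplets than the
#' permutation mean, the base threshold is returned unchanged with a warning.
#'
#' @param triplets Real-data triplet tibble from [build_triplets()].
#' @param perm_counts Integer vector of per-permutation triplet counts.
#' @param base_threshold The association threshold at which both real and
#'   permuted triplets were produced.
#' @return The matched p-value cutoff (a triplet is retained iff
#'   `max(p1, p2) <= cutoff`).
#' @export
match_threshold <- function(triplets, perm_counts, base_threshold = 1e-4) {
  if (length(perm_counts) == 0) stop("perm_counts is empty", call. = FALSE)
  m <- round(mean(perm_counts))
  if (nrow(triplets) < m) {
    warning("real data has fewer triplets (", nrow(triplets),
            ") than the permutation mean (", m,
            "); base threshold returned unchanged", call. = FALSE)
    return(base_threshold)
  }
  if (nrow(triplets) == m || m < 1) return(base_threshold)
  ranked <- triplets |>
    dplyr::mutate(worse_p = pmax(.data$p1, .data$p2)) |>
    dplyr::arrange(.data$worse_p, .data$snp_id, .data$gene1_id, .data$gene2_id)
  ranked$worse_p[m]
}
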