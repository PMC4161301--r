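#' Assemble quartets from triplets sharing a gene pair
#'
#' Two triplets with the same unordered pair of target genes but different
#' source SNPs define a quartet (a candidate bi-fan: two sources, two
#' targets).  SNP order is canonicalized so `snp1_id < snp2_id`; gene order is
#' inherited from the canonical triplet order (`gene1_id < gene2_id`).  With
#' `k` triplets on one gene pair, all `k*(k-1)/2` SNP pairs are emitted.
#'
#' @param triplets Triplet tibble from [build_triplets()].
#' @return Tibble with one row per quartet: SNP/gene identities, the two
#'   triplet kinds and marginal p-values (`p_s1_g1` = marginal p of
#'   `snp1 -> gene1`, etc.), source chromosomes, and `dependency_class`
#'   (`"mutual_mutual"`, `"mixed"` or `"directional_directional"`).
#' @export
assemble_quartets <- function(triplets) {
  empty <- tibble::tibble(
    snp1_id = character(), snp2_id = character(),
    gene1_id = character(), gene2_id = character(),
    triplet1_kind = character(), triplet2_kind = character(),
    p_s1_g1 = numeric(), p_s1_g2 = numeric(),
    p_s2_g1 = numeric(), p_s2_g2 = numeric(),
    chrom_s1 = character(), chrom_s2 = character(),
    dependency_class = character()
  )
  if (nrow(triplets) < 2) return(empty)
  key <- paste(triplets$gene1_id, triplets$gene2_id, sep = "\r")
  rows <- list()
  for (pair_key in unique(key)) {
    grp <- triplets[key == pair_key, ]
    if (nrow(grp) < 2) next
    grp <- dplyr::arrange(grp, .data$snp_id)
    idx <- utils::combn(nrow(grp), 2)
    for (q in seq_len(ncol(idx))) {
      a <- grp[idx[1, q], ]; b <- grp[idx[2, q], ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        snp1_id = a$snp_id, snp2_id = b$snp_id,
        gene1_id = a$gene1_id, gene2_id = a$gene2_id,
        triplet1_kind = a$kind, triplet2_kind = b$kind,
        p_s1_g1 = a$p1, p_s1_g2 = a$p2,
        p_s2_g1 = b$p1, p_s2_g2 = b$p2,
        chrom_s1 = a$chrom_snp, chrom_s2 = b$chrom_snp
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out$dependency_class <- dependency_structure(out$triplet1_kind,
                                               out$triplet2_kind)
  dplyr::arrange(out, .data$gene1_id, .data$gene2_id, .data$snp1_id,
                 .data$snp2_id)
}

#' Dependency structure of a quartet
#'
#' Maps the unordered pair of triplet kinds onto the three dependency
#' classes: two mutually independent associations, one of each, or two
#' directionally dependent associations.
#'
#' @param kind1,kind2 Triplet kinds (`"mutual"` or `"directional"`).
#' @return Character vector: `"mutual_mutual"`, `"mixed"` or
#'   `"directional_directional"`.
#' @export
dependency_structure <- function(kind1, kind2) {
  dplyr::case_when(
    kind1 == "mutual" & kind2 == "mutual" ~ "mutual_mutual",
    kind1 == "directional" & kind2 == "directional" ~ "directional_directional",
    TRUE ~ "mixed"
  )
}

#' Cooperating-sources filter
#'
#' For each quartet, fits the joint additive models
#' `g1 ~ b0 + b1*s1 + b2*s2` and `g2 ~ b0 + b1*s1 + b2*s2`.  The quartet
#' passes when all four slope coefficients (both SNPs in both models) are
#' significantly different from zero at level `alpha` — i.e. each source
#' carries independent information towards predicting each target.  Perfectly
#' collinear sources (LD r² = 1) fail with the `collinear` flag since the
#' coefficients are not identifiable.
#'
#' @param quartets Quartet tibble from [assemble_quartets()].
#' @param geno,expr Sample-aligned matrices.
#' @param alpha Significance level for the coefficient tests.
#' @param keep_all Return all rows (with a `cooperating` column) instead of
#'   only the passing ones.
#' @return The passing quartets, with joint-model coefficient p-value columns
#'   `coop_p_g1_s1`, `coop_p_g1_s2`, `coop_p_g2_s1`, `coop_p_g2_s2`, a
#'   `collinear` flag and `cooperating`.
#' @export
filter_cooperating <- function(quartets, geno, expr, alpha = 0.05,
                               keep_all = FALSE) {
  n <- nrow(quartets)
  p_g1_s1 <- p_g1_s2 <- p_g2_s1 <- p_g2_s2 <- rep(NA_real_, n)
  collinear <- rep(FALSE, n)
  for (i in seq_len(n)) {
    s1 <- geno$counts[, quartets$snp1_id[i]]
    s2 <- geno$counts[, quartets$snp2_id[i]]
    f1 <- tryCatch(ols2(expr$values[, quartets$gene1_id[i]], s1, s2),
                   error = function(e) list(degenerate = TRUE))
    f2 <- tryCatch(ols2(expr$values[, quartets$gene2_id[i]], s1, s2),
                   error = function(e) list(degenerate = TRUE))
    if (isTRUE(f1$degenerate) || isTRUE(f2$degenerate)) {
      collinear[i] <- TRUE
      next
    }
    p_g1_s1[i] <- f1$p1; p_g1_s2[i] <- f1$p2
    p_g2_s1[i] <- f2$p1; p_g2_s2[i] <- f2$p2
  }
  out <- quartets
  out$coop_p_g1_s1 <- p_g1_s1
  out$coop_p_g1_s2 <- p_g1_s2
  out$coop_p_g2_s1 <- p_g2_s1
  out$coop_p_g2_s2 <- p_g2_s2
  out$collinear <- collinear
  out$cooperating <- !collinear &
    p_g1_s1 < alpha & p_g1_s2 < alpha & p_g2_s1 < alpha & p_g2_s2 < alpha
  out$cooperating[is.na(out$cooperating)] <- FALSE
  if (keep_all) out else dplyr::filter(out, .data$cooperating)
}

#' Intermediate-SNP filter
#'
#' Removes quartets for which a third SNP s3 explains the expression of both
#' targets better than one of the sources.  A candidate s3 must (a) share a
#' chromosome with a source SNP (an "intermediate" explanation via linkage
#' requires co-localization), (b) itself form a triplet with the quartet's
#' two genes, and (c) for the co-chromosomal source s_i and *both* genes,
#' pass a conditional-significance exchange test: conditioning the gene on s3
#' renders s_i's coefficient non-significant (p >= alpha) while s3's
#' coefficient conditioned on s_i remains significant (p < alpha).  If any
#' candidate succeeds, the quartet fails.  Candidates collinear with the
#' source are skipped.
#'
#' @param quartets Quartet tibble (normally the cooperating survivors).
#' @param triplets The full triplet tibble used to index candidates by gene
#'   pair.
#' @param geno,expr Sample-aligned matrices.
#' @param alpha Significance level of the exchange test.
#' @param keep_all Return all rows (with `passed_intermediate`) instead of
#'   only the passing ones.
#' @return Quartets that have no better intermediate SNP, with a
#'   `passed_intermediate` column.
#' @export
filter_intermediate <- function(quartets, triplets, geno, expr, alpha = 0.05,
                                keep_all = FALSE) {
  n <- nrow(quartets)
  passed <- rep(TRUE, n)
  if (n > 0 && nrow(triplets) > 0) {
    trip_key <- paste(triplets$gene1_id, triplets$gene2_id, sep = "\r")
    for (i in seq_len(n)) {
      key <- paste(quartets$gene1_id[i], quartets$gene2_id[i], sep = "\r")
      cand <- triplets[trip_key == key, ]
      sources <- c(quartets$snp1_id[i], quartets$snp2_id[i])
      src_chrom <- norm_chrom(c(quartets$chrom_s1[i], quartets$chrom_s2[i]))
      cand <- cand[!(cand$snp_id %in% sources), ]
      if (nrow(cand) == 0) next
      g1 <- expr$values[, quartets$gene1_id[i]]
      g2 <- expr$values[, quartets$gene2_id[i]]
      for (j in seq_len(nrow(cand))) {
        s3_id <- cand$snp_id[j]
        s3_chrom <- norm_chrom(cand$chrom_snp[j])
        co <- which(src_chrom == s3_chrom)
        if (length(co) == 0) next
        s3 <- geno$counts[, s3_id]
        explained <- FALSE
        for (si_idx in co) {
          si <- geno$counts[, sources[si_idx]]
          fa <- tryCatch(ols2(g1, si, s3),
                         error = function(e) list(degenerate = TRUE))
          fb <- tryCatch(ols2(g2, si, s3),
                         error = function(e) list(degenerate = TRUE))
          if (isTRUE(fa$degenerate) || isTRUE(fb$degenerate)) next
          # source explained away on both genes, s3 still significant on both
          if (fa$p1 >= alpha && fb$p1 >= alpha &&
              fa$p2 < alpha && fb$p2 < alpha) {
            explained <- TRUE
            break
          }
        }
        if (explained) {
          passed[i] <- FALSE
          break
        }
      }
    }
  }
  out <- quartets
  out$passed_intermediate <- passed
  if (keep_all) out else dplyr::filter(out, .data$passed_intermediate)
}

#' Unique-gene-targets filter
#'
#' Keeps at most one quartet per unordered gene pair, so that no post-filter
#' quartet shares its pair of gene targets with any other.  The survivor is
#' the quartet minimizing the worst of its four marginal association
#' p-values, with ties broken lexicographically by `(snp1_id, snp2_id)`.
#'
#' @param quartets Quartet tibble (normally the intermediate-filter
#'   survivors).
#' @return The deduplicated quartets.
#' @export
filter_unique_targets <- function(quartets) {
  if (nrow(quartets) == 0) return(quartets)
  quartets |>
    dplyr::mutate(.worst_p = pmax(.data$p_s1_g1, .data$p_s1_g2,
                                  .data$p_s2_g1, .data$p_s2_g2)) |>
    dplyr::arrange(.data$.worst_p, .data$snp1_id, .data$snp2_id) |>
    dplyr::distinct(.data$gene1_id, .data$gene2_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$gene1_id, .data$gene2_id) |>
    dplyr::select(-".worst_p")
}

#' Run the full quartet-discovery chain on one dataset
#'
#' Convenience wrapper executing association scan, triplet construction,
#' quartet assembly and the three filters (cooperating sources, no better
#' intermediate SNP, unique gene targets) in the canonical order.  Counts are
#' monotonically non-increasing along the filter chain.
#'
#' @param geno,expr Sample-aligned matrices.
#' @param assoc_threshold Association-pair retention threshold.
#' @param alpha Nominal significance level for conditional tests and filters.
#' @param source_categories SNP categories eligible as sources.
#' @return List with elements `assoc`, `triplets`, `quartets` (unfiltered),
#'   `cooperating`, `intermediate`, `unique` (tibbles) and `counts` (named
#'   integer vector of the stage funnel).
#' @export
discover_quartets <- function(geno, expr, assoc_threshold = 1e-4,
                              alpha = 0.05,
                              source_categories = c("exon", "tf", "both")) {
  assoc <- associate_all(geno, expr, p_threshold = assoc_threshold,
                         source_categories = source_categories)
  triplets <- build_triplets(assoc, geno, expr, alpha = alpha)
  quartets <- assemble_quartets(triplets)
  coop <- filter_cooperating(quartets, geno, expr, alpha = alpha)
  inter <- filter_intermediate(coop, triplets, geno, expr, alpha = alpha)
  uniq <- filter_unique_targets(inter)
  list(
    assoc = assoc, triplets = triplets, quartets = quartets,
    cooperating = coop, intermediate = inter, unique = uniq,
    counts = c(
      n_assoc_pairs = nrow(assoc), n_triplets = nrow(triplets),
      n_quartets = nrow(quartets), n_cooperating = nrow(coop),
      n_intermediate = nrow(inter), n_unique_targets = nrow(uniq)
    )
  )
}
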