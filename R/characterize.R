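#' Enumerate all sign configurations of a quartet
#'
#' A quartet has four signed regulatory edges (s1->g1, s1->g2, s2->g1,
#' s2->g2), each up (+1) or down (-1): 2^4 = 16 configurations.  A
#' configuration is *consistent* when it has an even number of up edges —
#' equivalently, when the product of the four signs is +1.  The 8 consistent
#' configurations partition into 4 two-member categories under the two binary
#' symmetry criteria of [classify_category()].
#'
#' @return Tibble of all 16 configurations with columns `s1g1`, `s1g2`,
#'   `s2g1`, `s2g2` (each +1/-1), `consistent`, and (for consistent rows)
#'   `genes_axis`, `snps_axis`, `category`.
#' @export
sign_configurations <- function() {
  grid <- tidyr::expand_grid(s1g1 = c(1, -1), s1g2 = c(1, -1),
                             s2g1 = c(1, -1), s2g2 = c(1, -1))
  grid$consistent <- classify_consistency(grid$s1g1, grid$s1g2,
                                          grid$s2g1, grid$s2g2)
  cat <- rep(NA_character_, nrow(grid))
  ga <- rep(NA_character_, nrow(grid))
  sa <- rep(NA_character_, nrow(grid))
  ok <- grid$consistent
  if (any(ok)) {
    lab <- classify_category(grid$s1g1[ok], grid$s1g2[ok],
                             grid$s2g1[ok], grid$s2g2[ok])
    ga[ok] <- lab$genes_axis
    sa[ok] <- lab$snps_axis
    cat[ok] <- lab$category
  }
  grid$genes_axis <- ga
  grid$snps_axis <- sa
  grid$category <- cat
  grid
}

#' Parity consistency of a sign configuration
#'
#' `TRUE` iff the number of up (+1) edges is even — equivalently, the product
#' of the four edge signs is +1.  With four edges, an even number of up edges
#' is the same as an even number of down edges.
#'
#' @param s1g1,s1g2,s2g1,s2g2 Edge signs, each +1 or -1 (vectorized).
#' @return Logical vector.
#' @export
classify_consistency <- function(s1g1, s1g2, s2g1, s2g2) {
  stopifnot(all(abs(c(s1g1, s1g2, s2g1, s2g2)) == 1))
  s1g1 * s1g2 * s2g1 * s2g2 == 1
}

#' Symmetry category of a consistent sign configuration
#'
#' Two binary criteria classify the 8 consistent configurations into 4
#' categories of 2 members each:
#' * `genes_axis`: `"same"` when the two sources act on gene 2 in the same
#'   directions as on gene 1, i.e. `(s1g1, s2g1) == (s1g2, s2g2)`;
#'   `"opposite"` otherwise.
#' * `snps_axis`: `"same"` when source 2 acts on the two targets in the same
#'   directions as source 1, i.e. `(s1g1, s1g2) == (s2g1, s2g2)`;
#'   `"opposite"` otherwise.
#'
#' @param s1g1,s1g2,s2g1,s2g2 Edge signs of *consistent* configurations
#'   (vectorized); inconsistent input is a contract violation.
#' @return Tibble with `genes_axis`, `snps_axis` and the combined `category`
#'   label (e.g. `"same/opposite"`).
#' @export
classify_category <- function(s1g1, s1g2, s2g1, s2g2) {
  if (!all(classify_consistency(s1g1, s1g2, s2g1, s2g2))) {
    stop("category is defined only for consistent configurations",
         call. = FALSE)
  }
  genes_axis <- ifelse(s1g1 == s1g2 & s2g1 == s2g2, "same", "opposite")
  snps_axis <- ifelse(s1g1 == s2g1 & s1g2 == s2g2, "same", "opposite")
  tibble::tibble(
    genes_axis = genes_axis,
    snps_axis = snps_axis,
    category = paste(genes_axis, snps_axis, sep = "/")
  )
}

#' Orient the four edges of each quartet by marginal effect direction
#'
#' Edge sign is the sign of the marginal regression slope of the target on
#' the source's minor-allele count: up-regulation means a positive
#' correlation between minor-allele copies and expression.
#'
#' @param quartets Quartet tibble.
#' @param assoc Association tibble containing all four marginal records per
#'   quartet (as produced by [associate_all()] at the discovery threshold).
#' @return `quartets` with sign columns `s1g1`, `s1g2`, `s2g1`, `s2g2`
#'   (+1/-1).
#' @export
orient_edges <- function(quartets, assoc) {
  look <- function(snp, gene) {
    i <- match(paste(snp, gene), paste(assoc$snp_id, assoc$gene_id))
    b <- assoc$beta[i]
    if (anyNA(b)) stop("missing marginal association for an oriented edge",
                       call. = FALSE)
    if (any(b == 0)) stop("zero marginal slope cannot be oriented", call. = FALSE)
    sign(b)
  }
  quartets$s1g1 <- look(quartets$snp1_id, quartets$gene1_id)
  quartets$s1g2 <- look(quartets$snp1_id, quartets$gene2_id)
  quartets$s2g1 <- look(quartets$snp2_id, quartets$gene1_id)
  quartets$s2g2 <- look(quartets$snp2_id, quartets$gene2_id)
  quartets
}

#' Cis/trans class of each quartet
#'
#' A source is *cis* to a target when it resides within the target gene's
#' span (same chromosome, position inside the 1-based inclusive span), and
#' *trans* otherwise.  Counting cis relationships over the four source-target
#' pairs bins quartets into three classes: two cis, one cis, two trans (zero
#' cis).  Counts above 2 are reported as-is (`"cis_3"`, `"cis_4"`) with a
#' warning — they require a source inside both targets' spans.
#'
#' @param quartets Quartet tibble.
#' @param geno,expr Matrices providing SNP positions and gene spans.
#' @return `quartets` with `cis_count` and `cis_trans_class` columns.
#' @export
classify_cis_trans <- function(quartets, geno, expr) {
  one <- function(snp, gene) {
    si <- match(snp, geno$snps$snp_id)
    gi <- match(gene, expr$genes$gene_id)
    as.integer(
      norm_chrom(geno$snps$chrom[si]) == norm_chrom(expr$genes$chrom[gi]) &
        geno$snps$pos[si] >= expr$genes$start[gi] &
        geno$snps$pos[si] <= expr$genes$end[gi]
    )
  }
  cnt <- one(quartets$snp1_id, quartets$gene1_id) +
    one(quartets$snp1_id, quartets$gene2_id) +
    one(quartets$snp2_id, quartets$gene1_id) +
    one(quartets$snp2_id, quartets$gene2_id)
  if (any(cnt > 2)) {
    warning("quartet(s) with more than two cis relationships reported as-is",
            call. = FALSE)
  }
  quartets$cis_count <- cnt
  quartets$cis_trans_class <- dplyr::case_when(
    cnt == 0 ~ "two_trans",
    cnt == 1 ~ "one_cis",
    cnt == 2 ~ "two_cis",
    TRUE ~ paste0("cis_", cnt)
  )
  quartets
}

#' Co-expression of a quartet's two targets
#'
#' Pearson correlation of the two target genes' expression across samples.
#'
#' @param quartets Quartet tibble.
#' @param expr An [expression_matrix()].
#' @return `quartets` with `target_r` and `target_abs_r` columns (`NA` with a
#'   warning for constant genes).
#' @export
target_coexpression <- function(quartets, expr) {
  r <- vapply(seq_len(nrow(quartets)), function(i) {
    x <- expr$values[, quartets$gene1_id[i]]
    y <- expr$values[, quartets$gene2_id[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (anyNA(r)) warning("constant target gene(s): correlation undefined",
                        call. = FALSE)
  quartets$target_r <- r
  quartets$target_abs_r <- abs(r)
  quartets
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Used for every real-vs-permuted categorical comparison (annotation bins,
#' dependency classes, shared-term and GWAS overlaps).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
compare_categorical <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero contingency table", call. = FALSE)
  stats::fisher.test(tab)$p.value
}

#' Genes whose span contains each SNP
#'
#' @param geno A [genotype_matrix()].
#' @param genes Gene span tibble (`gene_id`, `chrom`, `start`, `end`), e.g.
#'   `expr$genes`.
#' @return Tibble `snp_id`, `gene_id` with one row per containment.
#' @export
snp_host_genes <- function(geno, genes) {
  rows <- list()
  gchrom <- norm_chrom(genes$chrom)
  schrom <- norm_chrom(geno$snps$chrom)
  for (ch in unique(schrom)) {
    i <- which(schrom == ch)
    j <- which(gchrom == ch)
    if (length(j) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = geno$snps$pos[i], width = 1L),
      IRanges::IRanges(start = genes$start[j], end = genes$end[j])
    )
    if (length(hits) == 0) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      snp_id = geno$snps$snp_id[i[S4Vectors::queryHits(hits)]],
      gene_id = genes$gene_id[j[S4Vectors::subjectHits(hits)]]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(snp_id = character(), gene_id = character())
  }
  dplyr::distinct(out)
}

# Does each quartet's gene pair share at least one annotation term?
pair_shares_term <- function(gene1, gene2, gene2terms) {
  terms <- split(gene2terms$term_id, gene2terms$gene_id)
  vapply(seq_along(gene1), function(i) {
    t1 <- terms[[gene1[i]]]
    t2 <- terms[[gene2[i]]]
    !is.null(t1) && !is.null(t2) && length(intersect(t1, t2)) > 0
  }, logical(1))
}

#' Shared-annotation enrichment of real vs permuted quartets
#'
#' For each quartet, records whether its pair of target genes (or, with
#' `on = "sources"`, the pair of genes harboring its source SNPs) shares at
#' least one annotation term, then compares the real and permuted sharing
#' fractions with a two-sided Fisher's exact test.  Genes absent from the
#' annotation table are treated as term-free (counted as non-sharing, with a
#' message).
#'
#' @param real_quartets,perm_quartets Quartet tibbles.
#' @param gene2terms Tibble `gene_id`, `term_id` (user-supplied; no live
#'   ontology access).
#' @param on `"targets"` (gene targets) or `"sources"` (host genes of the
#'   source SNPs; requires `host`).
#' @param host For `on = "sources"`: tibble `snp_id`, `gene_id` from
#'   [snp_host_genes()].  A source pair "shares" when any host gene of one
#'   SNP shares a term with any host gene of the other.
#' @return One-row tibble: sharing counts per set and the Fisher p-value.
#' @export
shared_annotation_test <- function(real_quartets, perm_quartets, gene2terms,
                                   on = c("targets", "sources"), host = NULL) {
  on <- match.arg(on)
  known <- unique(gene2terms$gene_id)
  shares <- function(q) {
    if (nrow(q) == 0) return(logical(0))
    if (on == "targets") {
      miss <- setdiff(unique(c(q$gene1_id, q$gene2_id)), known)
      if (length(miss) > 0) {
        message(length(miss), " gene(s) without annotation treated as term-free")
      }
      pair_shares_term(q$gene1_id, q$gene2_id, gene2terms)
    } else {
      if (is.null(host)) stop("on = 'sources' requires host", call. = FALSE)
      terms <- split(gene2terms$term_id, gene2terms$gene_id)
      hosts <- split(host$gene_id, host$snp_id)
      snp_terms <- function(s) unique(unlist(terms[hosts[[s]]]))
      vapply(seq_len(nrow(q)), function(i) {
        t1 <- snp_terms(q$snp1_id[i]); t2 <- snp_terms(q$snp2_id[i])
        length(intersect(t1, t2)) > 0
      }, logical(1))
    }
  }
  sr <- shares(real_quartets)
  sp <- shares(perm_quartets)
  tab <- matrix(c(sum(sr), sum(!sr), sum(sp), sum(!sp)), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("real", "permuted"),
                                c("shares", "no_shared_term")))
  tibble::tibble(
    comparison = paste0("shared_annotation_", on),
    n_real = length(sr), n_real_sharing = sum(sr),
    n_perm = length(sp), n_perm_sharing = sum(sp),
    p_value = compare_categorical(tab)
  )
}

#' GWAS-gene overlap of real vs permuted quartets
#'
#' For each quartet, records whether at least one source SNP resides in a
#' gene from a user-supplied GWAS-locus gene list, then compares real vs
#' permuted with a two-sided Fisher's exact test.
#'
#' @param real_quartets,perm_quartets Quartet tibbles.
#' @param gwas_genes Character vector of gene IDs.
#' @param host Tibble `snp_id`, `gene_id` from [snp_host_genes()].
#' @return One-row tibble with overlap counts and the Fisher p-value.
#' @export
gwas_overlap_test <- function(real_quartets, perm_quartets, gwas_genes, host) {
  in_gwas <- function(q) {
    if (nrow(q) == 0) return(logical(0))
    hosts <- split(host$gene_id, host$snp_id)
    vapply(seq_len(nrow(q)), function(i) {
      g <- unique(unlist(hosts[c(q$snp1_id[i], q$snp2_id[i])]))
      length(intersect(g, gwas_genes)) > 0
    }, logical(1))
  }
  vr <- in_gwas(real_quartets)
  vp <- in_gwas(perm_quartets)
  tab <- matrix(c(sum(vr), sum(!vr), sum(vp), sum(!vp)), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("real", "permuted"),
                                c("gwas_overlap", "none")))
  tibble::tibble(
    comparison = "gwas_overlap",
    n_real = length(vr), n_real_overlap = sum(vr),
    n_perm = length(vp), n_perm_overlap = sum(vp),
    p_value = compare_categorical(tab)
  )
}

# Annotation-category pair of the two sources, binned as exon+exon / exon+tf
# / tf+tf; "both"-category SNPs count as exon (documented precedence).
source_category_pair <- function(cat1, cat2) {
  simplify <- function(x) ifelse(x == "both", "exon", x)
  a <- simplify(cat1); b <- simplify(cat2)
  lo <- pmin(a, b); hi <- pmax(a, b)
  paste(lo, hi, sep = "+")
}

#' Attach every descriptive property to a quartet table
#'
#' Adds edge signs and parity consistency, symmetry category (for consistent
#' quartets), cis/trans class, target co-expression, source/target
#' same-chromosome flags and the source annotation-category bin.
#'
#' @param quartets Quartet tibble (final filtered set or a permuted set).
#' @param assoc Association tibble with the marginal records.
#' @param geno,expr Matrices for positions, spans, categories and expression.
#' @return The characterized quartet tibble.
#' @export
characterize_quartets <- function(quartets, assoc, geno, expr) {
  if (nrow(quartets) == 0) return(quartets)
  q <- orient_edges(quartets, assoc)
  q$consistent <- classify_consistency(q$s1g1, q$s1g2, q$s2g1, q$s2g2)
  q$genes_axis <- NA_character_
  q$snps_axis <- NA_character_
  q$category <- NA_character_
  if (any(q$consistent)) {
    lab <- classify_category(q$s1g1[q$consistent], q$s1g2[q$consistent],
                             q$s2g1[q$consistent], q$s2g2[q$consistent])
    q$genes_axis[q$consistent] <- lab$genes_axis
    q$snps_axis[q$consistent] <- lab$snps_axis
    q$category[q$consistent] <- lab$category
  }
  q <- classify_cis_trans(q, geno, expr)
  q <- target_coexpression(q, expr)
  gi1 <- match(q$gene1_id, expr$genes$gene_id)
  gi2 <- match(q$gene2_id, expr$genes$gene_id)
  q$sources_same_chrom <- norm_chrom(q$chrom_s1) == norm_chrom(q$chrom_s2)
  q$targets_same_chrom <- norm_chrom(expr$genes$chrom[gi1]) ==
    norm_chrom(expr$genes$chrom[gi2])
  si1 <- match(q$snp1_id, geno$snps$snp_id)
  si2 <- match(q$snp2_id, geno$snps$snp_id)
  q$source_categories <- source_category_pair(geno$snps$category[si1],
                                              geno$snps$category[si2])
  q
}
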