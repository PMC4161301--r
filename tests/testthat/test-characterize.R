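test_that("sign-configuration algebra: 16 total, 8 consistent, 4 categories", {
  cfgs <- sign_configurations()
  expect_equal(nrow(cfgs), 16)
  # parity law by independent enumeration: even number of up edges
  n_up <- rowSums(cfgs[, c("s1g1", "s1g2", "s2g1", "s2g2")] == 1)
  expect_identical(cfgs$consistent, n_up %% 2 == 0)
  expect_equal(sum(cfgs$consistent), 8)
  expect_equal(sum(!cfgs$consistent), 8)
  # product rule equivalent to the parity rule
  expect_identical(cfgs$consistent,
                   cfgs$s1g1 * cfgs$s1g2 * cfgs$s2g1 * cfgs$s2g2 == 1)
  # the 8 consistent configurations quotient into 4 categories of 2
  tab <- table(cfgs$category[cfgs$consistent])
  expect_equal(length(tab), 4)
  expect_true(all(tab == 2))
})

test_that("sign-flip maps act on categories through the two axes", {
  cfgs <- sign_configurations()
  ok <- cfgs[cfgs$consistent, ]
  for (i in seq_len(nrow(ok))) {
    # the two members of a category are global sign flips of each other
    partner <- classify_category(-ok$s1g1[i], -ok$s1g2[i],
                                 -ok$s2g1[i], -ok$s2g2[i])
    expect_identical(partner$category, ok$category[i])
    # flipping both edges of one source preserves the genes axis and
    # toggles the snps axis (moves to the paired category)
    src_flip <- classify_category(-ok$s1g1[i], -ok$s1g2[i],
                                  ok$s2g1[i], ok$s2g2[i])
    expect_identical(src_flip$genes_axis, ok$genes_axis[i])
    expect_false(identical(src_flip$snps_axis, ok$snps_axis[i]))
    # flipping both edges of one target does the reverse
    tgt_flip <- classify_category(-ok$s1g1[i], ok$s1g2[i],
                                  -ok$s2g1[i], ok$s2g2[i])
    expect_identical(tgt_flip$snps_axis, ok$snps_axis[i])
    expect_false(identical(tgt_flip$genes_axis, ok$genes_axis[i]))
  }
})

test_that("consistency and category are invariant to source/target swaps", {
  cfgs <- sign_configurations()
  # swapping the two sources
  expect_identical(
    classify_consistency(cfgs$s2g1, cfgs$s2g2, cfgs$s1g1, cfgs$s1g2),
    cfgs$consistent)
  # swapping the two targets
  expect_identical(
    classify_consistency(cfgs$s1g2, cfgs$s1g1, cfgs$s2g2, cfgs$s2g1),
    cfgs$consistent)
  ok <- cfgs[cfgs$consistent, ]
  swap_s <- classify_category(ok$s2g1, ok$s2g2, ok$s1g1, ok$s1g2)
  swap_g <- classify_category(ok$s1g2, ok$s1g1, ok$s2g2, ok$s2g1)
  expect_identical(swap_s$category, ok$category)
  expect_identical(swap_g$category, ok$category)
})

test_that("specific configurations classify as documented", {
  expect_true(classify_consistency(1, 1, 1, 1))
  expect_false(classify_consistency(1, 1, 1, -1))
  lab <- classify_category(1, 1, 1, 1)
  expect_identical(lab$genes_axis, "same")
  expect_identical(lab$snps_axis, "same")
  lab2 <- classify_category(1, -1, 1, -1)
  expect_identical(lab2$genes_axis, "opposite")
  expect_identical(lab2$snps_axis, "same")
  expect_error(classify_category(1, 1, 1, -1), "consistent")
})

test_that("edge orientation equals the sign of the Pearson correlation", {
  set.seed(501)
  n <- 100
  s1 <- rbinom(n, 2, 0.3); s2 <- rbinom(n, 2, 0.4)
  g1 <- s1 + s2 + rnorm(n); g2 <- -s1 - s2 + rnorm(n)
  geno <- make_geno(cbind(s1, s2))
  expr <- make_expr(cbind(g1, g2))
  assoc <- associate_all(geno, expr, p_threshold = 1)
  q <- tibble::tibble(snp1_id = "s001", snp2_id = "s002",
                      gene1_id = "g001", gene2_id = "g002")
  oe <- orient_edges(q, assoc)
  expect_equal(oe$s1g1, sign(cor(s1, g1)))
  expect_equal(oe$s1g2, sign(cor(s1, g2)))
  expect_equal(oe$s2g1, sign(cor(s2, g1)))
  expect_equal(oe$s2g2, sign(cor(s2, g2)))
})

test_that("cis/trans classes match a brute-force containment scan", {
  set.seed(511)
  geno <- make_geno(matrix(rbinom(200, 2, 0.3), 10, 20),
                    chrom = sample(c("1", "2"), 20, replace = TRUE),
                    pos = sample.int(1000, 20))
  expr <- make_expr(matrix(rnorm(100), 10, 10),
                    chrom = sample(c("1", "2"), 10, replace = TRUE),
                    start = sample.int(500, 10),
                    end = sample.int(500, 10) + 500L)
  q <- tibble::tibble(
    snp1_id = sample(geno$snps$snp_id, 15, replace = TRUE),
    snp2_id = sample(geno$snps$snp_id, 15, replace = TRUE),
    gene1_id = sample(expr$genes$gene_id, 15, replace = TRUE),
    gene2_id = sample(expr$genes$gene_id, 15, replace = TRUE)
  )
  got <- suppressWarnings(classify_cis_trans(q, geno, expr))
  cis1 <- function(snp, gene) {
    si <- match(snp, geno$snps$snp_id); gi <- match(gene, expr$genes$gene_id)
    geno$snps$chrom[si] == expr$genes$chrom[gi] &
      geno$snps$pos[si] >= expr$genes$start[gi] &
      geno$snps$pos[si] <= expr$genes$end[gi]
  }
  want <- cis1(q$snp1_id, q$gene1_id) + cis1(q$snp1_id, q$gene2_id) +
    cis1(q$snp2_id, q$gene1_id) + cis1(q$snp2_id, q$gene2_id)
  expect_equal(got$cis_count, as.integer(want))
  expect_identical(got$cis_trans_class[got$cis_count == 0][1], "two_trans")
})

test_that("a SNP inside the target span on the same chromosome is cis", {
  geno <- make_geno(matrix(rbinom(40, 2, 0.3), 10, 4),
                    chrom = c("1", "1", "3", "3"),
                    pos = c(150L, 999L, 150L, 150L))
  expr <- make_expr(matrix(rnorm(20), 10, 2), chrom = c("1", "2"),
                    start = c(100L, 100L), end = c(200L, 200L))
  q <- tibble::tibble(snp1_id = "s001", snp2_id = "s002",
                      gene1_id = "g001", gene2_id = "g002")
  out <- classify_cis_trans(q, geno, expr)
  expect_equal(out$cis_count, 1L)  # only s001 -> g001
  expect_identical(out$cis_trans_class, "one_cis")
  # sources on chromosomes absent from both targets -> two_trans
  q2 <- tibble::tibble(snp1_id = "s003", snp2_id = "s004",
                       gene1_id = "g001", gene2_id = "g002")
  expect_identical(classify_cis_trans(q2, geno, expr)$cis_trans_class,
                   "two_trans")
})

test_that("target co-expression is the Pearson correlation of the two genes", {
  set.seed(521)
  v <- rnorm(30)
  expr <- make_expr(cbind(v, -v, rnorm(30)))
  q <- tibble::tibble(gene1_id = c("g001", "g001"), gene2_id = c("g002", "g003"))
  out <- target_coexpression(q, expr)
  expect_equal(out$target_r[1], -1)
  expect_equal(out$target_abs_r[1], 1)
  expect_equal(out$target_r[2], cor(v, expr$values[, "g003"]))
})

test_that("Fisher's exact p agrees with hypergeometric enumeration", {
  expect_equal(compare_categorical(matrix(c(5, 5, 5, 5), 2)), 1)
  t2 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(compare_categorical(t2), fisher_enum_oracle(t2),
               tolerance = 1e-12)
  set.seed(531)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(compare_categorical(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-9)
  }
  expect_error(compare_categorical(matrix(0, 2, 2)), "all-zero")
})

test_that("the MHC-style enrichment table is significant in the right direction", {
  # 7 of 82 real quartets vs 4 of 342 permuted quartets in one region
  p <- compare_categorical(matrix(c(7, 82 - 7, 4, 342 - 4), 2, byrow = TRUE))
  expect_lt(p, 0.0014)
})

test_that("host-gene lookup matches a brute-force scan", {
  set.seed(541)
  geno <- make_geno(matrix(rbinom(300, 2, 0.3), 10, 30),
                    chrom = sample(c("1", "chr2"), 30, replace = TRUE),
                    pos = sample.int(2000, 30))
  genes <- tibble::tibble(
    gene_id = sprintf("h%02d", 1:12),
    chrom = sample(c("1", "2"), 12, replace = TRUE),
    start = sample.int(1500, 12)
  )
  genes$end <- genes$start + sample.int(800, 12)
  got <- snp_host_genes(geno, genes)
  for (i in seq_len(nrow(geno$snps))) {
    inside <- genes$gene_id[
      sub("^chr", "", genes$chrom) == sub("^chr", "", geno$snps$chrom[i]) &
        genes$start <= geno$snps$pos[i] & genes$end >= geno$snps$pos[i]]
    expect_setequal(got$gene_id[got$snp_id == geno$snps$snp_id[i]], inside)
  }
})

test_that("shared-annotation and GWAS overlap tests follow set semantics", {
  real <- tibble::tibble(
    snp1_id = c("sA", "sC"), snp2_id = c("sB", "sD"),
    gene1_id = c("g1", "g3"), gene2_id = c("g2", "g4")
  )
  perm <- tibble::tibble(
    snp1_id = c("sE", "sF"), snp2_id = c("sF", "sE"),
    gene1_id = c("g5", "g5"), gene2_id = c("g6", "g7")
  )
  g2t <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6", "hA", "hB"),
    term_id = c("T1", "T1", "T2", "T3", "T4", "T5", "TS", "TS")
  )
  out <- shared_annotation_test(real, perm, g2t)
  expect_equal(out$n_real_sharing, 1)   # g1,g2 share T1; g3,g4 disjoint
  expect_equal(out$n_perm_sharing, 0)   # g7 unannotated -> term-free
  host <- tibble::tibble(snp_id = c("sA", "sB", "sC", "sE", "sF"),
                         gene_id = c("hA", "hB", "hA", "hA", "hA"))
  out2 <- shared_annotation_test(real, perm, g2t, on = "sources", host = host)
  expect_equal(out2$n_real_sharing, 1)  # hA,hB share TS; sD has no host
  # GWAS overlap: empty list -> all false, p = 1
  g0 <- gwas_overlap_test(real, perm, character(0), host)
  expect_equal(g0$n_real_overlap, 0)
  expect_equal(g0$p_value, 1)
  gall <- gwas_overlap_test(real, perm, c("hA", "hB"), host)
  expect_equal(gall$n_real_overlap, 2)
  expect_equal(gall$n_perm_overlap, 2)
})

test_that("characterize_quartets assembles every descriptive column", {
  sim <- simulate_dataset(planted_bifan_config(n_bifans = 3, n_noise_snps = 8,
                                               n_noise_genes = 8,
                                               master_seed = 23))
  res <- discover_quartets(sim$geno, sim$expr)
  q <- characterize_quartets(res$unique, res$assoc, sim$geno, sim$expr)
  expect_true(all(c("s1g1", "s1g2", "s2g1", "s2g2", "consistent", "category",
                    "cis_trans_class", "target_r", "sources_same_chrom",
                    "targets_same_chrom", "source_categories") %in% names(q)))
  # planted unit-positive bi-fans are consistent, same/same, trans-only,
  # sources on different chromosomes
  expect_true(all(q$consistent))
  expect_true(all(q$category == "same/same"))
  expect_true(all(q$cis_trans_class == "two_trans"))
  expect_true(all(!q$sources_same_chrom))
  expect_true(all(q$source_categories %in% c("exon+exon", "exon+tf", "tf+tf")))
})
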