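fake_triplets <- function(snps, gene1 = "gA", gene2 = "gB", chrom = "1") {
  tibble::tibble(
    snp_id = snps, gene1_id = gene1, gene2_id = gene2,
    p1 = 1e-6, p2 = 1e-6, p1_given_g2 = 0.01, p2_given_g1 = 0.01,
    kind = "mutual", directional_target = NA_character_, chrom_snp = chrom
  )
}

test_that("quartet assembly is combinatorial over triplets sharing a gene pair", {
  # two triplets on the same gene pair -> one quartet
  q <- assemble_quartets(fake_triplets(c("sA", "sB")))
  expect_equal(nrow(q), 1)
  expect_identical(q$snp1_id, "sA")
  expect_identical(q$snp2_id, "sB")
  # different target pairs -> no quartet
  tr <- dplyr::bind_rows(fake_triplets("sA"),
                         fake_triplets("sB", gene2 = "gC"))
  expect_equal(nrow(assemble_quartets(tr)), 0)
  # k triplets -> k*(k-1)/2 quartets
  for (k in c(3, 5, 8)) {
    q <- assemble_quartets(fake_triplets(sprintf("s%02d", 1:k)))
    expect_equal(nrow(q), k * (k - 1) / 2)
    expect_true(all(q$snp1_id < q$snp2_id))
  }
})

test_that("assembly is invariant to triplet input order", {
  tr <- dplyr::bind_rows(
    fake_triplets(c("sC", "sA", "sB")),
    fake_triplets(c("sD", "sB"), gene1 = "gX", gene2 = "gY")
  )
  q1 <- assemble_quartets(tr)
  q2 <- assemble_quartets(tr[sample(nrow(tr)), ])
  expect_equal(q1, q2)
})

test_that("dependency classes derive from the unordered pair of triplet kinds", {
  expect_identical(dependency_structure("mutual", "mutual"), "mutual_mutual")
  expect_identical(dependency_structure("mutual", "directional"), "mixed")
  expect_identical(dependency_structure("directional", "mutual"), "mixed")
  expect_identical(dependency_structure("directional", "directional"),
                   "directional_directional")
})

test_that("cooperating filter demands all four joint coefficients", {
  pass <- 0; fail_single <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    s1 <- rbinom(n, 2, 0.3); s2 <- rbinom(n, 2, 0.3)
    g1 <- s1 + s2 + rnorm(n)
    g2 <- s1 - s2 + rnorm(n)
    g3 <- s1 + rnorm(n)  # depends only on s1
    geno <- make_geno(cbind(s1, s2))
    expr <- make_expr(cbind(g1, g2, g3))
    q_ok <- tibble::tibble(snp1_id = "s001", snp2_id = "s002",
                           gene1_id = "g001", gene2_id = "g002")
    q_bad <- tibble::tibble(snp1_id = "s001", snp2_id = "s002",
                            gene1_id = "g001", gene2_id = "g003")
    if (nrow(filter_cooperating(q_ok, geno, expr)) == 1) pass <- pass + 1
    if (nrow(filter_cooperating(q_bad, geno, expr)) == 0) {
      fail_single <- fail_single + 1
    }
  }
  expect_gte(pass, 19)
  # the null s2 coefficient in g3's model is significant ~5% of the time,
  # so the miss rate is bounded with a calibrated binomial band
  # (P[Binom(20, 0.05) >= 5] < 0.003)
  expect_gte(fail_single, 16)
})

test_that("perfectly collinear sources fail the cooperating filter flagged", {
  set.seed(301)
  n <- 100
  s1 <- rbinom(n, 2, 0.3)
  geno <- make_geno(cbind(s1, s1))  # exact copy
  expr <- make_expr(cbind(s1 + rnorm(n), s1 + rnorm(n)))
  q <- tibble::tibble(snp1_id = "s001", snp2_id = "s002",
                      gene1_id = "g001", gene2_id = "g002")
  res <- filter_cooperating(q, geno, expr, keep_all = TRUE)
  expect_true(res$collinear)
  expect_false(res$cooperating)
})

test_that("a co-chromosomal causal SNP removes the tag-SNP quartet", {
  # s3 causal (both genes), s1 a tag in LD r ~ 0.9 on the same chromosome,
  # s2 an independent source on another chromosome
  tag_removed <- 0; causal_kept <- 0
  for (seed in 1:20) {
    cfg <- sim_config(n_snps = 3, n_genes = 2, n_samples = 200,
                      maf_range = c(0.3, 0.3),
                      ld_pairs = list(ld_pair(c(1, 3), 0.9)),
                      noise_sd = 1, master_seed = seed)
    sim <- simulate_dataset(cfg)
    geno <- sim$geno
    geno$snps$chrom <- c("1", "2", "1")  # s1 and s3 co-chromosomal
    s2 <- geno$counts[, 2]; s3 <- geno$counts[, 3]
    vals <- cbind(s3 + s2 + rnorm(200), s3 + s2 + rnorm(200))
    expr <- make_expr(vals, samples = geno$samples)
    assoc <- associate_all(geno, expr, p_threshold = 1e-4)
    tr <- build_triplets(assoc, geno, expr)
    q <- assemble_quartets(tr)
    coop <- filter_cooperating(q, geno, expr)
    final <- filter_intermediate(coop, tr, geno, expr)
    pair <- function(d, a, b) any(d$snp1_id == a & d$snp2_id == b)
    if (pair(coop, "s0001", "s0002") && !pair(final, "s0001", "s0002")) {
      tag_removed <- tag_removed + 1
    }
    if (pair(final, "s0002", "s0003")) causal_kept <- causal_kept + 1
  }
  expect_gte(tag_removed, 11)   # majority behaviour across seeds
  expect_gte(causal_kept, 11)
})

test_that("the intermediate filter passes vacuously without co-chromosomal candidates", {
  tr <- dplyr::bind_rows(
    fake_triplets(c("sA", "sB"), chrom = "1"),
    fake_triplets("sC", chrom = "7")  # different chromosome: never tested
  )
  q <- assemble_quartets(tr[1:2, ])
  set.seed(311)
  geno <- make_geno(matrix(rbinom(300, 2, 0.3), 100, 3), chrom = c("1", "1", "7"))
  geno$snps$snp_id <- c("sA", "sB", "sC")
  colnames(geno$counts) <- geno$snps$snp_id
  expr <- make_expr(matrix(rnorm(200), 100, 2))
  expr$genes$gene_id <- c("gA", "gB")
  colnames(expr$values) <- expr$genes$gene_id
  out <- filter_intermediate(q, tr, geno, expr)
  expect_equal(nrow(out), 1)
  expect_true(out$passed_intermediate)
  # no third triplet at all -> also vacuous
  out2 <- filter_intermediate(q, tr[1:2, ], geno, expr)
  expect_equal(nrow(out2), 1)
})

test_that("unique-target selection minimizes the worst marginal p", {
  set.seed(321)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    q <- tibble::tibble(
      snp1_id = sprintf("a%02d", 1:k), snp2_id = sprintf("b%02d", 1:k),
      gene1_id = "gA", gene2_id = "gB",
      p_s1_g1 = runif(k, 0, 1e-4), p_s1_g2 = runif(k, 0, 1e-4),
      p_s2_g1 = runif(k, 0, 1e-4), p_s2_g2 = runif(k, 0, 1e-4)
    )
    extra <- tibble::tibble(
      snp1_id = "x", snp2_id = "y", gene1_id = "gC", gene2_id = "gD",
      p_s1_g1 = 1e-5, p_s1_g2 = 1e-5, p_s2_g1 = 1e-5, p_s2_g2 = 1e-5
    )
    out <- filter_unique_targets(dplyr::bind_rows(q, extra))
    expect_equal(nrow(out), 2)  # one per gene pair
    worst <- pmax(q$p_s1_g1, q$p_s1_g2, q$p_s2_g1, q$p_s2_g2)
    want <- q$snp1_id[which.min(worst)]  # brute-force argmin oracle
    expect_identical(out$snp1_id[out$gene1_id == "gA"], want)
  }
  # already-distinct gene pairs pass through unchanged
  distinct_q <- tibble::tibble(
    snp1_id = c("a", "b"), snp2_id = c("c", "d"),
    gene1_id = c("g1", "g2"), gene2_id = c("g3", "g4"),
    p_s1_g1 = 1e-6, p_s1_g2 = 1e-6, p_s2_g1 = 1e-6, p_s2_g2 = 1e-6
  )
  expect_equal(nrow(filter_unique_targets(distinct_q)), 2)
})

test_that("filter funnel counts are monotonically non-increasing", {
  sim <- simulate_dataset(planted_bifan_config(n_bifans = 4, n_noise_snps = 10,
                                               n_noise_genes = 10,
                                               master_seed = 5))
  res <- discover_quartets(sim$geno, sim$expr)
  cn <- res$counts
  expect_true(cn["n_quartets"] >= cn["n_cooperating"])
  expect_true(cn["n_cooperating"] >= cn["n_intermediate"])
  expect_true(cn["n_intermediate"] >= cn["n_unique_targets"])
})
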