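#' Describe a planted bi-fan motif
#'
#' Two source SNPs with additive effects on two target genes.  The 2x2
#' `effects` matrix holds per-minor-allele slopes, rows = sources, columns =
#' targets.
#'
#' @param snps Integer indices (into the simulated SNP set) of the two
#'   sources.
#' @param genes Integer indices of the two target genes.
#' @param effects 2x2 numeric slope matrix, all entries nonzero.
#' @param snp_chroms,gene_chroms Optional chromosome names overriding the
#'   default genome layout (e.g. to place the two sources on different
#'   chromosomes).
#' @return A `planted_bifan` description list.
#' @export
plant_bifan <- function(snps, genes, effects = matrix(1, 2, 2),
                        snp_chroms = NULL, gene_chroms = NULL) {
  effects <- matrix(as.numeric(effects), 2, 2)
  stopifnot(length(snps) == 2, length(genes) == 2, all(effects != 0),
            snps[1] != snps[2], genes[1] != genes[2])
  structure(list(snps = as.integer(snps), genes = as.integer(genes),
                 effects = effects, snp_chroms = snp_chroms,
                 gene_chroms = gene_chroms),
            class = "planted_bifan")
}

#' Describe a planted mediation chain (SNP -> gene1 -> gene2)
#'
#' @param snp Index of the source SNP.
#' @param gene1,gene2 Indices of the mediator and downstream gene.
#' @param slope1 Per-allele slope of `gene1` on the SNP.
#' @param slope2 Slope of `gene2` on `gene1`'s expression.
#' @return A `planted_mediation` description list.
#' @export
plant_mediation <- function(snp, gene1, gene2, slope1 = 1, slope2 = 1) {
  stopifnot(gene1 != gene2, slope1 != 0, slope2 != 0)
  structure(list(snp = as.integer(snp), gene1 = as.integer(gene1),
                 gene2 = as.integer(gene2), slope1 = slope1, slope2 = slope2),
            class = "planted_mediation")
}

#' Describe a target linkage-disequilibrium pair
#'
#' @param snps Indices of the two SNPs.
#' @param r Target Pearson correlation of allele counts, `|r| < 1`.
#' @return An `ld_pair` description list.
#' @export
ld_pair <- function(snps, r) {
  stopifnot(length(snps) == 2, snps[1] != snps[2], abs(r) < 1)
  structure(list(snps = as.integer(snps), r = r), class = "ld_pair")
}

#' Simulation configuration
#'
#' Defines a synthetic genotype/expression dataset with the statistical
#' structure the quartet analysis assumes: biallelic SNPs with MAF drawn from
#' `maf_range`, approximately Gaussian per-gene expression, additive
#' per-allele effects of planted sources, mediation chains, Gaussian-copula
#' LD pairs, and pure-noise nulls everywhere else.  The default
#' `n_samples = 50` mirrors the cohort size typical of fully sequenced
#' genotype + RNA-seq panels.
#'
#' @param n_snps,n_genes Dataset dimensions.
#' @param n_samples Cohort size.
#' @param maf_range Minor allele frequency range, inside (0.05, 0.5].
#' @param planted_bifans List of [plant_bifan()] descriptions.
#' @param planted_mediations List of [plant_mediation()] descriptions.
#' @param ld_pairs List of [ld_pair()] descriptions.
#' @param noise_sd Expression noise standard deviation (> 0).
#' @param master_seed Seed fully determining the dataset.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps, n_genes, n_samples = 50,
                       maf_range = c(0.1, 0.5), planted_bifans = list(),
                       planted_mediations = list(), ld_pairs = list(),
                       noise_sd = 1, master_seed = 1) {
  stopifnot(n_snps >= 1, n_genes >= 1, n_samples >= 4, noise_sd > 0,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0.05, maf_range[2] <= 0.5)
  for (b in planted_bifans) {
    stopifnot(inherits(b, "planted_bifan"),
              all(b$snps <= n_snps), all(b$genes <= n_genes))
  }
  for (m in planted_mediations) {
    stopifnot(inherits(m, "planted_mediation"), m$snp <= n_snps,
              m$gene1 <= n_genes, m$gene2 <= n_genes)
  }
  for (l in ld_pairs) {
    stopifnot(inherits(l, "ld_pair"), all(l$snps <= n_snps))
  }
  structure(
    list(n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
         n_samples = as.integer(n_samples), maf_range = maf_range,
         planted_bifans = planted_bifans,
         planted_mediations = planted_mediations, ld_pairs = ld_pairs,
         noise_sd = noise_sd, master_seed = master_seed),
    class = "sim_config"
  )
}

# P(Z1 < qa, Z2 < qb) for standard bivariate normal with correlation rho.
bvn_lower <- function(qa, qb, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(qa) * stats::pnorm(qb))
  s <- sqrt(1 - rho^2)
  stats::integrate(
    function(z) stats::dnorm(z) * stats::pnorm((qb - rho * z) / s),
    -Inf, qa, rel.tol = 1e-10
  )$value
}

# Correlation between Bernoulli(pa), Bernoulli(pb) obtained by thresholding a
# bivariate normal with latent correlation rho.
bern_corr <- function(pa, pb, rho) {
  qa <- stats::qnorm(pa); qb <- stats::qnorm(pb)
  p11 <- bvn_lower(qa, qb, rho)
  (p11 - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb))
}

# Latent normal correlation hitting a target allele-count correlation; the
# count correlation equals the allele-level Bernoulli correlation because a
# genotype is the sum of two iid allele draws.
solve_latent_rho <- function(pa, pb, r) {
  lim <- 0.9999
  lo <- bern_corr(pa, pb, -lim)
  hi <- bern_corr(pa, pb, lim)
  if (r < lo || r > hi) {
    stop(sprintf(
      "LD target r = %.3f unattainable for MAFs (%.3f, %.3f): attainable range [%.3f, %.3f]",
      r, pa, pb, lo, hi), call. = FALSE)
  }
  stats::uniroot(function(rho) bern_corr(pa, pb, rho) - r,
                 c(-lim, lim), tol = 1e-9)$root
}

default_chroms <- function(n) as.character(((seq_len(n) - 1L) %% 22L) + 1L)

#' Simulate a genotype/expression dataset with planted structure
#'
#' Genotypes are Binomial(2, MAF) minor-allele counts; LD pairs are generated
#' by thresholding correlated bivariate-normal latents at the allele level
#' (Gaussian copula), hitting the target count correlation.  Expression is
#' Gaussian noise plus the planted additive effects; mediation chains add the
#' mediator's realized expression into the downstream gene.  Non-planted
#' genes are pure noise.  The default genome layout spreads SNPs and genes
#' round-robin over 22 chromosomes with gene spans far from SNP positions, so
#' all non-planted relationships are trans; planted structures may override
#' chromosomes.  Fully reproducible from `master_seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_dataset`: list with `geno`
#'   ([genotype_matrix()]), `expr` ([expression_matrix()]) and `truth` (list
#'   of tibbles `bifans`, `mediations`, plus `null_genes`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$master_seed, {
    n <- config$n_samples
    p <- config$n_snps
    g <- config$n_genes
    samples <- sprintf("sample%03d", seq_len(n))
    snp_chrom <- default_chroms(p)
    gene_chrom <- default_chroms(g)
    for (b in config$planted_bifans) {
      if (!is.null(b$snp_chroms)) snp_chrom[b$snps] <- as.character(b$snp_chroms)
      if (!is.null(b$gene_chroms)) gene_chrom[b$genes] <- as.character(b$gene_chroms)
    }
    snps <- tibble::tibble(
      snp_id = sprintf("s%04d", seq_len(p)),
      chrom = snp_chrom,
      pos = 10000L + seq_len(p) * 137L,
      category = ifelse(seq_len(p) %% 2 == 1, "exon", "tf")
    )
    genes <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(g)),
      chrom = gene_chrom,
      start = 50000000L + seq_len(g) * 100000L,
      end = 50000000L + seq_len(g) * 100000L + 49999L
    )
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    counts <- matrix(0, n, p)
    in_ld <- integer(0)
    for (l in config$ld_pairs) {
      a <- l$snps[1]; b2 <- l$snps[2]
      rho <- solve_latent_rho(maf[a], maf[b2], l$r)
      qa <- stats::qnorm(maf[a]); qb <- stats::qnorm(maf[b2])
      dose_a <- dose_b <- numeric(n)
      for (slot in 1:2) {
        z1 <- stats::rnorm(n)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
        dose_a <- dose_a + (z1 < qa)
        dose_b <- dose_b + (z2 < qb)
      }
      counts[, a] <- dose_a
      counts[, b2] <- dose_b
      in_ld <- c(in_ld, a, b2)
    }
    free <- setdiff(seq_len(p), in_ld)
    for (j in free) counts[, j] <- stats::rbinom(n, 2, maf[j])
    values <- matrix(stats::rnorm(n * g, sd = config$noise_sd), n, g)
    bifan_rows <- list()
    for (k in seq_along(config$planted_bifans)) {
      b <- config$planted_bifans[[k]]
      for (si in 1:2) for (gi in 1:2) {
        values[, b$genes[gi]] <- values[, b$genes[gi]] +
          b$effects[si, gi] * counts[, b$snps[si]]
      }
      sg <- sign(b$effects)
      cons <- prod(sg) == 1
      lab <- if (cons) classify_category(sg[1, 1], sg[1, 2], sg[2, 1], sg[2, 2])
      bifan_rows[[k]] <- tibble::tibble(
        bifan = k,
        snp1_id = snps$snp_id[b$snps[1]], snp2_id = snps$snp_id[b$snps[2]],
        gene1_id = genes$gene_id[b$genes[1]],
        gene2_id = genes$gene_id[b$genes[2]],
        s1g1 = sg[1, 1], s1g2 = sg[1, 2], s2g1 = sg[2, 1], s2g2 = sg[2, 2],
        consistent = cons,
        category = if (cons) lab$category else NA_character_
      )
    }
    med_rows <- list()
    for (k in seq_along(config$planted_mediations)) {
      m <- config$planted_mediations[[k]]
      values[, m$gene1] <- values[, m$gene1] + m$slope1 * counts[, m$snp]
      values[, m$gene2] <- values[, m$gene2] + m$slope2 * values[, m$gene1]
      med_rows[[k]] <- tibble::tibble(
        snp_id = snps$snp_id[m$snp],
        gene1_id = genes$gene_id[m$gene1],
        gene2_id = genes$gene_id[m$gene2],
        slope1 = m$slope1, slope2 = m$slope2,
        expected_kind = "directional",
        directional_target = genes$gene_id[m$gene1]
      )
    }
    planted_genes <- unique(c(
      unlist(lapply(config$planted_bifans, `[[`, "genes")),
      unlist(lapply(config$planted_mediations,
                    function(m) c(m$gene1, m$gene2)))
    ))
    truth <- list(
      bifans = dplyr::bind_rows(bifan_rows),
      mediations = dplyr::bind_rows(med_rows),
      null_genes = genes$gene_id[setdiff(seq_len(g), planted_genes)]
    )
    structure(
      list(
        geno = genotype_matrix(counts, snps, samples),
        expr = expression_matrix(values, genes, samples),
        truth = truth,
        config = config
      ),
      class = "sim_dataset"
    )
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d samples, %d SNPs, %d genes; %d bi-fan(s), %d mediation(s), %d LD pair(s)\n",
    length(x$geno$samples), nrow(x$geno$snps), nrow(x$expr$genes),
    nrow(x$truth$bifans) %||% 0, nrow(x$truth$mediations) %||% 0,
    length(x$config$ld_pairs)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realized linkage disequilibrium between two simulated SNPs
#'
#' Pearson correlation of minor-allele counts.
#'
#' @param geno A [genotype_matrix()].
#' @param snp_a,snp_b SNP identifiers.
#' @return Correlation (NA with a warning for monomorphic SNPs).
#' @export
realized_ld <- function(geno, snp_a, snp_b) {
  x <- geno$counts[, snp_a]
  y <- geno$counts[, snp_b]
  obs <- !is.na(x) & !is.na(y)
  if (stats::sd(x[obs]) == 0 || stats::sd(y[obs]) == 0) {
    warning("monomorphic SNP: LD undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x[obs], y[obs])
}

#' Standard planted bi-fan benchmark configuration
#'
#' Builds a [sim_config()] with `n_bifans` unit-slope bi-fans whose two
#' sources sit on different chromosomes, plus pure-noise SNPs and genes.
#' This is the package's parameter-recovery benchmark: at `n_samples = 200`,
#' unit slopes, MAF 0.3 and noise sd 1, the final unique-target quartet set
#' is expected to recover essentially all planted motifs with no false
#' quartets among null gene pairs.
#'
#' @param n_bifans Number of planted bi-fans.
#' @param n_noise_snps,n_noise_genes Pure-noise SNPs and genes appended after
#'   the planted ones.
#' @param n_samples Cohort size.
#' @param maf Common minor allele frequency.
#' @param noise_sd Expression noise sd.
#' @param master_seed Seed.
#' @return A `sim_config`.
#' @export
planted_bifan_config <- function(n_bifans = 10, n_noise_snps = 40,
                                 n_noise_genes = 33, n_samples = 200,
                                 maf = 0.3, noise_sd = 1, master_seed = 1) {
  bifans <- lapply(seq_len(n_bifans), function(k) {
    plant_bifan(
      snps = c(2 * k - 1, 2 * k),
      genes = c(2 * k - 1, 2 * k),
      effects = matrix(1, 2, 2),
      snp_chroms = as.character(c((2 * k - 2) %% 22 + 1, (2 * k - 1) %% 22 + 1))
    )
  })
  sim_config(
    n_snps = 2 * n_bifans + n_noise_snps,
    n_genes = 2 * n_bifans + n_noise_genes,
    n_samples = n_samples,
    maf_range = c(maf, maf),
    planted_bifans = bifans,
    noise_sd = noise_sd,
    master_seed = master_seed
  )
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genotypes.tsv` (dosage format readable by [read_genotypes()]),
#' `expression.tsv` (genes x samples), `genes.bed`, `exons.bed`, `tf.bed`
#' (0-based half-open; 1-bp intervals at exon-/TF-category SNP positions) and
#' `ground_truth.json`.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotypes(sim$geno, file.path(dir, "genotypes.tsv"))
  em <- t(sim$expr$values)
  out <- data.frame(gene_id = rownames(em), em, check.names = FALSE)
  utils::write.table(out, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- function(chrom, start1, end1, name) {
    data.frame(chrom = chrom, start = start1 - 1L, end = end1, name = name)
  }
  utils::write.table(
    bed(sim$expr$genes$chrom, sim$expr$genes$start, sim$expr$genes$end,
        sim$expr$genes$gene_id),
    file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (nm in c("exon", "tf")) {
    sel <- sim$geno$snps$category %in% c(nm, "both")
    utils::write.table(
      bed(sim$geno$snps$chrom[sel], sim$geno$snps$pos[sel],
          sim$geno$snps$pos[sel], sim$geno$snps$snp_id[sel]),
      file.path(dir, paste0(nm, if (nm == "exon") "s" else "", ".bed")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(bifans = sim$truth$bifans, mediations = sim$truth$mediations,
         null_genes = sim$truth$null_genes),
    file.path(dir, "ground_truth.json")
  )
  invisible(dir)
}
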