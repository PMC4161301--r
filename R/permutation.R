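#' Permute genotype sample labels
#'
#' Shuffles which genotype row belongs to which sample ID, leaving expression
#' untouched.  This breaks every SNP-gene cross-link while preserving the
#' correlation structure among genotype profiles (and, trivially, among
#' expression profiles): per-SNP allele-count histograms and SNP-SNP
#' correlations are identical before and after.
#'
#' @param geno A [genotype_matrix()].
#' @param seed Integer seed fully determining the permutation (ignored when
#'   `perm` is given).
#' @param perm Optional explicit permutation of `seq_along(geno$samples)`
#'   (e.g. the identity, for which downstream counts equal the real-data
#'   counts exactly).
#' @return The permuted [genotype_matrix()].
#' @export
permute_samples <- function(geno, seed = NULL, perm = NULL) {
  n <- length(geno$samples)
  if (is.null(perm)) {
    if (is.null(seed)) stop("supply either seed or perm", call. = FALSE)
    perm <- withr::with_seed(seed, sample.int(n))
  }
  stopifnot(length(perm) == n, setequal(perm, seq_len(n)))
  geno$counts <- geno$counts[perm, , drop = FALSE]
  rownames(geno$counts) <- geno$samples
  geno
}

#' Run the quartet pipeline on permuted data
#'
#' Executes the full discovery chain (association scan, triplets, quartet
#' assembly and all three filters) on `n_perms` independently permuted copies
#' of the genotype matrix.  Per-run seeds are derived from `master_seed` by a
#' counter, so every run is reproducible in isolation.
#'
#' @param geno,expr Sample-aligned matrices.
#' @param n_perms Number of permutations.
#' @param assoc_threshold,alpha,source_categories Passed to
#'   [discover_quartets()].
#' @param master_seed Master seed; run `i` uses `master_seed + i`.
#' @return Object of class `quartet_null`: list with `runs` (tibble of
#'   per-run counts: `perm_index`, `seed`, `n_assoc_pairs`, `n_triplets`,
#'   `n_quartets`, `n_cooperating`, `n_intermediate`, `n_unique_targets`),
#'   `quartets` (pooled permuted-set quartets tagged with `perm_index`),
#'   `n_perms` and `master_seed`.
#' @export
run_null <- function(geno, expr, n_perms = 100, assoc_threshold = 1e-4,
                     alpha = 0.05, source_categories = c("exon", "tf", "both"),
                     master_seed = 1) {
  stopifnot(n_perms >= 1)
  runs <- vector("list", n_perms)
  pooled <- vector("list", n_perms)
  for (i in seq_len(n_perms)) {
    seed_i <- master_seed + i
    res <- tryCatch(
      discover_quartets(permute_samples(geno, seed = seed_i), expr,
                        assoc_threshold = assoc_threshold, alpha = alpha,
                        source_categories = source_categories),
      error = function(e) stop("permutation run ", i, " failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    runs[[i]] <- tibble::tibble(
      perm_index = i, seed = seed_i,
      !!!as.list(res$counts)
    )
    if (nrow(res$unique) > 0) {
      pooled[[i]] <- dplyr::mutate(res$unique, perm_index = i)
    }
  }
  structure(
    list(runs = dplyr::bind_rows(runs), quartets = dplyr::bind_rows(pooled),
         n_perms = n_perms, master_seed = master_seed),
    class = "quartet_null"
  )
}

#' @export
print.quartet_null <- function(x, ...) {
  cat(sprintf(
    "<quartet_null> %d permutations (master seed %s)\n", x$n_perms,
    format(x$master_seed)
  ))
  cat(sprintf(
    "  unique-target quartets: mean %.2f (pooled permuted set of %d)\n",
    mean(x$runs$n_unique_targets), nrow(x$quartets)
  ))
  invisible(x)
}

#' Empirical significance and FDR of a discovery count
#'
#' Compares a real-data count to its permutation distribution.  The primary
#' empirical p-value uses the add-one convention
#' `(1 + #\{perm >= real\}) / (1 + n_perms)` (never exactly zero at finite
#' permutations); the raw proportion is also reported.  The empirical FDR is
#' the mean permuted count divided by the real count, capped at 1; it is the
#' expected fraction of the reported discoveries that would arise under the
#' sample-permutation null.
#'
#' @param real_count Non-negative count observed in real data.
#' @param perm_counts Non-negative per-permutation counts.
#' @return One-row tibble: `real_count`, `n_perms`, `perm_mean`,
#'   `empirical_p` (add-one), `empirical_p_raw`, `empirical_fdr` (`NA` when
#'   `real_count` is 0).
#' @export
empirical_stats <- function(real_count, perm_counts) {
  if (length(perm_counts) == 0) stop("perm_counts is empty", call. = FALSE)
  if (real_count < 0 || any(perm_counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- length(perm_counts)
  ge <- sum(perm_counts >= real_count)
  tibble::tibble(
    real_count = real_count,
    n_perms = n,
    perm_mean = mean(perm_counts),
    empirical_p = (1 + ge) / (1 + n),
    empirical_p_raw = ge / n,
    empirical_fdr = if (real_count == 0) NA_real_ else
      min(1, mean(perm_counts) / real_count)
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.quartet_null <- function(x, ...) x$runs

#' @export
glance.quartet_null <- function(x, ...) {
  tibble::tibble(
    n_perms = x$n_perms,
    master_seed = x$master_seed,
    mean_assoc_pairs = mean(x$runs$n_assoc_pairs),
    mean_triplets = mean(x$runs$n_triplets),
    mean_quartets = mean(x$runs$n_quartets),
    mean_cooperating = mean(x$runs$n_cooperating),
    mean_unique_targets = mean(x$runs$n_unique_targets),
    pooled_set_size = nrow(x$quartets)
  )
}

#' Histogram of permutation counts with the real-data count marked
#'
#' The classic permutation-null figure: distribution of a per-permutation
#' count with a vertical line at the observed real-data value.
#'
#' @param object A `quartet_null` object.
#' @param real_count Optional real-data count to mark.
#' @param stat Which per-run count to plot.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.quartet_null <- function(object, real_count = NULL,
                                  stat = "n_unique_targets", ...) {
  stopifnot(stat %in% names(object$runs))
  p <- ggplot2::ggplot(object$runs,
                       ggplot2::aes(x = .data[[stat]])) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "grey30") +
    ggplot2::labs(
      x = sprintf("%s per permutation", stat),
      y = "permutations",
      title = sprintf("Permutation null of %s (%d permutations)", stat,
                      object$n_perms)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(real_count)) {
    p <- p + ggplot2::geom_vline(xintercept = real_count, colour = "red",
                                 linewidth = 1)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
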