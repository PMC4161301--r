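#' Pipeline configuration
#'
#' Bundles every tunable of the quartet-discovery pipeline.  Defaults follow
#' the method's standard operating point: association threshold `1e-4`,
#' nominal conditional/filter significance `0.05`, `100` sample permutations,
#' sources restricted to exon/TF SNPs.
#'
#' @param assoc_threshold Association-pair retention threshold in (0, 1).
#' @param nominal_alpha Nominal significance for conditional tests and the
#'   quartet filters.
#' @param n_perms Number of sample permutations (0 skips the null stage).
#' @param master_seed Master seed for all randomness.
#' @param source_categories SNP categories eligible as sources.
#' @param match_threshold When permutations are run, re-select the real-data
#'   triplets so their count matches the permutation mean (equal starting
#'   point for real vs permuted) before quartet assembly.
#' @return A `quartet_config` list.
#' @export
quartet_config <- function(assoc_threshold = 1e-4, nominal_alpha = 0.05,
                           n_perms = 100, master_seed = 1,
                           source_categories = c("exon", "tf", "both"),
                           match_threshold = TRUE) {
  stopifnot(assoc_threshold > 0, assoc_threshold < 1,
            nominal_alpha > 0, nominal_alpha < 1, n_perms >= 0)
  structure(
    list(assoc_threshold = assoc_threshold, nominal_alpha = nominal_alpha,
         n_perms = as.integer(n_perms), master_seed = master_seed,
         source_categories = source_categories,
         match_threshold = isTRUE(match_threshold)),
    class = "quartet_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Any subset of the [quartet_config()] fields may appear in the file;
#' missing fields take their defaults.
#'
#' @param path YAML file path.
#' @return A `quartet_config`.
#' @export
quartet_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(quartet_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(quartet_config, vals)
}

#' Run the full quartet-discovery pipeline
#'
#' Orchestrates sample intersection, the association scan, triplet
#' construction, quartet assembly and filtering, the optional
#' sample-permutation null with empirical significance/FDR, and quartet
#' characterization.  When permutations are run and
#' `config$match_threshold` is `TRUE`, real-data triplets are re-selected
#' (ranked by worse marginal p) so their count matches the permutation mean
#' before quartets are assembled — the equal-starting-point calibration.
#'
#' @param geno A [genotype_matrix()].
#' @param expr An [expression_matrix()].
#' @param config A [quartet_config()].
#' @param output_dir Optional directory; when given, per-stage TSVs and a
#'   JSON manifest are written.
#' @return Object of class `quartet_analysis`: list with `assoc`, `triplets`
#'   (the analysed, possibly threshold-matched set), `triplets_base` (at the
#'   base threshold), `quartets` (final characterized unique-target set),
#'   `stages` (all intermediate tibbles), `null` (`quartet_null` or `NULL`),
#'   `stats` (empirical significance of the final count), `manifest`.
#' @export
run_pipeline <- function(geno, expr, config = quartet_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "quartet_config"))
  shared <- intersect_samples(geno, expr)
  geno <- shared$geno
  expr <- shared$expr

  null <- NULL
  if (config$n_perms > 0) {
    null <- run_null(geno, expr, n_perms = config$n_perms,
                     assoc_threshold = config$assoc_threshold,
                     alpha = config$nominal_alpha,
                     source_categories = config$source_categories,
                     master_seed = config$master_seed)
  }

  assoc <- associate_all(geno, expr, p_threshold = config$assoc_threshold,
                         source_categories = config$source_categories)
  triplets_base <- build_triplets(assoc, geno, expr,
                                  alpha = config$nominal_alpha)
  matched_cutoff <- NA_real_
  triplets <- triplets_base
  if (!is.null(null) && config$match_threshold) {
    matched_cutoff <- match_threshold(triplets_base, null$runs$n_triplets,
                                      base_threshold = config$assoc_threshold)
    triplets <- dplyr::filter(
      triplets_base, pmax(.data$p1, .data$p2) <= matched_cutoff)
  }
  quartets_all <- assemble_quartets(triplets)
  coop <- filter_cooperating(quartets_all, geno, expr,
                             alpha = config$nominal_alpha)
  inter <- filter_intermediate(coop, triplets, geno, expr,
                               alpha = config$nominal_alpha)
  uniq <- filter_unique_targets(inter)
  quartets <- characterize_quartets(uniq, assoc, geno, expr)

  stats <- NULL
  if (!is.null(null)) {
    stats <- empirical_stats(nrow(uniq), null$runs$n_unique_targets)
  }

  counts <- c(
    n_samples = length(geno$samples), n_snps = nrow(geno$snps),
    n_genes = nrow(expr$genes),
    n_assoc_pairs = nrow(assoc), n_triplets_base = nrow(triplets_base),
    n_triplets = nrow(triplets), n_quartets = nrow(quartets_all),
    n_cooperating = nrow(coop), n_intermediate = nrow(inter),
    n_unique_targets = nrow(uniq)
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("bifanr")),
    config = unclass(config),
    matched_cutoff = matched_cutoff,
    counts = as.list(counts),
    hash = rlang::hash(list(unclass(config), counts))
  )

  out <- structure(
    list(assoc = assoc, triplets = triplets, triplets_base = triplets_base,
         quartets = quartets,
         stages = list(quartets_all = quartets_all, cooperating = coop,
                       intermediate = inter, unique = uniq),
         null = null, stats = stats, manifest = manifest,
         geno = geno, expr = expr),
    class = "quartet_analysis"
  )
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

write_pipeline_outputs <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(x$assoc, file.path(dir, "associations.tsv"))
  readr::write_tsv(x$triplets, file.path(dir, "triplets.tsv"))
  readr::write_tsv(x$quartets, file.path(dir, "quartets.tsv"))
  if (!is.null(x$null)) {
    readr::write_tsv(x$null$runs, file.path(dir, "permutation_summary.tsv"))
    readr::write_tsv(x$null$quartets, file.path(dir, "permuted_quartets.tsv"))
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.quartet_analysis <- function(x, ...) {
  cn <- x$manifest$counts
  cat("<quartet_analysis>\n")
  cat(sprintf("  %d samples, %d SNPs, %d genes\n", cn$n_samples, cn$n_snps,
              cn$n_genes))
  cat(sprintf(
    "  funnel: %d assoc pairs -> %d triplets -> %d quartets -> %d cooperating -> %d (intermediate) -> %d unique-target\n",
    cn$n_assoc_pairs, cn$n_triplets, cn$n_quartets, cn$n_cooperating,
    cn$n_intermediate, cn$n_unique_targets))
  if (!is.null(x$stats)) {
    cat(sprintf(
      "  permutation null (%d perms): mean %.2f unique-target quartets; empirical p = %.3f, empirical FDR = %s\n",
      x$null$n_perms, x$stats$perm_mean, x$stats$empirical_p,
      ifelse(is.na(x$stats$empirical_fdr), "n/a",
             sprintf("%.3f", x$stats$empirical_fdr))))
  }
  invisible(x)
}

#' @export
tidy.quartet_analysis <- function(x, ...) x$quartets

#' @export
glance.quartet_analysis <- function(x, ...) {
  out <- tibble::as_tibble(x$manifest$counts)
  out$matched_cutoff <- x$manifest$matched_cutoff
  if (!is.null(x$stats)) {
    out$perm_mean <- x$stats$perm_mean
    out$empirical_p <- x$stats$empirical_p
    out$empirical_fdr <- x$stats$empirical_fdr
  }
  out
}

#' @export
autoplot.quartet_analysis <- function(object, ...) {
  if (!is.null(object$null)) {
    return(autoplot(object$null,
                    real_count = object$manifest$counts$n_unique_targets, ...))
  }
  cn <- object$manifest$counts
  funnel <- tibble::tibble(
    stage = factor(
      c("association pairs", "triplets", "quartets", "cooperating",
        "no intermediate", "unique targets"),
      levels = c("association pairs", "triplets", "quartets", "cooperating",
                 "no intermediate", "unique targets")
    ),
    count = c(cn$n_assoc_pairs, cn$n_triplets, cn$n_quartets,
              cn$n_cooperating, cn$n_intermediate, cn$n_unique_targets)
  )
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "count", title = "Quartet discovery funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
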