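---
title: "Discovering cooperating eSNP quartets: model, filters and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cooperating eSNP quartets: model, filters and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifanr)
```

# The problem

Expression-associated SNPs (eSNPs) are usually mapped one SNP and one
transcript at a time. Most expression traits, however, are shaped by several
variants acting on several genes at once, and exhaustively scanning all SNP
pairs against all transcripts is statistically and computationally
prohibitive. bifanr implements a constructive alternative: it grows candidate
*bi-fan* motifs — two source SNPs that jointly regulate the same two target
genes — from well-powered single-SNP associations, and then calibrates how
many such "quartets" would arise by chance with a sample-permutation null.

The pipeline operates on

* a genotype matrix of per-sample minor-allele counts (0/1/2) with per-SNP
  chromosome/position and an annotation category (inside an exon, inside a
  transcription-factor gene span including introns, both, or other);
* an expression matrix of already-normalized per-sample values with per-gene
  spans. Normalization is deliberately out of scope; quantile-normalized
  input is assumed.

Only SNPs in the exon/TF/both categories are eligible as sources: these are
the regions with prior regulatory evidence, and restricting the source
universe keeps the testing burden proportionate to a small cohort.

# Stage by stage

## Marginal association

For SNP $s$ and gene $g$ the additive model is ordinary least squares of
expression on allele count,

$$ g = \beta_0 + \beta_1 s + \varepsilon, $$

with a two-sided p-value from the $t$ distribution on $n-2$ degrees of
freedom. No asymptotic approximation is used because the motivating cohorts
have only ~50 samples. Records with $p < 10^{-4}$ (the `assoc_threshold`
default) are *association pairs*. The sign of $\beta_1$ orients the edge:
up-regulation means more minor-allele copies predict higher expression.

Missing genotypes are dropped pairwise per test. A perfect fit reports the
smallest positive normal double as its p-value and is flagged; a constant
expression vector yields $\beta_1 = 0$, $p = 1$; a constant genotype is a
degenerate predictor and is skipped with a log message.

## Triplets by conditional independence

A SNP associated with two genes forms a candidate triplet. Each association
is re-tested in the joint model

$$ g_i = \beta_0 + \beta_1 s + \beta_2 g_j + \varepsilon, $$

asking whether the SNP stays nominally significant ($p < \alpha$, default
$\alpha = 0.05$, two-sided) given the other gene. Both survive: *mutually
independent*. Exactly one survives: *directionally independent*, the
surviving gene being the directional target (the classic signature of a
mediation chain $s \to g_1 \to g_2$). Neither: the candidate is discarded.
We use the joint-model coefficient test rather than a two-step residual
regression so the finite-sample degrees of freedom ($n-3$) are exact.

## Quartets and the three filters

Two triplets sharing both target genes define a quartet. Three filters are
applied in order; counts are non-increasing along the chain:

1. **Cooperating sources.** Fit $g_i = b_0 + b_1 s_1 + b_2 s_2$ for both
   genes; all four slope coefficients must be significant at $\alpha$. This
   is what "two SNPs carrying independent information" means operationally.
   Sources in perfect LD are not identifiable and fail with a `collinear`
   flag.
2. **No better intermediate SNP.** A third SNP $s_3$ disqualifies a quartet
   when (a) it shares a chromosome with a source (a linkage-mediated
   explanation requires co-localization), (b) it itself forms a triplet with
   the two genes, and (c) for both genes, conditioning on $s_3$ renders the
   co-chromosomal source non-significant while $s_3$ conditioned on that
   source stays significant. This conditional-significance *exchange test*
   is the package's own reconstruction of the intermediate-variant criterion
   — the one place where the method description leaves the exact
   inequalities open — and it is deliberately symmetric in the two genes:
   the tag is removed only when the candidate dominates it on *both*
   targets.
3. **Unique gene targets.** At most one quartet survives per unordered gene
   pair, so no double counting of the same expression signal. The survivor
   minimizes the worst of its four marginal p-values, ties broken
   lexicographically by SNP IDs — a deterministic "keep the best supported
   representative" rule (the original description does not specify the
   representative; merging annotations across duplicates was the
   alternative we rejected as harder to reason about downstream).

## Permutation null and empirical FDR

`run_null()` shuffles which genotype row belongs to which sample ID
(expression untouched), preserving all within-genotype and
within-expression correlation while severing every SNP–gene link, and runs
the full chain per permutation. Permuting the genotype side rather than the
expression side is an arbitrary choice — either breaks the cross-links —
and is fixed here for reproducibility. Per-run seeds derive from a master
seed by a counter.

Two conventions are reported:

* empirical p-value, add-one style: $(1 + \#\{perm \ge real\})/(1 + B)$ —
  primary, never exactly zero at finite $B$; the raw proportion is also
  returned;
* empirical FDR: mean permuted count / real count (capped at 1), the
  expected fraction of reported discoveries that are null.

`match_threshold()` implements the equal-starting-point calibration: rank
real triplets by their *worse* marginal p (the binding constraint that
defines a triplet) and cut so the real count equals the rounded permutation
mean. When the real data has fewer triplets than the null mean, the base
threshold is returned unchanged with a warning.

## Characterization and the sign algebra

Each final quartet gets: its dependency class (mutual/mutual, mixed,
directional/directional), cis/trans class (a source is *cis* to a target iff
it lies inside the target's span — a span rule, not a distance window;
quartets are binned by their count of cis pairs among the four), target
co-expression, same-chromosome flags, and the source annotation-category
pair (exon+exon / exon+tf / tf+tf, with "both"-category SNPs counted as
exon by documented precedence).

The direction-of-effect algebra is exact and fully enumerable: four signed
edges give $2^4 = 16$ configurations; a quartet is *consistent* iff the
number of up edges is even, i.e. the product of the four signs is $+1$ —
exactly 8 of 16. Two binary criteria (do the sources act on gene 2 as they
do on gene 1; does source 2 act on the targets as source 1 does) partition
the consistent half into four categories of two members each; the two
members of a category are global sign flips of each other, flipping one
source's two edges toggles the SNP-axis criterion, and flipping one
target's two edges toggles the gene-axis criterion. Consistency arises
mechanically from correlated (or anti-correlated) targets, which is why
real quartets are expected to be consistent while permuted ones often are
not.

Real-vs-permuted contrasts (annotation bins, dependency classes, shared
annotation terms, GWAS-gene overlap) use two-sided Fisher's exact tests;
co-expression contrasts compare $|r|$ with a rank test, chosen for
robustness since the original analysis names no test. Annotation and GWAS
inputs are plain user-supplied tables — there is no live ontology or
catalog access.

# The synthetic-data generator

`simulate_dataset()` produces datasets with exported ground truth so every
stage has a recoverable target. It emulates precisely the structure the
analysis assumes:

* genotypes: Binomial(2, MAF) minor-allele counts, MAF drawn from
  `maf_range` (default 0.1–0.5; the quality filters require > 0.05);
* LD pairs: allele-level Gaussian copula — threshold a bivariate normal at
  the allele frequencies with a latent correlation solved numerically so
  the realized count correlation hits the target; infeasible targets error
  with the attainable bound;
* expression: Gaussian noise (sd `noise_sd`, default 1) plus planted
  additive effects; bi-fans add $b_{ij} s_i$ into each target, mediation
  chains add the mediator's realized expression downstream; non-planted
  genes are pure noise;
* the default cohort size of 50 mirrors the small fully-sequenced panels
  the method targets; the recovery benchmark (`planted_bifan_config()`)
  raises it to 200 for stability.

What it does **not** emulate — and therefore what passing tests do not
demonstrate about real data: genome-scale LD blocks beyond designated
pairs, population structure, non-Gaussian expression tails, batch effects,
and the sheer multiplicity of a 7-million-SNP scan. The generator validates
the machinery's correctness and calibration, not its behaviour under every
real-data pathology.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally (the VCF convention); BED
  input (0-based half-open) is converted on read. Chromosome names are
  compared after stripping any `chr` prefix.
* The minor allele is cohort-relative and recomputed after sample
  intersection, then the MAF/missingness filters (strict $> 0.05$, strict
  $< 0.1$) are re-applied to a fixed point, so the matrix invariants hold
  for exactly the samples analysed. Whether the original analysis
  intersected samples before computing MAF is unknowable; recomputing is
  the conservative choice and the difference is confined to boundary SNPs.
* Collinearity in two-predictor fits is declared at $r^2 \ge 1 - 10^{-12}$;
  perfect fits report the smallest positive normal double rather than 0.
* All ranking ties (threshold matching, unique-target selection) break
  lexicographically on identifiers, so every output is deterministic.
* ID collisions across input files are hard errors — no silent renaming.

# Problem sizes in the verification suites

The shipped test and acceptance suites exercise: the full $16$-configuration
sign enumeration; $\ge 1000$ random regression instances against
closed-form/normal-equation oracles at $10^{-9}$; pure-noise calibration at
50 samples × 200 SNPs × 100 genes with 50 permutations; planted-motif
recovery with 10 unit-slope bi-fans, 40 noise SNPs and 33 noise genes (>500
null gene pairs) at $n = 200$ over 10 seeds; and the exhaustive
hypergeometric check of Fisher p-values for every 2×2 table with
$N \le 40$. These sizes were chosen to make each property decidable in
seconds to a couple of minutes while keeping the statistical bounds sharp
(binomial 99% bands for retention rates, calibrated binomial bounds for
per-seed stochastic assertions).

# Known limitations

* The intermediate-SNP exchange test is a reconstruction (see above); other
  readings of "explains the expression better" — e.g. model-selection by
  AIC or variance explained — would be defensible and may admit or reject
  borderline tags differently.
* Dataset-scale results from the motivating study (tens of thousands of
  triplets, the 82-quartet operating point) depend on a specific cohort and
  are not reproducible from synthetic data; the package reproduces the
  method's conventions and its analytic/combinatorial claims, and verifies
  the statistical machinery by construction.
* No covariates, population-structure correction or mixed models: the
  underlying association engine is plain OLS by design, matching the
  method it re-implements.
* No imputation, phasing or LD pruning; multiallelic VCF records are
  skipped with a warning.
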