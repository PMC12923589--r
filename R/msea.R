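# Marker-set enrichment analysis (MSEA).
#
# Tests whether the LD-independent markers mapped to a gene set carry
# stronger GWAS association scores than size-matched random gene sets. The
# test statistic is a chi-like sum over quantile thresholds:
#
#   chi = sum_i (O_i - E_i) / (sqrt(E_i) + kappa)
#
# where at quantile level q_i (threshold t_i = empirical q_i-quantile of the
# background scores) O_i is the number of module markers scoring above t_i,
# E_i = m * (1 - q_i) is the count expected if module markers were
# exchangeable with the background, and kappa stabilises terms with very
# small expected counts. Summing over a ladder of quantiles makes the
# statistic insensitive to any single significance cutoff.

#' Build the quantile scheme for the chi statistic
#'
#' The ladder spans `n` equally spaced levels from 0.5 up to
#' `q_upper = 1 - 1/mu`, where `mu` is the median gene-set size of the
#' collection under test, so larger typical modules probe deeper into the
#' upper tail. When `mu <= 2` the upper limit collapses onto 0.5 and the
#' scheme degenerates to the single median threshold (with a warning).
#'
#' @param module_sizes Integer vector of gene-set sizes (all >= 1).
#' @param n Number of quantile levels. Default 10.
#' @param kappa Stability constant added to `sqrt(E_i)` in each term.
#'   Default 1.
#' @param mu Override for the median module size; default
#'   `median(module_sizes)` (mean of the middle two for even counts).
#' @return Object of class `quantile_scheme`: list with `n`, `q_levels`,
#'   `mu`, `q_upper`, `kappa`.
#' @export
build_quantile_scheme <- function(module_sizes, n = 10, kappa = 1, mu = NULL) {
  if (length(n) != 1 || n < 1) abort("n must be a positive integer")
  stopifnot(length(module_sizes) >= 1, all(module_sizes >= 1), kappa >= 0)
  mu <- mu %||% median(module_sizes)
  q_upper <- max(0.5, 1 - 1 / mu)
  if (q_upper == 0.5) {
    warn("median module size <= 2: quantile scheme degenerates to the single level 0.5")
    q_levels <- 0.5
  } else {
    q_levels <- seq(0.5, q_upper, length.out = n)
  }
  structure(
    list(n = length(q_levels), q_levels = q_levels, mu = mu,
         q_upper = q_upper, kappa = kappa),
    class = "quantile_scheme"
  )
}

#' @export
print.quantile_scheme <- function(x, ...) {
  cat(sprintf("<quantile_scheme: %d level(s) in [%.3f, %.3f], mu = %g, kappa = %g>\n",
              x$n, x$q_levels[1], x$q_upper, x$mu, x$kappa))
  invisible(x)
}

# fast inner kernel shared by observed and permuted chi: counts of module
# scores strictly above each threshold vs expectation m * (1 - q)
chi_from_scores <- function(scores, thresholds, q_levels, kappa) {
  m <- length(scores)
  obs <- vapply(thresholds, function(t) sum(scores > t), numeric(1))
  expd <- m * (1 - q_levels)
  terms <- (obs - expd) / (sqrt(expd) + kappa)
  list(observed = obs, expected = expd, term = terms, chi = sum(terms))
}

#' Compute the chi-like enrichment statistic for one marker set
#'
#' @param module_markers Character vector of marker IDs belonging to the
#'   gene set (must be a subset of the background).
#' @param background Marker table restricted to the tissue background
#'   (columns `marker_id`, `score`): all markers mapped to at least one
#'   gene after LD filtering.
#' @param scheme A [build_quantile_scheme()] object.
#' @param thresholds Optional pre-computed score thresholds (one per
#'   quantile level), e.g. to hold the background fixed across repeated
#'   calls. Default: empirical quantiles of the background scores under the
#'   package convention ([empirical_quantile()]).
#' @return Object of class `chi_breakdown`: list with `quantiles` (tibble
#'   `q`, `threshold`, `observed`, `expected`, `term`) and `chi` (the sum of
#'   the terms). A marker counts as a positive association at a level only
#'   when its score is strictly above the threshold; ties do not count.
#' @export
compute_chi <- function(module_markers, background, scheme, thresholds = NULL) {
  background <- as_marker_table(background, "background")
  module_markers <- unique(as.character(module_markers))
  if (length(module_markers) == 0) abort("module has no markers")
  missing <- setdiff(module_markers, background$marker_id)
  if (length(missing) > 0) {
    abort(sprintf("%d module marker(s) absent from background (e.g. %s)",
                  length(missing), paste(head(missing, 3), collapse = ", ")))
  }
  stopifnot(inherits(scheme, "quantile_scheme"))
  thresholds <- thresholds %||% empirical_quantile(background$score, scheme$q_levels)
  stopifnot(length(thresholds) == scheme$n)
  scores <- background$score[match(module_markers, background$marker_id)]
  k <- chi_from_scores(scores, thresholds, scheme$q_levels, scheme$kappa)
  structure(
    list(
      quantiles = tibble(q = scheme$q_levels, threshold = thresholds,
                         observed = k$observed, expected = k$expected,
                         term = k$term),
      chi = k$chi,
      n_markers = length(scores)
    ),
    class = "chi_breakdown"
  )
}

#' @export
print.chi_breakdown <- function(x, ...) {
  cat(sprintf("<chi_breakdown: chi = %.4f over %d level(s), %d markers>\n",
              x$chi, nrow(x$quantiles), x$n_markers))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chi_breakdown <- function(x, ...) x$quantiles

# internal: precompute the lookup structures used by the permutation null
msea_context <- function(assignment, background, scheme) {
  stopifnot(inherits(assignment, "gene_marker_assignment"))
  background <- as_marker_table(background, "background")
  missing <- setdiff(assignment$background, background$marker_id)
  if (length(missing) > 0) {
    abort("assignment background contains markers absent from the score table")
  }
  list(
    genes = sort(unique(assignment$assignment$gene_id)),
    markers_by_gene = split(assignment$assignment$marker_id,
                            assignment$assignment$gene_id),
    score_of = setNames(background$score, background$marker_id),
    thresholds = empirical_quantile(background$score, scheme$q_levels)
  )
}

# internal: chi for one random draw of n_genes genes
null_chi_draw <- function(ctx, n_genes, scheme) {
  g <- sample(ctx$genes, n_genes)
  mk <- unique(unlist(ctx$markers_by_gene[g], use.names = FALSE))
  chi_from_scores(ctx$score_of[mk], ctx$thresholds, scheme$q_levels, scheme$kappa)$chi
}

#' Permutation null distribution of the chi statistic
#'
#' Implements the null hypothesis that the distinct markers of a set of N
#' genes carry the same proportion of positive associations as the distinct
#' markers of N random genes: each draw samples `n_genes` genes uniformly
#' without replacement from the tissue's gene universe, pools their
#' distinct markers and computes chi against the fixed background
#' thresholds.
#'
#' @param n_genes Number of genes per random set (matched to the tested
#'   module).
#' @param assignment A [map_markers_to_genes()] result.
#' @param background Tissue background marker table (`marker_id`, `score`).
#' @param scheme A [build_quantile_scheme()] object.
#' @param n_perm Number of permutations (minimum 100). Default 2000.
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @return Numeric vector of `n_perm` null chi values.
#' @export
null_chi_distribution <- function(n_genes, assignment, background, scheme,
                                  n_perm = 2000, seed = 1) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  ctx <- msea_context(assignment, background, scheme)
  if (n_genes > length(ctx$genes)) {
    abort(sprintf("gene universe (%d) smaller than requested set size (%d)",
                  length(ctx$genes), n_genes))
  }
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) null_chi_draw(ctx, n_genes, scheme),
           numeric(1))
  })
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Validating wrapper around the standard step-up adjustment
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p_values, method = "BH")
}

#' Score gene-set enrichment for GWAS signal across a collection
#'
#' For each gene set: intersects its genes with the tissue gene universe,
#' pools the distinct markers of the surviving genes, computes the observed
#' chi, and compares it to a size-matched permutation null
#' ([null_chi_distribution()]). Null draws are shared across modules with
#' the same intersected gene count, generated once per distinct size under
#' a single seeded stream. Z-scores use the sample (n-1) standard deviation
#' of the null; p-values are one-sided upper-tail Gaussian; FDR is
#' Benjamini-Hochberg across all modules scored in the call.
#'
#' @param collection Gene sets in long form: columns `set_id`, `gene_id`
#'   (optional `tissue`).
#' @param assignment A [map_markers_to_genes()] result for the tissue.
#' @param background Tissue background marker table (`marker_id`, `score`).
#' @param scheme Optional [build_quantile_scheme()]; default built from the
#'   intersected sizes of the scored modules with `n_quantiles` levels and
#'   `kappa`.
#' @param n_perm Permutations per null (minimum 100). Default 2000.
#' @param seed Integer seed for the permutation stream.
#' @param min_genes Gene sets with fewer intersected genes are skipped with
#'   a warning. Default 5.
#' @param n_quantiles,kappa Passed to [build_quantile_scheme()] when
#'   `scheme` is `NULL`.
#' @return Object of class `msea_result`. `tidy()` returns the per-module
#'   table (`set_id`, `tissue`, `n_genes`, `n_markers`, `chi_observed`,
#'   `null_mean`, `null_sd`, `z_score`, `p_value`, `fdr`, `n_permutations`,
#'   `flagged`), sorted by p-value; `glance()` a one-row summary. Modules
#'   whose null has zero spread are flagged with `p_value = 1` and `z_score
#'   = NA`.
#' @export
score_modules <- function(collection, assignment, background, scheme = NULL,
                          n_perm = 2000, seed = 1, min_genes = 5,
                          n_quantiles = 10, kappa = 1) {
  check_columns(collection, c("set_id", "gene_id"), "gene-set collection")
  stopifnot(inherits(assignment, "gene_marker_assignment"))
  if (n_perm < 100) abort("n_perm must be at least 100")
  tissue <- assignment$tissue

  universe <- unique(assignment$assignment$gene_id)
  sets <- collection |>
    filter(.data$gene_id %in% !!universe) |>
    distinct(.data$set_id, .data$gene_id)
  sizes <- sets |> count(.data$set_id, name = "n_genes")
  small <- sizes |> filter(.data$n_genes < min_genes)
  all_ids <- unique(collection$set_id)
  skipped <- union(setdiff(all_ids, sizes$set_id), small$set_id)
  if (length(skipped) > 0) {
    warn(sprintf("%d gene set(s) skipped with fewer than %d genes in the tissue universe",
                 length(skipped), min_genes))
  }
  scored <- sizes |> filter(.data$n_genes >= min_genes)
  if (nrow(scored) == 0) abort("no gene set passes the size floor in this tissue")

  scheme <- scheme %||% build_quantile_scheme(scored$n_genes, n = n_quantiles, kappa = kappa)
  ctx <- msea_context(assignment, background, scheme)

  genes_by_set <- split(sets$gene_id, sets$set_id)[scored$set_id]
  obs_chi <- vapply(genes_by_set, function(g) {
    mk <- unique(unlist(ctx$markers_by_gene[g], use.names = FALSE))
    chi_from_scores(ctx$score_of[mk], ctx$thresholds, scheme$q_levels, scheme$kappa)$chi
  }, numeric(1))
  n_markers <- vapply(genes_by_set, function(g) {
    length(unique(unlist(ctx$markers_by_gene[g], use.names = FALSE)))
  }, integer(1))

  # one null per distinct module size, generated in ascending size order
  # under a single seeded stream so results do not depend on module order
  uniq_sizes <- sort(unique(scored$n_genes))
  null_stats <- withr::with_seed(seed, {
    lapply(uniq_sizes, function(s) {
      draws <- vapply(seq_len(n_perm), function(i) null_chi_draw(ctx, s, scheme),
                      numeric(1))
      c(mean = mean(draws), sd = sd(draws))
    })
  })
  names(null_stats) <- as.character(uniq_sizes)

  null_mean <- vapply(as.character(scored$n_genes), function(s) null_stats[[s]][["mean"]], numeric(1))
  null_sd <- vapply(as.character(scored$n_genes), function(s) null_stats[[s]][["sd"]], numeric(1))
  flagged <- null_sd == 0
  z <- ifelse(flagged, NA_real_, (obs_chi - null_mean) / null_sd)
  p <- ifelse(flagged, 1, pnorm(z, lower.tail = FALSE))
  if (any(flagged)) {
    inform(sprintf("%d module(s) had a zero-spread null; z undefined, p set to 1",
                   sum(flagged)))
  }

  results <- tibble(
    set_id = scored$set_id,
    tissue = tissue,
    n_genes = scored$n_genes,
    n_markers = n_markers,
    chi_observed = unname(obs_chi),
    null_mean = null_mean,
    null_sd = null_sd,
    z_score = z,
    p_value = p,
    fdr = benjamini_hochberg(p),
    n_permutations = n_perm,
    flagged = flagged
  ) |>
    arrange(.data$p_value, .data$set_id)

  structure(
    list(results = results, scheme = scheme, skipped = skipped,
         params = list(n_perm = n_perm, seed = seed, min_genes = min_genes)),
    class = "msea_result"
  )
}

#' @export
print.msea_result <- function(x, ...) {
  cat(sprintf("<msea_result: %d module(s) scored, %d at FDR < 0.05, %d skipped>\n",
              nrow(x$results), sum(x$results$fdr < 0.05), length(x$skipped)))
  print(head(x$results, 5))
  invisible(x)
}

#' @rdname score_modules
#' @param x An `msea_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.msea_result <- function(x, ...) x$results

#' @rdname score_modules
#' @exportS3Method generics::glance
glance.msea_result <- function(x, ...) {
  tibble(
    n_modules = nrow(x$results),
    n_significant = sum(x$results$fdr < 0.05),
    n_skipped = length(x$skipped),
    mu = x$scheme$mu,
    q_upper = x$scheme$q_upper,
    kappa = x$scheme$kappa,
    n_permutations = x$params$n_perm,
    seed = x$params$seed
  )
}
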