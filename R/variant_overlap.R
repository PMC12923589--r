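# Rare/common-variant convergence layer: annotate network genes with
# rare-variant confidence levels and common-variant GWAS evidence, test
# subnetworks for overlap enrichment, summarise variant content per
# network, and compare groups of networks.

#' Annotate genes with rare- and common-variant status
#'
#' A gene is a rare-variant gene when it appears in the catalog at one of
#' the selected confidence levels; a common-variant gene when its best
#' mapped-marker GWAS score exceeds `common_threshold`. The default
#' threshold corresponds to marker p < 0.05 before multiple-testing
#' correction; it is a reporting convention, not a significance claim, and
#' is echoed in the output attribute `"common_threshold"`.
#'
#' @param genes Character vector of genes to annotate.
#' @param rare Rare-variant catalog (`gene_id`, `level`), or `NULL`.
#' @param common_scores Per-gene GWAS evidence (`gene_id`, `score` = best
#'   mapped-marker `-log10` p), or `NULL`.
#' @param levels Which catalog levels count as rare. Default all four.
#' @param common_threshold Score cutoff for common-variant status. Default
#'   `-log10(0.05)`.
#' @return Tibble `gene_id`, `rare_level`, `is_rare`, `is_common`,
#'   `category` (`"both"`, `"rare"`, `"common"`, `"neither"`), `label`
#'   (e.g. `"rare(1)"`, `"both(syndromic)"`).
#' @export
annotate_genes <- function(genes, rare = NULL, common_scores = NULL,
                           levels = c("1", "2", "3", "syndromic"),
                           common_threshold = -log10(0.05)) {
  genes <- unique(as.character(genes))
  levels <- match.arg(levels, several.ok = TRUE)
  rare_level <- rep(NA_character_, length(genes))
  if (!is.null(rare)) {
    check_columns(rare, c("gene_id", "level"), "rare-variant catalog")
    keep <- rare[rare$level %in% levels, ]
    rare_level <- as.character(keep$level[match(genes, keep$gene_id)])
  }
  is_common <- rep(FALSE, length(genes))
  if (!is.null(common_scores)) {
    check_columns(common_scores, c("gene_id", "score"), "common-variant scores")
    sc <- common_scores$score[match(genes, common_scores$gene_id)]
    is_common <- !is.na(sc) & sc > common_threshold
  }
  is_rare <- !is.na(rare_level)
  category <- dplyr::case_when(
    is_rare & is_common ~ "both",
    is_rare ~ "rare",
    is_common ~ "common",
    .default = "neither"
  )
  label <- ifelse(is_rare, sprintf("%s(%s)", category, rare_level), category)
  out <- tibble(gene_id = genes, rare_level = rare_level,
                is_rare = is_rare, is_common = is_common,
                category = category, label = label)
  attr(out, "common_threshold") <- common_threshold
  out
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a subnetwork of
#' `n` genes and `K` annotated genes in a background of `N` genes:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This equals the
#' one-sided Fisher exact test on the corresponding 2x2 table. Fold
#' enrichment is `(k/n) / (K/N)`, reported as `NA` when `K` or `n` is zero.
#'
#' @param k Observed overlap count.
#' @param K Annotated genes in the background.
#' @param n Subnetwork (query set) size.
#' @param N Background size.
#' @return One-row tibble of class `overlap_test`: `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p_value`.
#' @export
hypergeometric_enrichment <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N || k > min(K, n) || k < 0 || K < 0 || n < 0 || N < 0) {
    abort(sprintf("inconsistent margins: k=%s K=%s n=%s N=%s (need 0 <= k <= min(K, n) <= N)",
                  k, K, n, N))
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K == 0 || n == 0) NA_real_ else (k / n) / (K / N)
  structure(
    tibble(k = as.integer(k), K = as.integer(K), n = as.integer(n),
           N = as.integer(N), fold_enrichment = fold, p_value = p),
    class = c("overlap_test", "tbl_df", "tbl", "data.frame")
  )
}

#' Summarise the variant content of a network
#'
#' Raw and normalized counts of rare-variant and common-variant genes among
#' the network's node universe; normalized counts divide by the total
#' number of network genes, making networks of different sizes comparable.
#'
#' @param net A [directed_network()] or edge table.
#' @param rare Rare-variant catalog (`gene_id`, `level`), or `NULL`.
#' @param common_scores Per-gene GWAS evidence (`gene_id`, `score`), or
#'   `NULL`.
#' @param common_threshold Passed to [annotate_genes()].
#' @param label Optional network label column.
#' @return One-row tibble: `network`, `n_genes`, `n_rare`, `n_common`,
#'   `rare_normalized`, `common_normalized`.
#' @export
summarize_network_variants <- function(net, rare = NULL, common_scores = NULL,
                                       common_threshold = -log10(0.05),
                                       label = NA_character_) {
  net <- as_directed_network(net)
  if (length(net$nodes) == 0) abort("network has no genes")
  ann <- annotate_genes(net$nodes, rare = rare, common_scores = common_scores,
                        common_threshold = common_threshold)
  tibble(
    network = label,
    n_genes = length(net$nodes),
    n_rare = sum(ann$is_rare),
    n_common = sum(ann$is_common),
    rare_normalized = sum(ann$is_rare) / length(net$nodes),
    common_normalized = sum(ann$is_common) / length(net$nodes)
  )
}

#' Compare two groups of values by rank-sum test
#'
#' Wilcoxon rank-sum comparison of two groups (e.g. per-network normalized
#' variant counts for brain versus peripheral networks), two-sided or
#' one-sided with the first group expected greater. When requested, a
#' Shapiro-Wilk normality p-value per group is reported alongside as the
#' rationale for using a rank test; it does not alter the comparison.
#' With completely tied data the exact method is degenerate; the report
#' notes the fallback and returns p = 1.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @param test `"wilcoxon_two_sided"` or `"wilcoxon_one_sided_greater"`
#'   (alternative: `values_a` greater).
#' @param normality_check Also run Shapiro-Wilk per group. Default `FALSE`.
#' @return One-row tibble: `statistic`, `p_value`, `method`, `alternative`,
#'   `shapiro_p_a`, `shapiro_p_b`, `note`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("wilcoxon_two_sided", "wilcoxon_one_sided_greater"),
                           normality_check = FALSE) {
  test <- match.arg(test)
  stopifnot(length(values_a) >= 3, length(values_b) >= 3)
  alternative <- if (test == "wilcoxon_two_sided") "two.sided" else "greater"
  note <- NA_character_
  if (length(unique(c(values_a, values_b))) == 1) {
    note <- "all values tied; exact rank-sum degenerate, p = 1"
    inform(note)
    stat <- length(values_a) * length(values_b) / 2
    p <- 1
  } else {
    wt <- suppressWarnings(wilcox.test(values_a, values_b, alternative = alternative))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  sh_a <- sh_b <- NA_real_
  if (normality_check) {
    sh_a <- tryCatch(shapiro.test(values_a)$p.value, error = function(e) NA_real_)
    sh_b <- tryCatch(shapiro.test(values_b)$p.value, error = function(e) NA_real_)
  }
  tibble(statistic = stat, p_value = p, method = "wilcoxon_rank_sum",
         alternative = alternative, shapiro_p_a = sh_a, shapiro_p_b = sh_b,
         note = note)
}

#' Rank key-driver subnetworks by variant enrichment
#'
#' Orders subnetworks by descending `-log10` enrichment p-value, breaking
#' ties by descending fold enrichment and then ascending key-driver gene.
#'
#' @param results A `kda_result` or its tidied tibble (needs `kd_gene`).
#' @param tests Tibble with one enrichment test per key driver: columns
#'   `kd_gene`, `variant_type` (`"rare"` or `"common"`), `p_value`,
#'   `fold_enrichment` (as from [hypergeometric_enrichment()]).
#' @param by Which variant type to rank by. Default `"rare"`.
#' @return Tibble of the selected tests joined to the results, with
#'   `neg_log10_p` and `rank` columns, best-enriched first.
#' @export
rank_subnetworks <- function(results, tests, by = c("rare", "common")) {
  by <- match.arg(by)
  if (inherits(results, "kda_result")) results <- results$results
  check_columns(results, "kd_gene", "key-driver results")
  check_columns(tests, c("kd_gene", "variant_type", "p_value", "fold_enrichment"),
                "enrichment tests")
  sel <- tests |> filter(.data$variant_type == !!by)
  if (anyDuplicated(sel$kd_gene) > 0) abort("one test per key driver is required")
  sel |>
    left_join(select(results, "kd_gene", dplyr::any_of(c("n_subnetwork", "n_overlap"))),
              by = "kd_gene") |>
    mutate(neg_log10_p = -log10(.data$p_value)) |>
    arrange(dplyr::desc(.data$neg_log10_p), dplyr::desc(.data$fold_enrichment),
            .data$kd_gene) |>
    mutate(rank = row_number())
}
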