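# ggplot2 views of the result objects.

#' @describeIn score_modules Enrichment overview: modules ranked by
#'   `-log10` p-value, colored by FDR significance.
#' @param object An `msea_result` (or `kda_result`).
#' @param fdr_threshold Significance line. Default 0.05.
#' @exportS3Method ggplot2::autoplot
autoplot.msea_result <- function(object, fdr_threshold = 0.05, ...) {
  df <- object$results |>
    mutate(set_id = stats::reorder(.data$set_id, -.data$p_value),
           significant = .data$fdr < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_id, y = -log10(.data$p_value),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#2166ac"),
                               name = sprintf("FDR < %.2g", fdr_threshold)) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "enrichment p-value"),
                  title = "Gene-set enrichment for GWAS signal") +
    ggplot2::theme_minimal()
}

#' @describeIn score_key_drivers Candidate overview: overlap z-score
#'   against hub degree, significant drivers highlighted.
#' @param object A `kda_result`.
#' @param fdr_threshold Significance threshold. Default 0.05.
#' @exportS3Method ggplot2::autoplot
autoplot.kda_result <- function(object, fdr_threshold = 0.05, ...) {
  df <- object$results |> mutate(significant = .data$fdr < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$z_score,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "#b2182b"),
                                name = sprintf("FDR < %.2g", fdr_threshold)) +
    ggplot2::labs(x = "hub degree (in + out)",
                  y = "disease-overlap z-score",
                  title = "Key-driver candidates") +
    ggplot2::theme_minimal()
}

#' Plot normalized variant counts across networks
#'
#' Side-by-side normalized rare- and common-variant gene counts per
#' network, as produced by [summarize_network_variants()] over several
#' networks.
#'
#' @param summaries Tibble of per-network summaries (rows from
#'   [summarize_network_variants()]).
#' @return A ggplot object.
#' @export
plot_variant_summary <- function(summaries) {
  check_columns(summaries, c("network", "rare_normalized", "common_normalized"),
                "variant summaries")
  df <- summaries |>
    tidyr::pivot_longer(c("rare_normalized", "common_normalized"),
                        names_to = "variant_type", values_to = "normalized") |>
    mutate(variant_type = sub("_normalized", "", .data$variant_type))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network, y = .data$normalized,
                                   fill = .data$variant_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(common = "#4393c3", rare = "#d6604d"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "variant genes / network genes",
                  title = "Normalized variant counts per network") +
    ggplot2::theme_minimal()
}

#' Plot ranked subnetwork variant enrichment
#'
#' Horizontal bars of `-log10` enrichment p-values for the top key-driver
#' subnetworks, annotated with fold enrichment.
#'
#' @param ranked Output of [rank_subnetworks()].
#' @param top_n Number of subnetworks to show. Default 15.
#' @return A ggplot object.
#' @export
plot_subnetwork_ranking <- function(ranked, top_n = 15) {
  check_columns(ranked, c("kd_gene", "neg_log10_p", "fold_enrichment"),
                "ranked subnetworks")
  df <- head(ranked, top_n) |>
    mutate(kd_gene = stats::reorder(.data$kd_gene, .data$neg_log10_p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kd_gene, y = .data$neg_log10_p)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$fold_enrichment)),
                       hjust = -0.15, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "overlap p-value"),
                  title = "Key-driver subnetworks ranked by variant enrichment") +
    ggplot2::theme_minimal()
}
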