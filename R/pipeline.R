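# End-to-end orchestration: marker dependency filtering -> marker-set
# enrichment -> key-driver analysis -> variant overlap, driven by a single
# reproducible configuration.

#' Build a pipeline run configuration
#'
#' Collects the input paths and every stage parameter with its recorded
#' default. Configurations round-trip losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param gwas_path GWAS summary-statistic file (see [read_gwas_scores()]).
#' @param map_path Marker-to-gene map file.
#' @param modules_path GMT gene-set file.
#' @param network_path Directed network edge list / SIF file.
#' @param out_dir Output directory for result tables and the manifest.
#' @param ld_path Pairwise LD file (`marker_a`, `marker_b`, `r2`) or block
#'   file (`marker_id`, `block_id`); `NULL` skips LD filtering.
#' @param rare_path Rare-variant catalog file, or `NULL`.
#' @param tissues Tissues to analyse. Default `"synthetic"`.
#' @param p_column p-value column in the GWAS file. Default `"p"`.
#' @param r2_threshold LD clumping threshold. Default 0.5.
#' @param sources Mapping sources to use. Default all three.
#' @param n_quantiles,kappa,min_genes Enrichment-statistic parameters (see
#'   [score_modules()]).
#' @param n_perm Permutations for both enrichment and key-driver nulls.
#'   Default 2000.
#' @param seed Master seed; per-tissue stage seeds are derived from it by a
#'   fixed counter scheme, so tissues can be recomputed independently.
#' @param fdr_threshold Modules below this FDR feed the disease gene set
#'   for key-driver analysis. Default 0.05.
#' @param percentile,depth,direction Key-driver parameters (see
#'   [score_key_drivers()]).
#' @param common_threshold Common-variant score cutoff (see
#'   [annotate_genes()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(gwas_path, map_path, modules_path, network_path,
                       out_dir, ld_path = NULL, rare_path = NULL,
                       tissues = "synthetic", p_column = "p",
                       r2_threshold = 0.5,
                       sources = c("eqtl", "sqtl", "distance"),
                       n_quantiles = 10, kappa = 1, min_genes = 5,
                       n_perm = 2000, seed = 1, fdr_threshold = 0.05,
                       percentile = 0.75, depth = 1,
                       direction = c("undirected", "downstream", "upstream"),
                       common_threshold = -log10(0.05)) {
  cfg <- list(
    gwas_path = gwas_path, map_path = map_path, modules_path = modules_path,
    network_path = network_path, out_dir = out_dir, ld_path = ld_path,
    rare_path = rare_path, tissues = tissues, p_column = p_column,
    r2_threshold = r2_threshold, sources = sources,
    n_quantiles = n_quantiles, kappa = kappa, min_genes = min_genes,
    n_perm = n_perm, seed = seed, fdr_threshold = fdr_threshold,
    percentile = percentile, depth = depth,
    direction = match.arg(direction), common_threshold = common_threshold
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[names(cfg) %in% names(formals(run_config))])
}

# read LD in either supported on-disk form
read_ld_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("marker_a", "marker_b", "r2") %in% names(tbl)) ||
      all(c("marker_id", "block_id") %in% names(tbl))) {
    return(tbl)
  }
  abort(sprintf("LD file '%s' must have columns (marker_a, marker_b, r2) or (marker_id, block_id)",
                path))
}

#' Run the full pipeline from a configuration
#'
#' Per tissue: LD-clump the GWAS markers, build the gene-to-marker
#' assignment, score every gene set for enrichment, collect the disease
#' gene set (genes of modules below the FDR threshold), score key drivers
#' on the network, and test each key-driver subnetwork for rare- and
#' common-variant overlap enrichment. All result tables are written
#' tab-delimited under `out_dir` together with a manifest (parameters,
#' derived seeds, row counts, wall-clock). Rerunning the same
#' configuration on the same inputs reproduces every result table
#' byte-for-byte.
#'
#' @param config A [run_config()] or the path to its YAML file.
#' @return Invisibly, a list of class `pipeline_run`: `manifest`, per-tissue
#'   result objects, and output paths. Any stage error aborts with the
#'   stage and tissue named, after writing an `INCOMPLETE` marker file.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  stage <- "load inputs"
  tissue <- NA_character_
  on_fail <- function(e) {
    file.create(file.path(config$out_dir, "INCOMPLETE"))
    abort(sprintf("pipeline failed at stage '%s' (tissue %s): %s",
                  stage, tissue, conditionMessage(e)))
  }

  res <- tryCatch({
    markers <- read_gwas_scores(config$gwas_path, p_column = config$p_column)
    map <- read_marker_gene_map(config$map_path)
    modules <- read_gene_sets_gmt(config$modules_path)
    network <- read_edge_list(config$network_path)
    ld <- if (!is.null(config$ld_path)) read_ld_table(config$ld_path) else NULL
    rare <- if (!is.null(config$rare_path)) read_rare_variant_catalog(config$rare_path) else NULL

    stage <- "ld_clump"
    clumped <- ld_clump(markers, ld, r2_threshold = config$r2_threshold)

    per_tissue <- list()
    paths <- character()
    for (i in seq_along(config$tissues)) {
      tissue <- config$tissues[i]
      msea_seed <- derive_seed(config$seed, 10L * i)
      kda_seed <- derive_seed(config$seed, 10L * i + 1L)

      stage <- "map_markers_to_genes"
      assignment <- map_markers_to_genes(clumped, map, tissue,
                                         sources = config$sources)
      background <- clumped$markers |>
        filter(.data$marker_id %in% assignment$background)

      stage <- "score_modules"
      msea <- score_modules(modules, assignment, background,
                            n_perm = config$n_perm, seed = msea_seed,
                            min_genes = config$min_genes,
                            n_quantiles = config$n_quantiles,
                            kappa = config$kappa)
      msea_path <- file.path(config$out_dir, sprintf("%s_msea.tsv", tissue))
      write_results_table(tidy(msea), msea_path)
      paths <- c(paths, msea_path)

      significant <- msea$results |> filter(.data$fdr < config$fdr_threshold)
      disease_genes <- modules |>
        filter(.data$set_id %in% significant$set_id) |>
        pull("gene_id") |>
        intersect(unique(assignment$assignment$gene_id)) |>
        unique()

      kda <- NULL
      overlap <- NULL
      if (length(intersect(disease_genes, network$nodes)) > 0) {
        stage <- "score_key_drivers"
        kda <- score_key_drivers(network, disease_genes,
                                 depth = config$depth,
                                 direction = config$direction,
                                 n_perm = config$n_perm, seed = kda_seed,
                                 percentile = config$percentile)
        kda_path <- file.path(config$out_dir, sprintf("%s_kda.tsv", tissue))
        write_results_table(tidy(kda), kda_path)
        paths <- c(paths, kda_path)

        stage <- "variant_overlap"
        common_scores <- assignment$assignment |>
          left_join(background, by = "marker_id") |>
          group_by(.data$gene_id) |>
          summarise(score = max(.data$score), .groups = "drop")
        overlap <- subnetwork_overlap_tests(kda, network, rare, common_scores,
                                            common_threshold = config$common_threshold)
        ov_path <- file.path(config$out_dir, sprintf("%s_overlap.tsv", tissue))
        write_results_table(overlap, ov_path)
        paths <- c(paths, ov_path)
      } else {
        inform(sprintf("tissue '%s': no module below FDR %.3g intersects the network; key-driver stage skipped",
                       tissue, config$fdr_threshold))
      }
      per_tissue[[tissue]] <- list(msea = msea, kda = kda, overlap = overlap,
                                   disease_genes = disease_genes,
                                   seeds = c(msea = msea_seed, kda = kda_seed))
    }
    list(per_tissue = per_tissue, paths = paths,
         n_markers_retained = nrow(clumped$markers))
  }, error = on_fail)

  manifest <- list(
    package = as.character(utils::packageVersion("gwasnet")),
    config = unclass(config),
    tissues = lapply(res$per_tissue, function(tt) list(
      seeds = as.list(tt$seeds),
      n_modules_scored = nrow(tt$msea$results),
      n_significant = sum(tt$msea$results$fdr < config$fdr_threshold),
      n_disease_genes = length(tt$disease_genes),
      n_candidates = if (is.null(tt$kda)) 0L else nrow(tt$kda$results)
    )),
    n_markers_retained = res$n_markers_retained,
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  incomplete <- file.path(config$out_dir, "INCOMPLETE")
  if (file.exists(incomplete)) unlink(incomplete)

  out <- list(manifest = manifest, per_tissue = res$per_tissue,
              paths = res$paths)
  class(out) <- "pipeline_run"
  invisible(out)
}

#' Overlap-enrichment tests for every key-driver subnetwork
#'
#' For each scored key driver, tests its subnetwork for enrichment of
#' rare-variant genes and of common-variant genes against the network node
#' universe by the upper-tail hypergeometric test
#' ([hypergeometric_enrichment()]).
#'
#' @param kda A `kda_result`.
#' @param net The scored [directed_network()].
#' @param rare Rare-variant catalog, or `NULL` to skip rare tests.
#' @param common_scores Per-gene best-marker scores, or `NULL` to skip
#'   common tests.
#' @param common_threshold See [annotate_genes()].
#' @param background Optional alternative background gene list (e.g. all
#'   genes in the expression data); default the network node universe.
#' @return Tibble: `kd_gene`, `variant_type`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p_value`.
#' @export
subnetwork_overlap_tests <- function(kda, net, rare = NULL,
                                     common_scores = NULL,
                                     common_threshold = -log10(0.05),
                                     background = NULL) {
  stopifnot(inherits(kda, "kda_result"))
  net <- as_directed_network(net)
  bg <- unique(background %||% net$nodes)
  ann <- annotate_genes(bg, rare = rare, common_scores = common_scores,
                        common_threshold = common_threshold)
  type_sets <- list(
    rare = ann$gene_id[ann$is_rare],
    common = ann$gene_id[ann$is_common]
  )
  if (is.null(rare)) type_sets$rare <- NULL
  if (is.null(common_scores)) type_sets$common <- NULL
  if (length(type_sets) == 0) abort("need a rare catalog and/or common scores to test")

  purrr::map_dfr(names(type_sets), function(vt) {
    genes_vt <- type_sets[[vt]]
    purrr::map2_dfr(kda$results$kd_gene, kda$results$subnetwork, function(kd, sub) {
      sub_bg <- intersect(sub, bg)
      test <- hypergeometric_enrichment(
        k = length(intersect(sub_bg, genes_vt)),
        K = length(genes_vt),
        n = length(sub_bg),
        N = length(bg)
      )
      mutate(test, kd_gene = kd, variant_type = vt, .before = 1)
    })
  })
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d tissue(s), %d output table(s)>\n",
              length(x$per_tissue), length(x$paths)))
  invisible(x)
}
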