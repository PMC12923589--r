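# Key-driver analysis (KDA) on directed gene regulatory networks: hub
# candidate selection, neighborhood extraction, and permutation enrichment
# of candidate subnetworks for a disease gene set.

#' Merge directed networks by edge union
#'
#' Sparse networks from related tissues are merged into a composite network
#' by taking the union of their edge sets (and node universes). Per-source
#' edge counts are attached for provenance.
#'
#' @param ... `directed_network` objects (or edge tables), or a single list
#'   of them.
#' @return A [directed_network()]; attribute `"provenance"` is a tibble of
#'   per-source edge and node counts.
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1 && is.list(nets[[1]]) && !inherits(nets[[1]], "directed_network") &&
      !is.data.frame(nets[[1]])) {
    nets <- nets[[1]]
  }
  if (length(nets) == 0) abort("merge_networks() needs at least one network")
  nets <- lapply(nets, as_directed_network)
  merged <- directed_network(
    bind_rows(lapply(nets, function(n) n$edges)),
    nodes = unlist(lapply(nets, function(n) n$nodes), use.names = FALSE)
  )
  attr(merged, "provenance") <- tibble(
    source = seq_along(nets),
    n_edges = vapply(nets, function(n) nrow(n$edges), integer(1)),
    n_nodes = vapply(nets, function(n) length(n$nodes), integer(1))
  )
  merged
}

# total (in + out) or out-only degree for every node in the universe
node_degrees <- function(net, mode = c("total", "out")) {
  mode <- match.arg(mode)
  g <- as_igraph(net)
  deg <- igraph::degree(g, mode = if (mode == "total") "all" else "out")
  tibble(gene = names(deg), degree = as.integer(deg)) |> arrange(.data$gene)
}

#' Select hub candidates from a directed network
#'
#' Key-driver candidates are the most connected nodes: those whose degree
#' reaches the `percentile` cutoff of the degree distribution over
#' positive-degree nodes (default the top 25% of edge connections).
#' Degree is in-degree plus out-degree by default; the cutoff uses the
#' package-wide empirical quantile convention ([empirical_quantile()]).
#'
#' @param net A [directed_network()] or edge table.
#' @param percentile Degree percentile defining hubs, in (0, 1). Default
#'   0.75.
#' @param mode `"total"` (in + out, default) or `"out"` degree.
#' @return Tibble `gene`, `degree`, `is_candidate`, with the numeric cutoff
#'   in attribute `"cutoff"`.
#' @export
find_hub_candidates <- function(net, percentile = 0.75, mode = c("total", "out")) {
  net <- as_directed_network(net)
  stopifnot(percentile > 0, percentile < 1)
  if (nrow(net$edges) == 0) abort("network has no edges; hub selection undefined")
  deg <- node_degrees(net, mode = match.arg(mode))
  pos <- deg$degree[deg$degree >= 1]
  cutoff <- empirical_quantile(pos, percentile)
  out <- deg |> mutate(is_candidate = .data$degree >= cutoff & .data$degree >= 1)
  attr(out, "cutoff") <- cutoff
  out
}

#' Extract the neighborhood subnetwork of a gene
#'
#' Nodes reachable from `center` within `depth` steps, following edges in
#' both directions (`undirected`, default), only outgoing (`downstream`) or
#' only incoming (`upstream`). The center is always included.
#'
#' @param net A [directed_network()] or edge table.
#' @param center Gene at the neighborhood center; must be a network node.
#' @param depth Maximum number of steps (>= 1). Default 1 (first-degree
#'   neighbors).
#' @param direction Edge-following rule; see above.
#' @return Sorted character vector of member genes.
#' @export
extract_subnetwork <- function(net, center, depth = 1,
                               direction = c("undirected", "downstream", "upstream")) {
  net <- as_directed_network(net)
  direction <- match.arg(direction)
  stopifnot(depth >= 1)
  if (!center %in% net$nodes) abort(sprintf("gene '%s' is not in the network", center))
  g <- as_igraph(net)
  mode <- switch(direction, undirected = "all", downstream = "out", upstream = "in")
  nb <- igraph::ego(g, order = depth, nodes = center, mode = mode)[[1]]
  sort(names(nb))
}

#' Score hub candidates as key drivers of a disease gene set
#'
#' For every hub candidate the statistic is the overlap between its
#' neighborhood subnetwork and the disease gene set. The null reshuffles
#' subnetwork membership: node sets of the same size are drawn uniformly
#' from the network's node universe, and the observed overlap is
#' standardised against the null mean and (sample) standard deviation.
#' P-values are one-sided upper-tail Gaussian, with Benjamini-Hochberg FDR
#' across candidates; results are ranked by p-value, then fold over the
#' null mean, then gene ID. Null draws are shared between candidates whose
#' subnetworks have equal size.
#'
#' A topology-preserving alternative null (`null_method = "neighborhoods"`)
#' draws the neighborhood of a random node and truncates/accepts it at the
#' matched size; the topology-free uniform node set is the default.
#'
#' @param net A [directed_network()] or edge table.
#' @param disease_genes Character vector of disease-associated genes
#'   (e.g. the union of genes in enrichment-significant modules); must
#'   intersect the network nodes.
#' @param candidates Optional [find_hub_candidates()] table; computed at
#'   `percentile` when `NULL`.
#' @param depth,direction Neighborhood rule passed to
#'   [extract_subnetwork()]. Defaults: depth 1, undirected.
#' @param n_perm Number of reshuffled node sets per subnetwork size.
#'   Default 2000.
#' @param seed Integer seed.
#' @param percentile Hub-degree percentile when `candidates` is `NULL`.
#'   Default 0.75.
#' @param null_method `"node_sets"` (default) or `"neighborhoods"`.
#' @return Object of class `kda_result`; `tidy()` gives the candidate table
#'   (`kd_gene`, `degree`, `n_subnetwork`, `subnetwork` list-column,
#'   `n_overlap`, `null_mean`, `null_sd`, `fold`, `z_score`, `p_value`,
#'   `fdr`, `flagged`, `n_permutations`, `depth`, `direction`). Candidates
#'   with a zero-spread null are flagged with `p_value = 1`.
#' @export
score_key_drivers <- function(net, disease_genes, candidates = NULL,
                              depth = 1,
                              direction = c("undirected", "downstream", "upstream"),
                              n_perm = 2000, seed = 1, percentile = 0.75,
                              null_method = c("node_sets", "neighborhoods")) {
  net <- as_directed_network(net)
  direction <- match.arg(direction)
  null_method <- match.arg(null_method)
  disease_genes <- unique(as.character(disease_genes))
  if (length(intersect(disease_genes, net$nodes)) == 0) {
    abort("disease gene set does not intersect the network nodes")
  }
  candidates <- candidates %||% find_hub_candidates(net, percentile = percentile)
  cand <- candidates |> filter(.data$is_candidate) |> arrange(.data$gene)
  if (nrow(cand) == 0) abort("no hub candidates to score")

  g <- as_igraph(net)
  mode <- switch(direction, undirected = "all", downstream = "out", upstream = "in")
  nbhd <- igraph::ego(g, order = depth, nodes = cand$gene, mode = mode)
  subnets <- lapply(nbhd, function(v) sort(names(v)))
  sizes <- lengths(subnets)
  is_disease <- net$nodes %in% disease_genes
  n_nodes <- length(net$nodes)
  obs <- vapply(subnets, function(s) sum(s %in% disease_genes), numeric(1))

  uniq_sizes <- sort(unique(sizes))
  null_stats <- withr::with_seed(seed, {
    res <- lapply(uniq_sizes, function(s) {
      draws <- if (null_method == "node_sets") {
        vapply(seq_len(n_perm), function(i) sum(is_disease[sample.int(n_nodes, s)]),
               numeric(1))
      } else {
        vapply(seq_len(n_perm), function(i) {
          ctr <- net$nodes[sample.int(n_nodes, 1)]
          nb <- names(igraph::ego(g, order = depth, nodes = ctr, mode = mode)[[1]])
          if (length(nb) > s) nb <- c(ctr, sample(setdiff(nb, ctr), s - 1))
          if (length(nb) < s) nb <- union(nb, net$nodes[sample.int(n_nodes, s - length(nb))])
          sum(nb %in% disease_genes)
        }, numeric(1))
      }
      c(mean = mean(draws), sd = sd(draws))
    })
    names(res) <- as.character(uniq_sizes)
    res
  })

  null_mean <- vapply(as.character(sizes), function(s) null_stats[[s]][["mean"]], numeric(1))
  null_sd <- vapply(as.character(sizes), function(s) null_stats[[s]][["sd"]], numeric(1))
  flagged <- null_sd == 0
  z <- ifelse(flagged, NA_real_, (obs - null_mean) / null_sd)
  p <- ifelse(flagged, 1, pnorm(z, lower.tail = FALSE))
  fold <- ifelse(null_mean > 0, obs / null_mean, NA_real_)

  results <- tibble(
    kd_gene = cand$gene,
    degree = cand$degree,
    n_subnetwork = as.integer(sizes),
    subnetwork = subnets,
    n_overlap = as.integer(obs),
    null_mean = unname(null_mean),
    null_sd = unname(null_sd),
    fold = fold,
    z_score = z,
    p_value = p,
    fdr = benjamini_hochberg(p),
    flagged = flagged,
    n_permutations = n_perm,
    depth = depth,
    direction = direction
  ) |>
    arrange(.data$p_value, dplyr::desc(.data$fold), .data$kd_gene)

  structure(
    list(results = results, disease_genes = disease_genes,
         params = list(depth = depth, direction = direction, n_perm = n_perm,
                       seed = seed, percentile = percentile,
                       null_method = null_method)),
    class = "kda_result"
  )
}

#' @export
print.kda_result <- function(x, ...) {
  cat(sprintf("<kda_result: %d candidate(s), %d at FDR < 0.05, disease set of %d gene(s)>\n",
              nrow(x$results), sum(x$results$fdr < 0.05), length(x$disease_genes)))
  print(head(select(x$results, -"subnetwork"), 5))
  invisible(x)
}

#' @rdname score_key_drivers
#' @param x A `kda_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kda_result <- function(x, ...) x$results

#' @rdname score_key_drivers
#' @exportS3Method generics::glance
glance.kda_result <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$results),
    n_significant = sum(x$results$fdr < 0.05),
    n_disease_genes = length(x$disease_genes),
    depth = x$params$depth,
    direction = x$params$direction,
    n_permutations = x$params$n_perm,
    seed = x$params$seed
  )
}

#' Export a key-driver subnetwork for visualization
#'
#' Writes the edge set induced among the subnetwork genes, as SIF
#' (`source TAB interaction TAB target`; isolated members as single-field
#' lines) or GraphML. Node attributes from `annotations` (e.g. rare-variant
#' level and common-variant score from [annotate_genes()]) are carried into
#' GraphML output so external viewers can color nodes by variant status.
#'
#' @param net The full [directed_network()].
#' @param result A `kda_result` (select the row with `kd_gene`) or a
#'   character vector of subnetwork genes.
#' @param kd_gene Key driver to export when `result` is a `kda_result`.
#' @param annotations Optional per-gene table (column `gene_id` plus
#'   attribute columns) attached as node attributes.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_subnetwork <- function(net, result, kd_gene = NULL, annotations = NULL,
                              path, format = c("sif", "graphml")) {
  net <- as_directed_network(net)
  format <- match.arg(format)
  if (inherits(result, "kda_result")) {
    if (is.null(kd_gene)) abort("kd_gene must name which key driver to export")
    row <- result$results |> filter(.data$kd_gene == !!kd_gene)
    if (nrow(row) == 0) abort(sprintf("'%s' is not among the scored key drivers", kd_gene))
    genes <- row$subnetwork[[1]]
  } else {
    genes <- unique(as.character(result))
  }
  induced <- net$edges |> filter(.data$from %in% genes, .data$to %in% genes)

  if (format == "sif") {
    lines <- sprintf("%s\tregulates\t%s", induced$from, induced$to)
    isolated <- setdiff(genes, unique(c(induced$from, induced$to)))
    writeLines(c(lines, isolated), path)
  } else {
    sub <- directed_network(induced, nodes = genes)
    g <- as_igraph(sub)
    if (!is.null(annotations)) {
      check_columns(annotations, "gene_id", "annotations")
      idx <- match(igraph::V(g)$name, annotations$gene_id)
      for (col in setdiff(names(annotations), "gene_id")) {
        vals <- annotations[[col]][idx]
        if (is.logical(vals)) vals <- as.integer(vals)
        if (is.factor(vals)) vals <- as.character(vals)
        if (is.character(vals)) vals[is.na(vals)] <- ""
        g <- igraph::set_vertex_attr(g, col, value = vals)
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
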