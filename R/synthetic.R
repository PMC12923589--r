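# Synthetic-data generators. Every pipeline input can be produced with
# known ground truth: uniform null GWAS p-values with a planted shifted-
# exponential signal tail, block-structured LD, gene modules with planted
# enrichment, scale-free directed networks with planted key drivers, and a
# rare-variant catalog concentrated in key-driver neighborhoods.

marker_ids <- function(n) sprintf("m%06d", seq_len(n))
gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate synthetic GWAS summary statistics with block LD
#'
#' Null markers draw `p ~ Uniform(0, 1]`. Signal markers draw their
#' `-log10 p` score from `Exponential(rate = log 10) + effect_shift`; at
#' `effect_shift = 0` this is exactly the null `-log10 Uniform`
#' distribution, so the shift is the whole effect. Markers are partitioned
#' into contiguous blocks; within-block pairs share `r2 = block_r2` and
#' between-block r-squared is 0.
#'
#' @param n_markers Number of markers (IDs `m000001`, ...).
#' @param n_blocks Number of LD blocks.
#' @param block_r2 Within-block r-squared. Default 0.8.
#' @param signal_markers Character vector of marker IDs carrying signal
#'   (must exist in the universe).
#' @param effect_shift Shift added to signal `-log10 p` scores (>= 0).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return List: `markers` (tibble `marker_id`, `raw_p`, `score`), `ld`
#'   (pairwise tibble `marker_a`, `marker_b`, `r2`), `blocks` (tibble
#'   `marker_id`, `block_id`), `truth` (signal markers and parameters).
#' @export
generate_gwas <- function(n_markers, n_blocks, block_r2 = 0.8,
                          signal_markers = character(), effect_shift = 0,
                          seed = 1) {
  stopifnot(n_markers >= 1, n_blocks >= 1, n_blocks <= n_markers,
            block_r2 >= 0, block_r2 <= 1, effect_shift >= 0)
  ids <- marker_ids(n_markers)
  bad <- setdiff(signal_markers, ids)
  if (length(bad) > 0) {
    abort(sprintf("%d signal marker(s) not in the marker universe", length(bad)))
  }
  is_signal <- ids %in% signal_markers
  block_id <- rep(seq_len(n_blocks), each = ceiling(n_markers / n_blocks))[seq_len(n_markers)]

  score <- withr::with_seed(seed, {
    s <- -log10(runif(n_markers))            # null: -log10 Uniform(0, 1]
    n_sig <- sum(is_signal)
    if (n_sig > 0) {
      s[is_signal] <- rexp(n_sig, rate = log(10)) + effect_shift
    }
    s
  })
  markers <- tibble(marker_id = ids, raw_p = 10^(-score), score = score)

  by_block <- split(ids, block_id)
  pair_list <- lapply(by_block, function(b) {
    if (length(b) < 2) return(NULL)
    cmb <- utils::combn(b, 2)
    tibble(marker_a = cmb[1, ], marker_b = cmb[2, ], r2 = block_r2)
  })
  ld <- bind_rows(pair_list)
  if (nrow(ld) == 0) ld <- tibble(marker_a = character(), marker_b = character(), r2 = numeric())

  list(
    markers = markers,
    ld = ld,
    blocks = tibble(marker_id = ids, block_id = block_id),
    truth = list(signal_markers = ids[is_signal], effect_shift = effect_shift,
                 n_markers = n_markers, n_blocks = n_blocks,
                 block_r2 = block_r2, seed = seed)
  )
}

#' Generate gene modules and a marker-to-gene map with planted enrichment
#'
#' Genes are partitioned into modules with sizes drawn uniformly from
#' `module_size_range`; each gene receives `markers_per_gene` distinct
#' markers (drawn globally without replacement). Genes of planted modules
#' draw exclusively from the supplied signal-marker pool, all other genes
#' from the null pool, so planted modules are enriched for high scores by
#' construction and the remaining universe is clean null.
#'
#' @param n_genes Size of the gene universe (IDs `g00001`, ...). Genes left
#'   over after filling modules stay in the universe (mapped but in no
#'   module), mimicking genes outside any coexpression module.
#' @param n_modules Number of modules (`mod001`, ...).
#' @param module_size_range Length-2 integer range of module sizes.
#' @param markers_per_gene Markers assigned to each gene.
#' @param planted_fraction Fraction of modules planted with signal.
#' @param markers Marker table from [generate_gwas()] (or compatible).
#' @param signal_markers Marker IDs forming the signal pool (typically
#'   `generate_gwas()$truth$signal_markers`).
#' @param seed Integer seed.
#' @param tissue Tissue label for the map and modules. Default
#'   `"synthetic"`.
#' @return List: `modules` (long tibble `set_id`, `tissue`, `gene_id`),
#'   `map` (tibble `marker_id`, `gene_id`, `tissue`, `source = "eqtl"`),
#'   `truth` (planted module IDs, their genes, parameters).
#' @export
generate_modules_and_map <- function(n_genes, n_modules,
                                     module_size_range = c(10, 25),
                                     markers_per_gene = 8,
                                     planted_fraction = 0,
                                     markers, signal_markers = character(),
                                     seed = 1, tissue = "synthetic") {
  stopifnot(n_genes >= 1, n_modules >= 1, length(module_size_range) == 2,
            module_size_range[1] >= 1, module_size_range[2] >= module_size_range[1],
            markers_per_gene >= 1, planted_fraction >= 0, planted_fraction <= 1)
  markers <- as_marker_table(markers)
  signal_markers <- intersect(signal_markers, markers$marker_id)
  null_pool_all <- setdiff(markers$marker_id, signal_markers)
  genes <- gene_ids(n_genes)

  withr::with_seed(seed, {
    sizes <- sample(seq(module_size_range[1], module_size_range[2]),
                    n_modules, replace = TRUE)
    if (sum(sizes) > n_genes) {
      abort(sprintf("module sizes sum to %d but only %d genes available",
                    sum(sizes), n_genes))
    }
    module_names <- sprintf("mod%03d", seq_len(n_modules))
    shuffled <- sample(genes)
    assignment <- rep(NA_character_, n_genes)
    assignment[seq_len(sum(sizes))] <- rep(module_names, times = sizes)
    gene_module <- tibble(gene_id = shuffled, set_id = assignment)

    n_planted <- round(planted_fraction * n_modules)
    planted <- if (n_planted > 0) sort(sample(module_names, n_planted)) else character()
    planted_genes <- gene_module$gene_id[gene_module$set_id %in% planted]
    other_genes <- setdiff(genes, planted_genes)

    need_signal <- length(planted_genes) * markers_per_gene
    need_null <- length(other_genes) * markers_per_gene
    if (need_signal > length(signal_markers)) {
      abort(sprintf("need %d signal markers for planted genes but pool has %d",
                    need_signal, length(signal_markers)))
    }
    if (need_null > length(null_pool_all)) {
      abort(sprintf("need %d null markers but pool has %d",
                    need_null, length(null_pool_all)))
    }
    sig_draw <- sample(signal_markers, need_signal)
    null_draw <- sample(null_pool_all, need_null)

    map <- bind_rows(
      if (length(planted_genes) > 0) {
        tibble(marker_id = sig_draw,
               gene_id = rep(planted_genes, each = markers_per_gene))
      },
      tibble(marker_id = null_draw,
             gene_id = rep(other_genes, each = markers_per_gene))
    ) |>
      mutate(tissue = !!tissue, source = "eqtl") |>
      arrange(.data$gene_id, .data$marker_id)

    modules <- gene_module |>
      filter(!is.na(.data$set_id)) |>
      mutate(tissue = !!tissue) |>
      select("set_id", "tissue", "gene_id") |>
      arrange(.data$set_id, .data$gene_id)

    list(
      modules = modules,
      map = map,
      truth = list(planted_modules = planted,
                   signal_genes = sort(planted_genes),
                   n_genes = n_genes, n_modules = n_modules,
                   module_size_range = module_size_range,
                   markers_per_gene = markers_per_gene,
                   planted_fraction = planted_fraction, seed = seed)
    )
  })
}

#' Generate a scale-free directed network with planted key drivers
#'
#' Grows an undirected preferential-attachment graph and orients each edge
#' from the older (higher-degree) endpoint to the newer one with
#' probability `forward_prob` (else reversed), producing out-hubs that
#' resemble regulators. Planted key drivers are rewired: their existing
#' edges are dropped and replaced by out-edges to a neighborhood in which a
#' fraction `nbhd_disease_fraction` of members are disease genes; the
#' planted degree targets the upper tail of the degree distribution so
#' planted drivers always clear the hub-candidate cutoff. A fraction of
#' key-driver neighborhood genes is labeled as rare-variant genes (levels
#' drawn uniformly from 1/2/3/syndromic), with a low background rate
#' elsewhere, emulating rare/common-variant convergence around drivers.
#'
#' @param n_nodes Number of nodes.
#' @param attachment_edges Edges added per new node in the
#'   preferential-attachment growth. Default 2.
#' @param planted_kds Number of planted key drivers. Default 0.
#' @param nbhd_disease_fraction Fraction of each planted neighborhood drawn
#'   from `disease_genes`. Default 0.8.
#' @param disease_genes Character vector of disease genes (subset of node
#'   names).
#' @param rare_genes_fraction Fraction of key-driver neighborhood genes
#'   labeled rare. Default 0.5.
#' @param rare_background_fraction Rare-gene rate outside neighborhoods.
#'   Default 0.02.
#' @param forward_prob Probability of orienting an edge old-to-new.
#'   Default 0.8.
#' @param node_names Node names; default `g00001`, ... so networks align
#'   with [generate_modules_and_map()] gene universes.
#' @param seed Integer seed.
#' @return List: `network` ([directed_network()]), `rare` (tibble
#'   `gene_id`, `level`), `truth` (planted KDs, their neighborhoods, rare
#'   genes, parameters).
#' @export
generate_network <- function(n_nodes, attachment_edges = 2, planted_kds = 0,
                             nbhd_disease_fraction = 0.8,
                             disease_genes = character(),
                             rare_genes_fraction = 0.5,
                             rare_background_fraction = 0.02,
                             forward_prob = 0.8, node_names = NULL, seed = 1) {
  stopifnot(n_nodes >= 3, attachment_edges >= 1,
            nbhd_disease_fraction >= 0, nbhd_disease_fraction <= 1,
            rare_genes_fraction >= 0, rare_genes_fraction <= 1,
            rare_background_fraction >= 0, rare_background_fraction <= 1)
  if (planted_kds > n_nodes) abort("more planted key drivers than nodes")
  nodes <- node_names %||% gene_ids(n_nodes)
  stopifnot(length(nodes) == n_nodes)

  withr::with_seed(seed, {
    g0 <- igraph::sample_pa(n_nodes, m = attachment_edges, directed = FALSE)
    el <- igraph::as_edgelist(g0, names = FALSE)
    older <- pmin(el[, 1], el[, 2])
    newer <- pmax(el[, 1], el[, 2])
    fwd <- runif(nrow(el)) < forward_prob
    edges <- tibble(
      from = nodes[ifelse(fwd, older, newer)],
      to = nodes[ifelse(fwd, newer, older)]
    )

    kds <- character()
    kd_nbhd <- list()
    if (planted_kds > 0) {
      deg_tbl <- table(c(edges$from, edges$to))
      deg <- as.integer(deg_tbl[nodes])
      deg[is.na(deg)] <- 0L
      kd_pool <- setdiff(nodes, disease_genes)
      if (length(kd_pool) < planted_kds) kd_pool <- nodes
      kds <- sort(sample(kd_pool, planted_kds))
      # target the upper tail so planted drivers stay above the hub cutoff
      # even after the rewiring perturbs the degree distribution
      d_kd <- max(ceiling(1.5 * empirical_quantile(deg[deg >= 1], 0.75)),
                  ceiling(empirical_quantile(deg[deg >= 1], 0.95)), 10)
      dis_pool_full <- intersect(disease_genes, nodes)
      n_dis <- round(nbhd_disease_fraction * d_kd)
      for (kd in kds) {
        edges <- edges |> filter(.data$from != !!kd, .data$to != !!kd)
        dis_pool <- setdiff(dis_pool_full, kd)
        oth_pool <- setdiff(nodes, c(dis_pool_full, kd))
        if (n_dis > length(dis_pool)) {
          abort(sprintf("planted neighborhood needs %d disease genes but only %d available",
                        n_dis, length(dis_pool)))
        }
        nb <- c(if (n_dis > 0) sample(dis_pool, n_dis),
                sample(oth_pool, d_kd - n_dis))
        edges <- bind_rows(edges, tibble(from = kd, to = nb))
        kd_nbhd[[kd]] <- sort(nb)
      }
    }
    net <- directed_network(edges, nodes = nodes)

    nbhd_union <- unique(unlist(kd_nbhd, use.names = FALSE))
    elsewhere <- setdiff(nodes, c(nbhd_union, kds))
    rare_genes <- c(
      if (length(nbhd_union) > 0) sample(nbhd_union, round(rare_genes_fraction * length(nbhd_union))),
      sample(elsewhere, round(rare_background_fraction * length(elsewhere)))
    )
    rare <- tibble(
      gene_id = sort(rare_genes),
      level = sample(.rare_levels, length(rare_genes), replace = TRUE)
    )

    list(
      network = net,
      rare = rare,
      truth = list(planted_kds = kds, kd_neighborhoods = kd_nbhd,
                   rare_genes = sort(rare_genes),
                   n_nodes = n_nodes, attachment_edges = attachment_edges,
                   nbhd_disease_fraction = nbhd_disease_fraction,
                   rare_genes_fraction = rare_genes_fraction,
                   rare_background_fraction = rare_background_fraction,
                   forward_prob = forward_prob, seed = seed)
    )
  })
}

# study-condition defaults for a complete synthetic scenario
scenario_defaults <- function() {
  list(
    n_markers = 4000, n_blocks = 2000, block_r2 = 0.8, effect_shift = 1.5,
    n_genes = 400, n_modules = 20, module_size_range = c(10, 25),
    markers_per_gene = 8, planted_fraction = 0.15,
    attachment_edges = 2, planted_kds = 3, nbhd_disease_fraction = 0.8,
    rare_genes_fraction = 0.5, rare_background_fraction = 0.02,
    forward_prob = 0.8, tissue = "synthetic"
  )
}

#' Generate a complete, internally consistent synthetic scenario
#'
#' Produces every pipeline input with one call. Profiles: `"null"` plants
#' nothing anywhere (uniform GWAS, random modules, no planted drivers) and
#' feeds the type-I-error suites; `"enriched"` plants signal modules only;
#' `"full"` additionally plants key drivers whose neighborhoods are
#' enriched for the planted modules' genes and for rare-variant genes.
#' When `dir` is given, all inputs are written in the standard on-disk
#' formats (readable with zero dropped rows by the package readers) along
#' with the ground truth and the echoed parameters; regeneration from the
#' same seed is byte-identical.
#'
#' @param profile `"null"`, `"enriched"` or `"full"`.
#' @param seed Integer master seed; component seeds are derived from it.
#' @param dir Optional output directory for the file bundle.
#' @param overwrite Overwrite an existing bundle. Default `FALSE` (error
#'   if bundle files already exist).
#' @param params Named list of overrides for the generator defaults (e.g.
#'   `n_modules`, `effect_shift`).
#' @return List: `profile`, `params`, `markers`, `ld`, `blocks`, `map`,
#'   `modules`, `network`, `rare`, `truth`, and `paths` (when written).
#' @export
generate_scenario <- function(profile = c("null", "enriched", "full"),
                              seed = 1, dir = NULL, overwrite = FALSE,
                              params = list()) {
  profile <- match.arg(profile)
  p <- scenario_defaults()
  if (profile == "null") {
    p$planted_fraction <- 0
    p$effect_shift <- 0
    p$planted_kds <- 0
  } else if (profile == "enriched") {
    p$planted_kds <- 0
  }
  p <- utils::modifyList(p, params)

  ids <- marker_ids(p$n_markers)
  n_planted_mod <- round(p$planted_fraction * p$n_modules)
  need_signal <- n_planted_mod * p$module_size_range[2] * p$markers_per_gene
  signal_markers <- if (need_signal > 0) {
    withr::with_seed(derive_seed(seed, 1L), sample(ids, need_signal))
  } else {
    character()
  }

  gwas <- generate_gwas(p$n_markers, p$n_blocks, p$block_r2,
                        signal_markers = signal_markers,
                        effect_shift = p$effect_shift,
                        seed = derive_seed(seed, 2L))
  mm <- generate_modules_and_map(p$n_genes, p$n_modules, p$module_size_range,
                                 p$markers_per_gene, p$planted_fraction,
                                 markers = gwas$markers,
                                 signal_markers = gwas$truth$signal_markers,
                                 seed = derive_seed(seed, 3L),
                                 tissue = p$tissue)
  nw <- generate_network(p$n_genes, p$attachment_edges, p$planted_kds,
                         p$nbhd_disease_fraction,
                         disease_genes = mm$truth$signal_genes,
                         rare_genes_fraction = p$rare_genes_fraction,
                         rare_background_fraction = p$rare_background_fraction,
                         forward_prob = p$forward_prob,
                         node_names = gene_ids(p$n_genes),
                         seed = derive_seed(seed, 4L))

  truth <- list(
    profile = profile, seed = seed,
    signal_markers = gwas$truth$signal_markers,
    planted_modules = mm$truth$planted_modules,
    signal_genes = mm$truth$signal_genes,
    planted_kds = nw$truth$planted_kds,
    kd_neighborhoods = nw$truth$kd_neighborhoods,
    rare_genes = nw$truth$rare_genes,
    params = p
  )

  out <- list(profile = profile, params = p, markers = gwas$markers,
              ld = gwas$ld, blocks = gwas$blocks, map = mm$map,
              modules = mm$modules, network = nw$network, rare = nw$rare,
              truth = truth, paths = NULL)

  if (!is.null(dir)) {
    out$paths <- write_scenario(out, dir, overwrite = overwrite)
  }
  out
}

# write the scenario bundle in the standard formats
write_scenario <- function(scn, dir, overwrite = FALSE) {
  paths <- list(
    gwas = file.path(dir, "gwas.tsv"),
    ld = file.path(dir, "ld.tsv"),
    blocks = file.path(dir, "ld_blocks.tsv"),
    map = file.path(dir, "marker_map.tsv"),
    modules = file.path(dir, "modules.gmt"),
    network = file.path(dir, "network.sif"),
    rare = file.path(dir, "rare_variants.tsv"),
    truth = file.path(dir, "truth.yaml"),
    params = file.path(dir, "params.yaml")
  )
  existing <- vapply(paths, file.exists, logical(1))
  if (any(existing) && !overwrite) {
    abort(sprintf("scenario files already exist in '%s'; use overwrite = TRUE", dir))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  readr::write_tsv(scn$markers |> mutate(p = .data$raw_p) |>
                     select("marker_id", "p"), paths$gwas, progress = FALSE)
  readr::write_tsv(scn$ld, paths$ld, progress = FALSE)
  readr::write_tsv(scn$blocks, paths$blocks, progress = FALSE)
  readr::write_tsv(scn$map, paths$map, progress = FALSE)

  gmt_lines <- scn$modules |>
    group_by(.data$set_id) |>
    summarise(line = paste(c(.data$set_id[1], "synthetic module",
                             sort(.data$gene_id)), collapse = "\t"),
              .groups = "drop") |>
    arrange(.data$set_id) |>
    pull("line")
  writeLines(gmt_lines, paths$modules)

  writeLines(sprintf("%s\tregulates\t%s", scn$network$edges$from,
                     scn$network$edges$to), paths$network)
  readr::write_tsv(scn$rare, paths$rare, progress = FALSE)
  yaml::write_yaml(scn$truth, paths$truth)
  yaml::write_yaml(scn$params, paths$params)
  paths
}
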