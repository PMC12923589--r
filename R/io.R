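# Readers and writers for the plain-text formats the pipeline consumes:
# GWAS summary-statistic tables, GMT gene sets, SIF / two-column edge lists,
# marker-to-gene maps, rare-variant catalogs, and tab-delimited result tables.

# detect tab vs comma from the first line; tab wins when both occur
detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) abort(sprintf("file is empty: %s", path))
  if (grepl("\t", first)) "\t" else ","
}

#' Retrieve the load report attached to a read result
#'
#' Every reader accounts for all input rows: `kept + dropped = total`.
#'
#' @param x An object returned by one of the `read_*()` functions.
#' @return A list with elements `total`, `kept`, `dropped`.
#' @export
load_report <- function(x) attr(x, "load_report")

#' Read GWAS summary statistics into a marker table
#'
#' Reads a delimited text file of per-marker association p-values and returns
#' a marker table with `score = -log10(p)`. The full spectrum of association
#' strengths is retained: no p-value cutoff is applied, so downstream
#' enrichment tests see strong, moderate and weak signals alike.
#'
#' Rows with missing or unparseable p-values, or with p outside `(0, 1]`, are
#' dropped with a warning and counted in the load report ([load_report()]).
#' `p = 1` maps to score 0 and is kept; `p <= 0` has no finite `-log10` and is
#' rejected. Duplicate marker IDs are an error: the upstream harmonisation
#' that produced the file must resolve them.
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param p_column Name of the p-value column. Default `"p"`.
#' @param marker_column Name of the marker ID column; default the first
#'   column of the file.
#' @param delim Field delimiter; `NULL` (default) auto-detects, preferring
#'   tab over comma.
#' @return A tibble with columns `marker_id`, `raw_p`, `score`, carrying a
#'   load report attribute.
#' @export
read_gwas_scores <- function(path, p_column = "p", marker_column = NULL,
                             delim = NULL) {
  delim <- delim %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (is.null(marker_column)) marker_column <- names(raw)[1]
  check_columns(raw, c(marker_column, p_column), sprintf("GWAS file '%s'", path))
  total <- nrow(raw)
  p <- suppressWarnings(as.numeric(raw[[p_column]]))
  ok <- !is.na(p) & p > 0 & p <= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("%d row(s) with missing or out-of-range p-values dropped (p must be in (0, 1])",
                 n_dropped))
  }
  out <- tibble(
    marker_id = as.character(raw[[marker_column]])[ok],
    raw_p = p[ok],
    score = -log10(p[ok])
  )
  if (anyDuplicated(out$marker_id) > 0) {
    dups <- unique(out$marker_id[duplicated(out$marker_id)])
    abort(sprintf("duplicate marker ID(s) in GWAS file: %s",
                  paste(head(dups, 5), collapse = ", ")))
  }
  attr(out, "load_report") <- list(total = total, kept = nrow(out), dropped = n_dropped)
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `set_id TAB description TAB gene1
#' TAB gene2 ...`. Returned in long (tidy) form with one row per
#' (set, gene) pair.
#'
#' @param path Path to the GMT file.
#' @param tissue Optional tissue label attached to every set (GMT itself
#'   carries none). Default `NA`.
#' @return A tibble with columns `set_id`, `tissue`, `description`,
#'   `gene_id`.
#' @export
read_gene_sets_gmt <- function(path, tissue = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("GMT file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1]))
  }
  set_ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(set_ids) > 0) {
    abort(sprintf("duplicate set_id in GMT file: %s",
                  paste(unique(set_ids[duplicated(set_ids)]), collapse = ", ")))
  }
  n_dup_genes <- 0L
  rows <- purrr::map2(fields, set_ids, function(f, id) {
    genes <- f[-c(1, 2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes) > 0) {
      n_dup_genes <<- n_dup_genes + sum(duplicated(genes))
      genes <- unique(genes)
    }
    tibble(set_id = id, tissue = tissue, description = f[[2]], gene_id = genes)
  })
  if (n_dup_genes > 0) {
    warn(sprintf("%d duplicate gene entr(ies) within sets were deduplicated", n_dup_genes))
  }
  bind_rows(rows)
}

#' Construct a directed network from an edge table
#'
#' The package's network container: a deduplicated edge list plus a node
#' universe (edge endpoints and any isolated nodes).
#'
#' @param edges Data frame with columns `from`, `to` (extra columns dropped).
#' @param nodes Optional character vector of node names to include even when
#'   isolated.
#' @return An object of class `directed_network` with elements `edges`
#'   (tibble) and `nodes` (character).
#' @export
directed_network <- function(edges, nodes = NULL) {
  check_columns(edges, c("from", "to"), "edge table")
  edges <- distinct(as_tibble(edges[, c("from", "to")]))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes %||% character()))))
  structure(list(edges = edges, nodes = nodes), class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# internal: coerce edge tables / networks to directed_network
as_directed_network <- function(x) {
  if (inherits(x, "directed_network")) return(x)
  directed_network(x)
}

# internal: igraph view of a directed_network
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE, vertices = net$nodes)
}

#' Read a network edge list (two-column or SIF)
#'
#' Auto-detects the dialect from the column count: two whitespace/tab
#' separated columns are `source target`; three columns with a non-numeric
#' middle column are SIF (`source interaction target`); three columns with a
#' numeric third column are `source target weight` (the weight is ignored —
#' the pipeline consumes edge topology only).
#'
#' @param path Path to the edge-list file (no header).
#' @param directed Interpret edges as directed (default `TRUE`).
#' @return A [directed_network()] carrying a load report.
#' @export
read_edge_list <- function(path, directed = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("edge-list file is empty: %s", path))
  fields <- strsplit(trimws(lines), "[\t ]+")
  ncol <- lengths(fields)
  if (any(ncol < 2)) {
    abort(sprintf("edge-list line %d has fewer than 2 fields", which(ncol < 2)[1]))
  }
  from <- vapply(fields, `[[`, character(1), 1)
  second <- vapply(fields, `[[`, character(1), 2)
  if (all(ncol >= 3)) {
    third <- vapply(fields, `[[`, character(1), 3)
    mid_numeric <- !anyNA(suppressWarnings(as.numeric(second)))
    if (!mid_numeric) {          # SIF: source interaction target
      to <- third
    } else {
      to <- second               # numeric middle would be odd; treat as 2-col
    }
  } else {
    to <- second                 # 2-col, possibly with numeric weight ignored
  }
  edges <- tibble(from = from, to = to)
  if (!directed) {
    # store both orientations so downstream directed ops see symmetry
    edges <- distinct(bind_rows(edges, tibble(from = to, to = from)))
  }
  net <- directed_network(edges)
  attr(net, "load_report") <- list(total = length(lines),
                                   kept = nrow(net$edges),
                                   dropped = length(lines) - nrow(net$edges))
  net
}

#' Read a marker-to-gene mapping table
#'
#' @param path Delimited file with columns `marker_id`, `gene_id`, `tissue`,
#'   `source` (source one of `eqtl`, `sqtl`, `distance`).
#' @param delim Delimiter; `NULL` auto-detects.
#' @return Tibble of distinct mapping records.
#' @export
read_marker_gene_map <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  map <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  check_columns(map, c("marker_id", "gene_id", "tissue", "source"),
                sprintf("marker-gene map '%s'", path))
  bad <- setdiff(unique(map$source), c("eqtl", "sqtl", "distance"))
  if (length(bad) > 0) {
    abort(sprintf("unknown mapping source(s): %s (expected eqtl, sqtl, distance)",
                  paste(bad, collapse = ", ")))
  }
  n0 <- nrow(map)
  map <- distinct(map, .data$marker_id, .data$gene_id, .data$tissue, .data$source)
  if (nrow(map) < n0) {
    warn(sprintf("%d duplicate mapping record(s) removed", n0 - nrow(map)))
  }
  map
}

# confidence order for rare-variant levels, strongest first
.rare_levels <- c("1", "2", "3", "syndromic")

#' Read a rare-variant gene catalog
#'
#' Expects columns `gene_id` and `level`, with level one of `1`, `2`, `3`,
#' `syndromic` (SFARI-style confidence tiers: 1 = high confidence,
#' 2 = strong candidate, 3 = suggestive evidence, syndromic = mutations
#' associated with a broader syndrome that includes the phenotype). When a
#' gene appears with several levels the highest-confidence one is kept
#' (1 > 2 > 3 > syndromic) and the conflict is reported.
#'
#' @param path Delimited file path.
#' @param delim Delimiter; `NULL` auto-detects.
#' @return Tibble with columns `gene_id`, `level`, one row per gene.
#' @export
read_rare_variant_catalog <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  cat_raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                               progress = FALSE,
                               col_types = readr::cols(.default = readr::col_character()))
  check_columns(cat_raw, c("gene_id", "level"), sprintf("rare-variant catalog '%s'", path))
  lev <- tolower(trimws(cat_raw$level))
  bad <- setdiff(unique(lev), .rare_levels)
  if (length(bad) > 0) {
    abort(sprintf("unknown rare-variant level(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(.rare_levels, collapse = ", ")))
  }
  out <- tibble(gene_id = cat_raw$gene_id, level = lev) |>
    mutate(rank = match(.data$level, .rare_levels)) |>
    group_by(.data$gene_id)
  conflicts <- out |> summarise(n = dplyr::n_distinct(.data$level)) |> filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    inform(sprintf("%d gene(s) listed at multiple levels; keeping the highest-confidence level",
                   nrow(conflicts)))
  }
  out |>
    slice(which.min(.data$rank)) |>
    ungroup() |>
    select("gene_id", "level") |>
    arrange(.data$gene_id)
}

# flatten list columns (e.g. subnetwork membership) to comma-joined strings
flatten_list_cols <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ","), character(1))
    }
  }
  df
}

#' Write a result table to tab-delimited text
#'
#' Deterministic column order (as given), header row, full-precision numeric
#' formatting so that a write-then-read round trip reproduces values to
#' better than 1e-12. List columns (e.g. subnetwork membership) are collapsed
#' to comma-joined strings.
#'
#' @param records Data frame of results (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- flatten_list_cols(as_tibble(records))
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a table written by [write_results_table()]
#'
#' @param path Path to the tab-delimited file.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
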