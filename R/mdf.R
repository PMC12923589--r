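# Marker dependency filtering (MDF): linkage-disequilibrium clumping of GWAS
# markers and construction of tissue-specific gene -> marker assignments.

# normalise LD input to one of two forms:
#   pairwise: tibble(marker_a, marker_b, r2)
#   blocks:   tibble(marker_id, block_id)
ld_mode <- function(ld) {
  if (is.null(ld)) return("none")
  if (all(c("marker_a", "marker_b", "r2") %in% names(ld))) return("pairwise")
  if (all(c("marker_id", "block_id") %in% names(ld))) return("blocks")
  abort("LD info must have columns (marker_a, marker_b, r2) or (marker_id, block_id)")
}

#' LD-clump a marker table
#'
#' Removes markers whose association signal is redundant with a stronger
#' marker in linkage disequilibrium, keeping the marker with the strongest
#' GWAS association among correlated ones. Markers are processed in
#' descending score order (ties broken by ascending marker ID); a marker is
#' retained unless its r-squared with an already-retained marker exceeds
#' `r2_threshold`, in which case it is recorded as removed and assigned to
#' the earliest-retained such marker. Missing LD entries are treated as
#' r-squared 0, so markers with no LD information are always retained.
#'
#' LD can be given as pairwise records (`marker_a`, `marker_b`, `r2`) or as
#' block assignments (`marker_id`, `block_id`); in block mode every
#' within-block pair is treated as exceeding the threshold, so exactly the
#' top-scoring marker of each block is retained.
#'
#' @param markers Marker table with columns `marker_id`, `score`.
#' @param ld Pairwise or block LD information (see above); `NULL` retains
#'   everything.
#' @param r2_threshold Retain markers only if their r-squared with every
#'   already-retained marker is at or below this value. Default 0.5.
#' @return An object of class `clumped_markers`: list with `markers` (the
#'   retained subset, a tibble), `removed` (tibble `marker_id`,
#'   `representative`), and `r2_threshold`.
#' @export
ld_clump <- function(markers, ld = NULL, r2_threshold = 0.5) {
  markers <- as_marker_table(markers)
  stopifnot(is.numeric(r2_threshold), length(r2_threshold) == 1,
            r2_threshold > 0, r2_threshold <= 1)
  mode <- ld_mode(ld)

  ord <- order(-markers$score, markers$marker_id)
  ids <- markers$marker_id[ord]

  if (mode == "none") {
    removed <- tibble(marker_id = character(), representative = character())
    res <- list(markers = markers, removed = removed, r2_threshold = r2_threshold)
    class(res) <- "clumped_markers"
    return(res)
  }

  if (mode == "blocks") {
    blk <- ld[!is.na(ld$block_id), c("marker_id", "block_id")]
    unknown <- setdiff(blk$marker_id, markers$marker_id)
    if (length(unknown) > 0) {
      warn(sprintf("%d marker(s) in LD info absent from marker table; ignored",
                   length(unknown)))
      blk <- blk[blk$marker_id %in% markers$marker_id, ]
    }
    block_of <- setNames(as.character(blk$block_id), blk$marker_id)
    seen_block <- new.env(parent = emptyenv())
    keep <- logical(length(ids))
    rep_of <- character(0)
    rep_names <- character(0)
    for (i in seq_along(ids)) {
      b <- unname(block_of[ids[i]])
      if (is.na(b)) {
        keep[i] <- TRUE
      } else if (is.null(seen_block[[b]])) {
        seen_block[[b]] <- ids[i]
        keep[i] <- TRUE
      } else {
        rep_of <- c(rep_of, seen_block[[b]])
        rep_names <- c(rep_names, ids[i])
      }
    }
    retained_ids <- ids[keep]
  } else {
    pw <- ld[, c("marker_a", "marker_b", "r2")]
    pw <- pw[!is.na(pw$r2) & pw$marker_a != pw$marker_b, ]
    unknown <- setdiff(unique(c(pw$marker_a, pw$marker_b)), markers$marker_id)
    if (length(unknown) > 0) {
      warn(sprintf("%d marker(s) in LD info absent from marker table; ignored",
                   length(unknown)))
      pw <- pw[pw$marker_a %in% markers$marker_id & pw$marker_b %in% markers$marker_id, ]
    }
    pw <- pw[pw$r2 > r2_threshold, ]
    # adjacency over the dependency graph (symmetric)
    adj <- split(c(pw$marker_b, pw$marker_a), c(pw$marker_a, pw$marker_b))
    retained_rank <- new.env(parent = emptyenv())   # marker -> retention index
    keep <- logical(length(ids))
    rep_of <- character(0)
    rep_names <- character(0)
    n_ret <- 0L
    for (i in seq_along(ids)) {
      id <- ids[i]
      nb <- adj[[id]]
      rep_id <- NA_character_
      if (!is.null(nb)) {
        best <- Inf
        for (m in unique(nb)) {
          r <- retained_rank[[m]]
          if (!is.null(r) && r < best) {
            best <- r
            rep_id <- m
          }
        }
      }
      if (is.na(rep_id)) {
        n_ret <- n_ret + 1L
        retained_rank[[id]] <- n_ret
        keep[i] <- TRUE
      } else {
        rep_of <- c(rep_of, rep_id)
        rep_names <- c(rep_names, id)
      }
    }
    retained_ids <- ids[keep]
  }

  retained <- markers[match(retained_ids, markers$marker_id), ]
  retained <- arrange(retained, dplyr::desc(.data$score), .data$marker_id)
  removed <- tibble(marker_id = rep_names, representative = rep_of)
  res <- list(markers = retained, removed = removed, r2_threshold = r2_threshold)
  class(res) <- "clumped_markers"
  res
}

#' @export
print.clumped_markers <- function(x, ...) {
  cat(sprintf("<clumped_markers: %d retained, %d removed (r2 > %g)>\n",
              nrow(x$markers), nrow(x$removed), x$r2_threshold))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clumped_markers <- function(x, ...) x$markers

#' Build tissue-specific gene-to-marker assignments
#'
#' For one tissue, collects for each gene the distinct LD-independent
#' markers mapped to it by any of the selected sources (eQTL, sQTL,
#' distance). Genes with no retained marker are excluded; the tissue's
#' background marker universe is the union of all assigned markers.
#'
#' @param clumped A `clumped_markers` object from [ld_clump()] (or a plain
#'   marker table, in which case every marker counts as retained).
#' @param map Marker-to-gene map with columns `marker_id`, `gene_id`,
#'   `tissue`, `source`.
#' @param tissue Tissue to assemble; must be present in `map`.
#' @param sources Which mapping sources to use. Default all three.
#' @return Object of class `gene_marker_assignment`: list with `assignment`
#'   (tibble `gene_id`, `marker_id`), `background` (character vector of
#'   marker IDs), `tissue` and `sources`.
#' @export
map_markers_to_genes <- function(clumped, map,
                                 tissue,
                                 sources = c("eqtl", "sqtl", "distance")) {
  retained <- if (inherits(clumped, "clumped_markers")) clumped$markers else as_marker_table(clumped)
  check_columns(map, c("marker_id", "gene_id", "tissue", "source"), "marker-gene map")
  sources <- match.arg(sources, several.ok = TRUE)
  tissues <- unique(map$tissue)
  if (!tissue %in% tissues) {
    abort(sprintf("tissue '%s' not present in map; available: %s",
                  tissue, paste(sort(tissues), collapse = ", ")))
  }
  sub <- map |>
    filter(.data$tissue == !!tissue, .data$source %in% !!sources,
           .data$marker_id %in% retained$marker_id) |>
    distinct(.data$gene_id, .data$marker_id) |>
    arrange(.data$gene_id, .data$marker_id)
  res <- list(
    assignment = sub,
    background = sort(unique(sub$marker_id)),
    tissue = tissue,
    sources = sources
  )
  class(res) <- "gene_marker_assignment"
  res
}

#' @export
print.gene_marker_assignment <- function(x, ...) {
  cat(sprintf("<gene_marker_assignment: tissue '%s', %d genes, %d background markers>\n",
              x$tissue, dplyr::n_distinct(x$assignment$gene_id), length(x$background)))
  invisible(x)
}

#' Distance-based marker-to-gene mapping
#'
#' Maps a marker to a gene when its position falls within the gene body
#' extended by `window` base pairs on both sides, capturing cis-regulatory
#' proximity. Coordinates are 1-based inclusive.
#'
#' @param marker_positions Table with columns `marker_id`, `chrom`, `pos`.
#' @param gene_annotations Table with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive; see [read_gene_annotations_bed()] for BED
#'   input).
#' @param window Flank size in bp added to each gene end. Default 20000
#'   (±20 kb).
#' @param tissue Tissue label recorded in the output map. Default `"all"`.
#' @return A marker-to-gene map tibble (`marker_id`, `gene_id`, `tissue`,
#'   `source = "distance"`).
#' @export
build_distance_map <- function(marker_positions, gene_annotations,
                               window = 20000, tissue = "all") {
  check_columns(marker_positions, c("marker_id", "chrom", "pos"), "marker positions")
  check_columns(gene_annotations, c("gene_id", "chrom", "start", "end"), "gene annotations")
  stopifnot(window >= 0)
  orphan_chroms <- setdiff(unique(marker_positions$chrom), unique(gene_annotations$chrom))
  if (length(orphan_chroms) > 0) {
    warn(sprintf("markers on chromosome(s) %s have no gene annotations and map to nothing",
                 paste(orphan_chroms, collapse = ", ")))
  }
  genes <- gene_annotations |>
    mutate(win_start = .data$start - window, win_end = .data$end + window)
  hits <- dplyr::inner_join(
    as_tibble(marker_positions), genes,
    by = dplyr::join_by(chrom, between(pos, win_start, win_end))
  )
  hits |>
    distinct(.data$marker_id, .data$gene_id) |>
    mutate(tissue = !!tissue, source = "distance") |>
    arrange(.data$gene_id, .data$marker_id)
}

#' Read gene annotations from a BED file
#'
#' BED uses 0-based half-open intervals; they are converted to the 1-based
#' inclusive convention used by [build_distance_map()] (`start + 1`, `end`
#' unchanged) and the conversion is reported.
#'
#' @param path BED file with at least 4 columns: chrom, start, end, name.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_annotations_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(bed) < 4) abort("BED gene file needs at least 4 columns (chrom, start, end, name)")
  inform("BED 0-based half-open coordinates converted to 1-based inclusive")
  tibble(
    gene_id = as.character(bed[[4]]),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]])
  )
}
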