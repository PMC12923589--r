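# Marker dependency filtering: greedy LD clumping and gene-marker maps.

test_that("greedy clumping keeps the strongest marker in each dependency group", {
  markers <- tibble::tibble(marker_id = c("m1", "m2", "m3"), score = c(5, 3, 1))
  ld <- tibble::tibble(marker_a = c("m1", "m1", "m2"),
                       marker_b = c("m2", "m3", "m3"),
                       r2 = c(0.9, 0.1, 0.1))
  cl <- ld_clump(markers, ld, r2_threshold = 0.5)
  expect_setequal(cl$markers$marker_id, c("m1", "m3"))
  expect_equal(cl$removed$marker_id, "m2")
  expect_equal(cl$removed$representative, "m1")

  # independent markers all retained
  ld0 <- dplyr::mutate(ld, r2 = 0)
  expect_equal(nrow(ld_clump(markers, ld0, 0.5)$markers), 3)
})

test_that("block mode retains exactly the top scorer per block", {
  set.seed(5)
  markers <- tibble::tibble(marker_id = sprintf("m%02d", 1:10),
                            score = round(runif(10) * 10, 3))
  blocks <- tibble::tibble(marker_id = markers$marker_id,
                           block_id = rep(1:3, length.out = 10))
  cl <- ld_clump(markers, blocks, 0.5)
  expect_equal(nrow(cl$markers), 3)
  best <- markers |>
    dplyr::mutate(block = blocks$block_id) |>
    dplyr::group_by(block) |>
    dplyr::slice_max(score, n = 1) |>
    dplyr::pull(marker_id)
  expect_setequal(cl$markers$marker_id, best)
  # every removed marker points at its block's retained representative
  rep_block <- blocks$block_id[match(cl$removed$representative, blocks$marker_id)]
  own_block <- blocks$block_id[match(cl$removed$marker_id, blocks$marker_id)]
  expect_equal(rep_block, own_block)
})

test_that("clumping matches the step-by-step greedy reference on random instances", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(3:12, 1)
    markers <- tibble::tibble(marker_id = sprintf("m%02d", seq_len(n)),
                              score = sample(seq_len(2 * n), n) / 2)
    pairs <- t(utils::combn(markers$marker_id, 2))
    ld <- tibble::tibble(marker_a = pairs[, 1], marker_b = pairs[, 2],
                         r2 = round(runif(nrow(pairs)), 2))
    ref <- reference_clump(markers, ld, 0.5)
    got <- ld_clump(markers, ld, 0.5)
    expect_equal(sort(got$markers$marker_id), sort(ref$retained))
    expect_equal(got$removed$representative[order(got$removed$marker_id)],
                 ref$representative[order(ref$removed)])
  }
})

test_that("clumping invariants hold: idempotence, threshold monotonicity, r2 bound", {
  set.seed(99)
  markers <- tibble::tibble(marker_id = sprintf("m%02d", 1:20),
                            score = runif(20) * 8)
  pairs <- t(utils::combn(markers$marker_id, 2))
  ld <- tibble::tibble(marker_a = pairs[, 1], marker_b = pairs[, 2],
                       r2 = round(runif(nrow(pairs))^2, 2))

  cl <- ld_clump(markers, ld, 0.5)
  # retained set has no pairwise dependency above threshold
  kept <- cl$markers$marker_id
  viol <- ld[ld$marker_a %in% kept & ld$marker_b %in% kept & ld$r2 > 0.5, ]
  expect_equal(nrow(viol), 0)
  # representative at least as strong as the removed marker
  sc <- setNames(markers$score, markers$marker_id)
  expect_true(all(sc[cl$removed$representative] >= sc[cl$removed$marker_id]))
  # idempotence (LD rows for already-removed markers are ignorable)
  again <- suppressWarnings(ld_clump(cl$markers, ld, 0.5))
  expect_equal(again$markers, cl$markers)
  # raising the threshold never reduces the retained count
  n_kept <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0),
                   function(t) nrow(ld_clump(markers, ld, t)$markers), numeric(1))
  expect_true(all(diff(n_kept) >= 0))
})

test_that("markers missing from the table are ignored with a warning", {
  markers <- tibble::tibble(marker_id = c("m1", "m2"), score = c(2, 1))
  ld <- tibble::tibble(marker_a = c("m1", "mX"), marker_b = c("m2", "m1"),
                       r2 = c(0.9, 0.9))
  expect_warning(cl <- ld_clump(markers, ld, 0.5), "absent")
  expect_equal(cl$markers$marker_id, "m1")
})

test_that("gene mapping pools distinct retained markers across sources", {
  markers <- tibble::tibble(marker_id = c("rs1", "rs2"), score = c(1, 2))
  cl <- ld_clump(markers, NULL)
  map <- tibble::tibble(
    marker_id = c("rs1", "rs1", "rs2"),
    gene_id = "G1",
    tissue = "brain",
    source = c("eqtl", "distance", "sqtl")
  )
  asg <- map_markers_to_genes(cl, map, "brain")
  expect_setequal(asg$assignment$marker_id, c("rs1", "rs2"))
  expect_equal(asg$background, c("rs1", "rs2"))

  asg_e <- map_markers_to_genes(cl, map, "brain", sources = "eqtl")
  expect_equal(asg_e$assignment$marker_id, "rs1")

  expect_error(map_markers_to_genes(cl, map, "liver"), "available.*brain")
})

test_that("gene mapping excludes clumped-away markers and is order-invariant", {
  set.seed(3)
  markers <- tibble::tibble(marker_id = sprintf("rs%02d", 1:12), score = runif(12))
  # remove two markers via blocks
  blocks <- tibble::tibble(marker_id = c("rs01", "rs02", "rs03", "rs04"),
                           block_id = c(1, 1, 2, 2))
  cl <- ld_clump(markers, blocks, 0.5)
  expect_equal(nrow(cl$markers), 10)
  map <- tibble::tibble(
    marker_id = rep(markers$marker_id, each = 2),
    gene_id = rep(sprintf("G%d", 1:5), length.out = 24),
    tissue = "t1", source = "eqtl"
  ) |> dplyr::distinct()
  asg <- map_markers_to_genes(cl, map, "t1")
  expect_equal(length(asg$background), 10)
  # row order of the map does not matter
  asg_shuf <- map_markers_to_genes(cl, map[sample.int(nrow(map)), ], "t1")
  expect_equal(asg_shuf$assignment, asg$assignment)
  expect_equal(asg_shuf$background, asg$background)
})

test_that("distance mapping uses 1-based inclusive windows around genes", {
  genes <- tibble::tibble(gene_id = "G1", chrom = "1", start = 1000, end = 2000)
  mk <- function(pos) tibble::tibble(marker_id = "m", chrom = "1", pos = pos)
  inside <- build_distance_map(mk(21999), genes, window = 20000)
  expect_equal(nrow(inside), 1)
  outside <- build_distance_map(mk(22001), genes, window = 20000)
  expect_equal(nrow(outside), 0)
  # lower boundary: start - window
  expect_equal(nrow(build_distance_map(mk(-19000), genes, window = 20000)), 1)

  # all-pairs interval oracle on a toy chromosome
  set.seed(8)
  genes3 <- tibble::tibble(gene_id = c("G1", "G2", "G3"), chrom = "1",
                           start = c(100, 5000, 9000), end = c(600, 6000, 9500))
  pos <- sample.int(12000, 6)
  mk6 <- tibble::tibble(marker_id = sprintf("m%d", 1:6), chrom = "1", pos = pos)
  w <- 300
  got <- build_distance_map(mk6, genes3, window = w)
  expected <- expand.grid(i = 1:6, j = 1:3) |>
    dplyr::filter(pos[i] >= genes3$start[j] - w, pos[i] <= genes3$end[j] + w)
  expect_equal(nrow(got), nrow(expected))

  other_chrom <- tibble::tibble(marker_id = "mx", chrom = "2", pos = 100)
  expect_warning(none <- build_distance_map(other_chrom, genes3, window = w),
                 "no gene annotations")
  expect_equal(nrow(none), 0)
})
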