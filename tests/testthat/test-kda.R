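# Key-driver analysis: merging, hub selection, neighborhoods, scoring, export.

chain_net <- function() directed_network(tibble::tibble(from = c("A", "B"), to = c("B", "C")))

test_that("network merging is a deduplicating edge union", {
  n1 <- directed_network(tibble::tibble(from = "A", to = "B"))
  n2 <- directed_network(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  m <- merge_networks(n1, n2)
  expect_equal(nrow(m$edges), 2)

  d1 <- directed_network(tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a")))
  d2 <- directed_network(tibble::tibble(from = c("x", "y", "z"), to = c("y", "z", "x")))
  expect_equal(nrow(merge_networks(d1, d2)$edges), 6)

  # inclusion-exclusion on three synthetic nets with known overlap
  set.seed(12)
  mk_net <- function() {
    e <- expand.grid(from = letters[1:6], to = letters[1:6], stringsAsFactors = FALSE)
    e <- e[e$from != e$to, ]
    directed_network(e[sample.int(nrow(e), 12), ])
  }
  nets <- list(mk_net(), mk_net(), mk_net())
  key <- function(n) paste(n$edges$from, n$edges$to)
  expected <- length(unique(c(key(nets[[1]]), key(nets[[2]]), key(nets[[3]]))))
  expect_equal(nrow(merge_networks(nets)$edges), expected)

  # associativity/commutativity on edge sets
  ab_c <- merge_networks(merge_networks(nets[[1]], nets[[2]]), nets[[3]])
  c_ba <- merge_networks(nets[[3]], merge_networks(nets[[2]], nets[[1]]))
  expect_setequal(key(ab_c), key(c_ba))
})

test_that("hub candidates are the top tail of the degree distribution", {
  star <- directed_network(tibble::tibble(from = "hub", to = sprintf("l%d", 1:9)))
  hc <- find_hub_candidates(star, 0.75)
  expect_true(hc$is_candidate[hc$gene == "hub"])

  # regular ring: everyone ties at the cutoff
  ring <- directed_network(tibble::tibble(from = letters[1:5],
                                          to = letters[c(2:5, 1)]))
  expect_true(all(find_hub_candidates(ring, 0.75)$is_candidate))

  # scale-free network: candidate set equals the sort-and-count oracle
  nw <- generate_network(100, attachment_edges = 2, seed = 31)$network
  hc2 <- find_hub_candidates(nw, 0.75)
  deg <- hc2$degree
  cutoff <- empirical_quantile(deg[deg >= 1], 0.75)
  expect_equal(sum(hc2$is_candidate), sum(deg >= cutoff & deg >= 1))

  no_edges <- directed_network(tibble::tibble(from = character(), to = character()),
                               nodes = c("A", "B"))
  expect_error(find_hub_candidates(no_edges), "no edges")
})

test_that("subnetwork extraction follows the direction rule and matches BFS", {
  net <- chain_net()
  expect_equal(extract_subnetwork(net, "B", 1, "undirected"), c("A", "B", "C"))
  expect_equal(extract_subnetwork(net, "B", 1, "downstream"), c("B", "C"))
  expect_equal(extract_subnetwork(net, "B", 1, "upstream"), c("A", "B"))
  expect_error(extract_subnetwork(net, "Z"), "not in the network")

  set.seed(44)
  edges <- tibble::tibble(from = sample(sprintf("n%02d", 1:50), 120, replace = TRUE),
                          to = sample(sprintf("n%02d", 1:50), 120, replace = TRUE))
  edges <- edges[edges$from != edges$to, ]
  rnet <- directed_network(edges)
  for (dirn in c("undirected", "downstream", "upstream")) {
    for (ctr in sample(rnet$nodes, 5)) {
      expect_equal(extract_subnetwork(rnet, ctr, 2, dirn),
                   reference_bfs(rnet$edges, ctr, 2, dirn),
                   info = sprintf("%s from %s", dirn, ctr))
    }
  }
})

test_that("key-driver scoring honours its sign and degeneracy contracts", {
  nw <- generate_network(80, attachment_edges = 2, seed = 7)$network

  # disease set = all nodes: overlap saturates, null has zero spread
  res_all <- score_key_drivers(nw, nw$nodes, n_perm = 200, seed = 1)
  expect_true(all(res_all$results$flagged))
  expect_true(all(res_all$results$p_value == 1))

  # disease set disjoint from a candidate's subnetwork: z < 0, p > 0.5
  hc <- find_hub_candidates(nw)
  kd1 <- hc$gene[hc$is_candidate][1]
  sub1 <- extract_subnetwork(nw, kd1, 1)
  disjoint <- setdiff(nw$nodes, sub1)[1:30]
  res <- score_key_drivers(nw, disjoint, n_perm = 500, seed = 2)
  row <- res$results[res$results$kd_gene == kd1, ]
  expect_lt(row$z_score, 0)
  expect_gt(row$p_value, 0.5)

  expect_error(score_key_drivers(nw, "not_a_node", n_perm = 200, seed = 1),
               "does not intersect")
})

test_that("permutation null mean matches the hypergeometric expectation", {
  nw <- generate_network(200, attachment_edges = 2, seed = 3)$network
  set.seed(2)
  disease <- sample(nw$nodes, 40)
  res <- score_key_drivers(nw, disease, n_perm = 5000, seed = 11)
  expected <- res$results$n_subnetwork * 40 / length(nw$nodes)
  mc_se <- res$results$null_sd / sqrt(5000)
  expect_true(all(abs(res$results$null_mean - expected) <= 3 * mc_se + 1e-9))
})

test_that("planted key drivers score far above background hubs", {
  scn <- generate_scenario("full", seed = 13, params = fast_params)
  res <- score_key_drivers(scn$network, scn$truth$signal_genes,
                           n_perm = 2000, seed = 4)
  planted <- scn$truth$planted_kds
  ranks <- match(planted, res$results$kd_gene)
  expect_true(all(ranks <= length(planted) + 2))
  expect_true(all(res$results$p_value[ranks] < 0.001))
})

test_that("subnetwork export writes induced edges in SIF and GraphML", {
  net <- directed_network(tibble::tibble(from = c("A", "B", "C", "D"),
                                         to = c("B", "C", "D", "A")))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_subnetwork(net, c("A", "B", "C"), path = sif, format = "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), 2)          # A->B, B->C induced
  expect_setequal(lines, c("A\tregulates\tB", "B\tregulates\tC"))

  # induced edge count equals a brute-force filter of the full edge list
  nw <- generate_network(60, attachment_edges = 2, seed = 9)$network
  genes <- extract_subnetwork(nw, find_hub_candidates(nw)$gene[which.max(find_hub_candidates(nw)$degree)], 1)
  sif2 <- withr::local_tempfile(fileext = ".sif")
  export_subnetwork(nw, genes, path = sif2, format = "sif")
  induced <- nw$edges[nw$edges$from %in% genes & nw$edges$to %in% genes, ]
  expect_equal(sum(grepl("\tregulates\t", readLines(sif2))), nrow(induced))

  # GraphML round trip preserves node attributes
  ann <- tibble::tibble(gene_id = c("A", "B", "C"),
                        rare_level = c("1", NA, "3"),
                        common_score = c(2.5, 0.1, NA))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_subnetwork(net, c("A", "B", "C"), annotations = ann,
                    path = gml, format = "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("A", "B", "C"))
  expect_equal(igraph::vertex_attr(back, "rare_level")[match("A", igraph::V(back)$name)], "1")
  expect_equal(igraph::vertex_attr(back, "common_score")[match("A", igraph::V(back)$name)], 2.5)

  expect_error(export_subnetwork(net, c("A", "B"), path = sif, format = "dot"),
               "should be one of")
})
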