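# Marker-set enrichment: quantile scheme, chi statistic, permutation null.

test_that("quantile scheme spans 0.5 to 1 - 1/mu with equal spacing", {
  sch <- build_quantile_scheme(c(10, 20, 30), n = 10)
  expect_equal(sch$mu, 20)
  expect_equal(sch$q_upper, 0.95)
  expect_equal(sch$q_levels, seq(0.5, 0.95, by = 0.05))

  sch2 <- build_quantile_scheme(c(100, 100), n = 2)
  expect_equal(sch2$q_levels, c(0.5, 0.99))

  # even count: mean of the middle two sizes
  expect_equal(build_quantile_scheme(c(4, 10, 20, 100))$mu, 15)

  expect_warning(deg <- build_quantile_scheme(2, n = 10), "degenerates")
  expect_equal(deg$q_levels, 0.5)
  expect_error(build_quantile_scheme(c(10, 20), n = 0), "positive")
})

test_that("chi equals the direct summation on the worked 20-marker instance", {
  background <- tibble::tibble(marker_id = sprintf("s%02d", 1:20), score = 1:20)
  module <- sprintf("s%02d", 16:20)       # the top-5 scorers
  scheme <- build_quantile_scheme(c(4, 4), n = 2, kappa = 1, mu = 4)
  expect_equal(scheme$q_levels, c(0.5, 0.75))
  br <- compute_chi(module, background, scheme)
  expect_equal(br$quantiles$threshold, c(10.5, 15.5))
  expect_equal(br$quantiles$observed, c(5, 5))
  expected_chi <- (5 - 2.5) / (sqrt(2.5) + 1) + (5 - 1.25) / (sqrt(1.25) + 1)
  expect_equal(br$chi, expected_chi, tolerance = 1e-12)
  # additivity to 1e-12
  expect_equal(br$chi, sum(br$quantiles$term), tolerance = 1e-12)
})

test_that("chi breakdown satisfies its structural invariants", {
  set.seed(21)
  background <- tibble::tibble(marker_id = sprintf("s%03d", 1:200),
                               score = -log10(runif(200)))
  scheme <- build_quantile_scheme(c(10, 15, 20))
  module <- sample(background$marker_id, 30)
  br <- compute_chi(module, background, scheme)
  expect_true(all(diff(br$quantiles$observed) <= 0))   # O_i non-increasing
  expect_true(all(diff(br$quantiles$expected) <= 0))   # E_i non-increasing
  expect_equal(br$chi, sum(br$quantiles$term), tolerance = 1e-12)

  # module == whole background: O_i equals a brute-force recount
  br_all <- compute_chi(background$marker_id, background, scheme)
  recount <- vapply(br_all$quantiles$threshold,
                    function(t) sum(background$score > t), numeric(1))
  expect_equal(br_all$quantiles$observed, recount)

  # O = E exactly at a single median level gives chi = 0
  bg_even <- tibble::tibble(marker_id = sprintf("e%02d", 1:10), score = 1:10)
  sch1 <- suppressWarnings(build_quantile_scheme(2, n = 10))
  half <- compute_chi(c("e03", "e08"), bg_even, sch1)   # one above, one below
  expect_equal(half$chi, 0)

  expect_error(compute_chi(character(), background, scheme), "no markers")
  expect_error(compute_chi("nope", background, scheme), "absent from background")
})

test_that("raising a module marker's score never decreases chi at fixed thresholds", {
  set.seed(31)
  background <- tibble::tibble(marker_id = sprintf("s%03d", 1:150),
                               score = -log10(runif(150)))
  scheme <- build_quantile_scheme(c(8, 12, 16))
  thresholds <- empirical_quantile(background$score, scheme$q_levels)
  module <- sample(background$marker_id, 25)
  base_chi <- compute_chi(module, background, scheme, thresholds = thresholds)$chi
  for (i in 1:10) {
    bumped <- background
    target <- sample(module, 1)
    bumped$score[bumped$marker_id == target] <-
      bumped$score[bumped$marker_id == target] + runif(1, 0, 4)
    new_chi <- compute_chi(module, bumped, scheme, thresholds = thresholds)$chi
    expect_gte(new_chi, base_chi - 1e-12)
  }
})

make_null_msea <- function(seed, params = list()) {
  scn <- generate_scenario("null", seed = seed, params = utils::modifyList(fast_params, params))
  cl <- ld_clump(scn$markers, scn$ld)
  asg <- map_markers_to_genes(cl, scn$map, "synthetic")
  bg <- dplyr::filter(cl$markers, marker_id %in% asg$background)
  list(scn = scn, asg = asg, bg = bg)
}

test_that("permutation null is seeded, deterministic, and degenerate on flat scores", {
  d <- make_null_msea(4)
  scheme <- build_quantile_scheme(c(8, 10, 12))
  a <- null_chi_distribution(8, d$asg, d$bg, scheme, n_perm = 150, seed = 42)
  b <- null_chi_distribution(8, d$asg, d$bg, scheme, n_perm = 150, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, null_chi_distribution(8, d$asg, d$bg, scheme,
                                                  n_perm = 150, seed = 43)))

  # flat scores with equal marker counts per gene: every null draw pools the
  # same number of markers, sees zero positives, and lands on one constant
  asg_full <- map_markers_to_genes(d$scn$markers, d$scn$map, "synthetic")
  flat <- dplyr::mutate(d$scn$markers, score = 1)
  nulls <- null_chi_distribution(8, asg_full, flat, scheme, n_perm = 120, seed = 1)
  expect_equal(length(unique(nulls)), 1)

  expect_error(null_chi_distribution(8, d$asg, d$bg, scheme, n_perm = 50, seed = 1),
               "at least 100")
  expect_error(null_chi_distribution(1e6, d$asg, d$bg, scheme, n_perm = 100, seed = 1),
               "smaller")
})

test_that("on null data observed z-scores are centred near zero", {
  d <- make_null_msea(17)
  res <- score_modules(d$scn$modules, d$asg, d$bg, n_perm = 300, seed = 9,
                       min_genes = 3)
  zs <- res$results$z_score
  expect_equal(mean(zs), 0, tolerance = 0.45)  # ~N(0, 1/sqrt(10)) spread
  expect_true(all(res$results$fdr >= res$results$p_value))
})

test_that("planted modules reach small p-values and rank on top", {
  scn <- generate_scenario("full", seed = 23, params = fast_params)
  cl <- ld_clump(scn$markers, scn$ld)
  asg <- map_markers_to_genes(cl, scn$map, "synthetic")
  bg <- dplyr::filter(cl$markers, marker_id %in% asg$background)
  res <- score_modules(scn$modules, asg, bg, n_perm = 2000, seed = 5)
  planted <- scn$truth$planted_modules
  top <- res$results$set_id[seq_along(planted)]
  expect_setequal(top, planted)
  expect_true(all(res$results$p_value[res$results$set_id %in% planted] < 0.001))
})

test_that("module scoring respects the size floor and flags zero-spread nulls", {
  d <- make_null_msea(6)
  small_sets <- dplyr::bind_rows(
    d$scn$modules,
    tibble::tibble(set_id = "tiny", tissue = "synthetic",
                   gene_id = d$scn$modules$gene_id[1:2])
  )
  expect_warning(res <- score_modules(small_sets, d$asg, d$bg,
                                      n_perm = 150, seed = 2),
                 "skipped")
  expect_true("tiny" %in% res$skipped)

  # flat scores + equal marker counts per gene: null has zero spread
  asg_full <- map_markers_to_genes(d$scn$markers, d$scn$map, "synthetic")
  flat <- dplyr::mutate(d$scn$markers, score = 2)
  expect_message(res2 <- score_modules(d$scn$modules, asg_full, flat,
                                       n_perm = 150, seed = 2),
                 "zero-spread")
  expect_true(all(res2$results$p_value == 1))
  expect_true(all(res2$results$flagged))
})

test_that("BH adjustment matches worked examples and caps at one", {
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(1, 1)), c(1, 1))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, NA)), "missing")
})

test_that("BH agrees with the independent step-up definition on random vectors", {
  for (s in 1:50) {
    set.seed(s)
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(benjamini_hochberg(p), reference_bh(p), tolerance = 1e-12)
  }
})
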