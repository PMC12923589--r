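# Independent reference implementations used as oracles. These are written
# as literal, unoptimised transcriptions of the definitions and stay
# independent of the package's internal code paths.

# greedy LD clumping, step by step: process in descending score (ties by
# ascending id); retain unless r2 > threshold with an already-retained
# marker; assign removed markers to the earliest-retained dependent marker
reference_clump <- function(markers, ld_pairs, r2_threshold) {
  r2_of <- function(a, b) {
    hit <- ld_pairs[(ld_pairs$marker_a == a & ld_pairs$marker_b == b) |
                      (ld_pairs$marker_a == b & ld_pairs$marker_b == a), ]
    if (nrow(hit) == 0) 0 else max(hit$r2)
  }
  ord <- order(-markers$score, markers$marker_id)
  retained <- character()
  removed <- character()
  representative <- character()
  for (id in markers$marker_id[ord]) {
    rep_id <- NA_character_
    for (r in retained) {            # retention order
      if (r2_of(id, r) > r2_threshold) {
        rep_id <- r
        break
      }
    }
    if (is.na(rep_id)) {
      retained <- c(retained, id)
    } else {
      removed <- c(removed, id)
      representative <- c(representative, rep_id)
    }
  }
  list(retained = retained, removed = removed, representative = representative)
}

# breadth-first search reachability within `depth` steps
reference_bfs <- function(edges, center, depth, direction = "undirected") {
  step_neighbors <- function(node) {
    out <- edges$to[edges$from == node]
    inc <- edges$from[edges$to == node]
    switch(direction,
           undirected = c(out, inc),
           downstream = out,
           upstream = inc)
  }
  frontier <- center
  seen <- center
  for (d in seq_len(depth)) {
    nxt <- unique(unlist(lapply(frontier, step_neighbors)))
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
    if (length(frontier) == 0) break
  }
  sort(seen)
}

# Benjamini-Hochberg step-up written from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
reference_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hypergeometric upper tail from the combinatorial definition
reference_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# exhaustive enumeration over all size-n subsets of 1:N
reference_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
}

# exact one-sided rank-sum p by enumerating all rank assignments
reference_ranksum_greater <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  obs <- sum(rank(pooled)[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  stats_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n_a * (n_a + 1) / 2
  })
  mean(stats_all >= obs)
}

# small scenario parameters reused across suites to keep tests quick
fast_params <- list(n_markers = 1200, n_blocks = 600, n_genes = 120,
                    n_modules = 10, module_size_range = c(6, 12),
                    markers_per_gene = 5)
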