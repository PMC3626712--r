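test_that("combination-space counts follow the closed form", {
  expect_equal(es_count(4, 2), 54)
  expect_equal(es_total(2), 9)
  # independent arithmetic: direct summation
  expect_equal(es_count(5, 3), choose(5, 3) * 27)
  expect_equal(es_total(7), sum(choose(7, 2:7) * 3^(2:7)))
  expect_error(es_count(4, 1), "2 <= m <= n")
  expect_error(es_count(4, 5), "2 <= m <= n")
})

test_that("enumerate_combinations yields exactly the closed-form count", {
  for (n in 2:7) {
    for (m in 2:n) {
      combos <- enumerate_combinations(n, m)
      expect_length(combos, es_count(n, m))
      keys <- vapply(combos, function(cb)
        paste(c(cb$snp_indices, cb$genotype_pattern), collapse = ","),
        character(1))
      expect_equal(anyDuplicated(keys), 0L)
    }
  }
  # single-subset edge: n = m gives the 3^n pure pattern space
  expect_length(enumerate_combinations(3, 3), 27)
  expect_error(enumerate_combinations(3, 4), "1 <= m <= n_snps")
})

test_that("exhaustive_best agrees with a naive double-loop oracle", {
  for (seed in c(3, 17)) {
    d <- random_dataset(n_subjects = 25, n_snps = 4, seed = seed,
                        missing_rate = 0.05)
    for (direction in c("low_risk", "high_risk")) {
      got <- exhaustive_best(d, 2, direction)
      expect_equal(got$nodes_evaluated, es_count(4, 2))
      want <- brute_exhaustive_best(d, 2, direction)
      if (want$dv <= 0) {
        expect_equal(nrow(got$nodes), 0)
      } else {
        expect_equal(got$nodes$reported_diff[1], want$dv)
        # ranking is non-increasing
        expect_true(all(diff(got$nodes$reported_diff) <= 0))
      }
    }
  }
})

test_that("a planted overwhelming case enrichment ranks first", {
  p <- simulation_params(
    n_cases = 80, n_controls = 120, n_snps = 5,
    planted = list(combo = snp_combination(c(2, 4), c(3, 1)),
                   p_case = 0.95, p_control = 0.02), seed = 9)
  d <- simulate_dataset(p)
  top <- exhaustive_best(d, 2, "high_risk")$nodes[1, ]
  expect_equal(top$snps, "2,4")
  expect_equal(top$pattern, "3,1")
  expect_equal(top$direction, "high_risk")
})

test_that("expand_node children match full-dataset counts and obey bounds", {
  d <- random_dataset(n_subjects = 50, n_snps = 5, seed = 21,
                      missing_rate = 0.1)
  combo <- snp_combination(c(2, 4), c(1, 2))
  node <- list(combo = combo, counts = match_counts(d, combo))
  children <- expand_node(node, d, prune_empty = FALSE)
  expect_length(children, (5 - 2) * 3)
  for (ch in children) {
    full <- match_counts(d, ch$combo)
    expect_equal(ch$counts$controls_matched, full$controls_matched)
    expect_equal(ch$counts$cases_matched, full$cases_matched)
    expect_equal(ch$level, 3)
  }
  pruned <- expand_node(node, d, prune_empty = TRUE)
  keep <- vapply(children, function(ch)
    ch$counts$controls_matched + ch$counts$cases_matched > 0, logical(1))
  expect_length(pruned, sum(keep))

  # a parent matching nobody has no children under pruning
  dead <- list(combo = snp_combination(c(1, 2), c(3, 3)))
  d_const <- genotype_dataset(matrix(1L, 6, 3),
                              rep(c("case", "control"), 3))
  expect_length(expand_node(dead, d_const, prune_empty = TRUE), 0)
})

test_that("search output is deterministic and winners re-verify", {
  d <- random_dataset(n_subjects = 80, n_snps = 6, seed = 31)
  cfg <- search_config(max_order = 4)
  r1 <- ibbfs_search(d, cfg)
  r2 <- ibbfs_search(d, cfg)
  expect_identical(r1$results, r2$results)
  for (dir in names(r1$results)) {
    for (lr in r1$results[[dir]]) {
      expect_true(all(diff(lr$nodes$reported_diff) <= 0))
      for (i in seq_len(min(nrow(lr$nodes), 5))) {
        node <- lr$nodes[i, ]
        mc <- match_counts(d, snp_combination(
          as.integer(strsplit(node$snps, ",")[[1]]),
          as.integer(strsplit(node$pattern, ",")[[1]])))
        expect_equal(node$controls_matched, mc$controls_matched)
        expect_equal(node$cases_matched, mc$cases_matched)
      }
    }
  }
})

test_that("a constant genotype column dominates every level", {
  # All subjects share code 2 at SNP 3: any combination extending it has
  # the full cohort imbalance |N - C| while the column alone never splits.
  set.seed(77)
  g <- matrix(sample(1:3, 20 * 4, replace = TRUE), nrow = 20)
  g <- cbind(g, 2L)  # SNP 5 constant
  d <- genotype_dataset(g, c(rep("case", 12), rep("control", 8)))
  res <- ibbfs_search(d, search_config(direction = "high_risk"))
  for (lr in res$results$high_risk) {
    expect_lte(lr$nodes$reported_diff[1], abs(12 - 8) + 12)  # sanity ceiling
  }
  # level 2 winner restricted to {const SNP + most imbalanced partner}
  expect_true(grepl("5", res$results$high_risk[["2"]]$nodes$snps[1]) ||
                res$results$high_risk[["2"]]$nodes$reported_diff[1] >= 1)
})

test_that("infinite-beam search equals the exhaustive oracle per level", {
  for (seed in c(5, 23)) {
    d <- simulate_dataset(simulation_params(
      n_cases = 90, n_controls = 110, n_snps = 5,
      planted = list(combo = snp_combination(c(1, 3, 5), c(2, 1, 2)),
                     p_case = 0.4, p_control = 0.1), seed = seed))
    res <- ibbfs_search(d, search_config(beam_width_rule = "inf"))
    for (dir in c("low_risk", "high_risk")) {
      for (m in 2:5) {
        ib <- res$results[[dir]][[as.character(m)]]
        ex <- exhaustive_best(d, m, dir)
        if (nrow(ex$nodes) == 0) {
          expect_equal(nrow(ib$nodes), 0)
        } else {
          expect_equal(ib$nodes$snps[1], ex$nodes$snps[1])
          expect_equal(ib$nodes$pattern[1], ex$nodes$pattern[1])
          expect_equal(ib$nodes$reported_diff[1], ex$nodes$reported_diff[1])
        }
        expect_lte(ib$nodes_evaluated, ex$nodes_evaluated)
      }
    }
  }
})

test_that("the default beam is sound: never above the exhaustive optimum", {
  d <- random_dataset(n_subjects = 100, n_snps = 6, seed = 41)
  res <- ibbfs_search(d, search_config())  # r = n - m + 1
  for (dir in c("low_risk", "high_risk")) {
    for (m in names(res$results[[dir]])) {
      ib <- res$results[[dir]][[m]]
      ex <- exhaustive_best(d, as.integer(m), dir)
      ib_best <- if (nrow(ib$nodes) > 0) ib$nodes$reported_diff[1] else 0
      ex_best <- if (nrow(ex$nodes) > 0) ex$nodes$reported_diff[1] else 0
      expect_lte(ib_best, ex_best)
      expect_lte(ib$nodes_evaluated, ex$nodes_evaluated)
    }
  }
})

test_that("search_config rejects invalid settings", {
  expect_error(search_config(min_order = 1), "min_order")
  expect_error(search_config(min_order = 3, max_order = 2), "max_order")
  expect_error(search_config(beam_width_rule = "bogus"), "beam_width_rule")
  d <- random_dataset(20, 3, seed = 1)
  expect_error(
    ibbfs_search(d, search_config(beam_width_rule = function(n, m) 0)),
    "width < 1")
})
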