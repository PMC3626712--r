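#' Size of the exhaustive combination space
#'
#' `es_count(n, m)` is the number of genotype combinations of order `m` over
#' `n` biallelic SNPs, `choose(n, m) * 3^m` (each selected SNP contributes
#' three genotype states).  `es_total(n)` sums the counts over orders
#' `m = 2, ..., n` — the full cost of an exhaustive interaction search.
#'
#' @param n total number of SNPs (>= 2).
#' @param m combination order, `2 <= m <= n` (for `es_count`; order 1 is
#'   allowed by [enumerate_combinations()] but is not an interaction).
#' @return integer-valued numeric count.
#' @examples
#' es_count(4, 2)  # 54
#' es_total(7)     # 16362
#' @export
es_count <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (length(n) != 1 || length(m) != 1 || is.na(n) || is.na(m)) {
    stop("n and m must be single integers")
  }
  if (n < 2 || m < 2 || m > n) stop("need 2 <= m <= n")
  choose(n, m) * 3^m
}

#' @rdname es_count
#' @export
es_total <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || n < 2) stop("n must be an integer >= 2")
  sum(vapply(2:n, function(m) es_count(n, m), numeric(1)))
}

# All 3^m genotype patterns of length m, one per row, lexicographic order
# (last position varies fastest).
subset_patterns <- function(m) {
  as.matrix(rev(expand.grid(rev(lapply(seq_len(m), function(i) 1:3)))))
}

#' Enumerate all genotype combinations of a given order
#'
#' Yields every [snp_combination()] of `m` SNPs out of `n_snps`, in
#' deterministic lexicographic order (SNP subsets in [combn()] order, and
#' within a subset the 3^m genotype patterns with the last SNP varying
#' fastest).  The length of the result equals `es_count(n_snps, m)` for
#' `m >= 2`.
#'
#' @param n_snps total number of SNP columns.
#' @param m combination order, `1 <= m <= n_snps`.
#' @return list of [snp_combination()] objects.
#' @export
enumerate_combinations <- function(n_snps, m) {
  n_snps <- as.integer(n_snps); m <- as.integer(m)
  if (m < 1 || m > n_snps) stop("need 1 <= m <= n_snps")
  subsets <- combn(n_snps, m)
  patterns <- subset_patterns(m)
  out <- vector("list", ncol(subsets) * nrow(patterns))
  k <- 1L
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    for (p in seq_len(nrow(patterns))) {
      out[[k]] <- snp_combination(idx, patterns[p, ])
      k <- k + 1L
    }
  }
  out
}

# Match counts for every genotype pattern of one SNP subset at once.
# Returns a data.frame with 3^m rows: pattern key (lexicographic position),
# controls, cases.  Rows with a missing code at any subset SNP match nothing.
eval_subset <- function(dataset, idx) {
  m <- length(idx)
  g <- dataset$genotypes[, idx, drop = FALSE]
  complete <- rowSums(g == 0) == 0
  w <- 3^((m - 1):0)
  key <- as.vector((g - 1) %*% w) + 1L
  is_case <- dataset$phenotype == "case"
  nb <- 3^m
  data.frame(
    key = seq_len(nb),
    controls = tabulate(key[complete & !is_case], nbins = nb),
    cases = tabulate(key[complete & is_case], nbins = nb)
  )
}

# Build the internal node table for one subset from eval_subset output.
subset_nodes <- function(idx, ev) {
  patterns <- subset_patterns(length(idx))
  data.frame(
    snps = paste(idx, collapse = ","),
    pattern = apply(patterns, 1, paste, collapse = ","),
    controls_matched = ev$controls,
    cases_matched = ev$cases,
    stringsAsFactors = FALSE
  )
}

# Direction value: positive when the node points the requested way.
direction_value <- function(signed_diff, direction) {
  if (direction == "low_risk") signed_diff else -signed_diff
}

# Sortable fixed-width keys for deterministic tie-breaking
# (smaller SNP-index tuple first, then smaller genotype-pattern tuple).
tuple_key <- function(s) {
  vapply(strsplit(s, ","), function(v)
    paste(sprintf("%04d", as.integer(v)), collapse = ","), character(1))
}

# Rank a node table for one direction: direction value descending, then
# index tuple, then pattern tuple.  Returns the permuted table with added
# signed_diff / reported_diff / direction / dv columns.
rank_nodes <- function(nodes, direction) {
  nodes$signed_diff <- nodes$controls_matched - nodes$cases_matched
  nodes$reported_diff <- abs(nodes$signed_diff)
  nodes$direction <- ifelse(nodes$signed_diff > 0, "low_risk",
                            ifelse(nodes$signed_diff < 0, "high_risk", "neutral"))
  nodes$dv <- direction_value(nodes$signed_diff, direction)
  ord <- order(-nodes$dv, tuple_key(nodes$snps), tuple_key(nodes$pattern))
  nodes[ord, , drop = FALSE]
}

#' Per-level search result
#'
#' Ranked winners of one search level in one risk direction, best-first by
#' reported difference with deterministic tie-breaking (smaller SNP-index
#' tuple, then smaller genotype-pattern tuple).
#'
#' @param level combination order m.
#' @param direction `"low_risk"` or `"high_risk"`.
#' @param nodes data.frame of winning nodes with columns `snps`, `pattern`,
#'   `controls_matched`, `cases_matched`, `signed_diff`, `reported_diff`,
#'   `direction`.
#' @param nodes_evaluated number of combinations whose counts were computed
#'   at this level.
#' @return object of class `level_result`.
#' @keywords internal
level_result <- function(level, direction, nodes, nodes_evaluated) {
  nodes$dv <- NULL
  rownames(nodes) <- NULL
  structure(list(level = level, direction = direction, nodes = nodes,
                 nodes_evaluated = nodes_evaluated),
            class = "level_result")
}

#' @export
print.level_result <- function(x, ...) {
  cat("level ", x$level, " (", x$direction, "): ", nrow(x$nodes),
      " winners, ", x$nodes_evaluated, " nodes evaluated\n", sep = "")
  if (nrow(x$nodes) > 0) {
    print(utils::head(x$nodes, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Exhaustive search over all combinations of one order
#'
#' Evaluates every genotype combination of order `m` and returns the ranked
#' winners for the requested risk direction.  This is the oracle the
#' branch-and-bound search is measured against: its top node is the global
#' optimum for that order and direction.
#'
#' @param dataset a [genotype_dataset()].
#' @param order combination order m, `2 <= m <= n_snps(dataset)` (order 1 is
#'   also accepted for single-SNP screens).
#' @param direction `"low_risk"` (control excess) or `"high_risk"` (case
#'   excess).
#' @param top_k maximum number of winners to keep (default all).
#' @return a `level_result`; `nodes_evaluated` equals
#'   `es_count(n_snps, order)` for `order >= 2`.
#' @export
exhaustive_best <- function(dataset, order,
                            direction = c("low_risk", "high_risk"),
                            top_k = Inf) {
  check_dataset(dataset)
  direction <- match.arg(direction)
  order <- as.integer(order)
  n <- n_snps(dataset)
  if (order < 1 || order > n) stop("order must be between 1 and ", n)
  subsets <- combn(n, order)
  nodes <- do.call(rbind, lapply(seq_len(ncol(subsets)), function(s) {
    idx <- subsets[, s]
    subset_nodes(idx, eval_subset(dataset, idx))
  }))
  ranked <- rank_nodes(nodes, direction)
  winners <- ranked[ranked$dv > 0, , drop = FALSE]
  if (is.finite(top_k)) winners <- utils::head(winners, top_k)
  level_result(order, direction, winners,
               nodes_evaluated = ncol(subsets) * 3^order)
}

#' Search configuration
#'
#' @param min_order first (exhaustively evaluated) combination order;
#'   default 2 — the search is anchored on the full two-SNP scan.
#' @param max_order last order; default the number of SNPs.
#' @param direction `"both"`, `"low_risk"` or `"high_risk"`.  Directions are
#'   searched with independent beams so one cannot starve the other.
#' @param beam_width_rule retained combinations per level: `"paper"` (the
#'   feature-selection rule r = n - m + 1, where n is the SNP count and m the
#'   current order), `"inf"` (keep everything: exhaustive, for oracle
#'   comparisons), a single positive integer, or a `function(n, m)`.
#' @param prune_empty drop combinations matching zero cases and zero
#'   controls (default TRUE); such nodes can never lead to a nonzero bound.
#' @param cutoff_bound B: winners must have an absolute signed difference
#'   strictly greater than B (default 0, i.e. neutral nodes are never
#'   winners).
#' @return object of class `search_config`.
#' @export
search_config <- function(min_order = 2, max_order = NULL,
                          direction = c("both", "low_risk", "high_risk"),
                          beam_width_rule = "paper", prune_empty = TRUE,
                          cutoff_bound = 0) {
  direction <- match.arg(direction)
  min_order <- as.integer(min_order)
  if (min_order < 2) stop("min_order must be >= 2")
  if (!is.null(max_order)) {
    max_order <- as.integer(max_order)
    if (max_order < min_order) stop("max_order must be >= min_order")
  }
  rule <- beam_rule_function(beam_width_rule)
  structure(list(min_order = min_order, max_order = max_order,
                 direction = direction, beam_width_rule = beam_width_rule,
                 beam_fn = rule, prune_empty = isTRUE(prune_empty),
                 cutoff_bound = as.integer(cutoff_bound)),
            class = "search_config")
}

beam_rule_function <- function(rule) {
  if (is.function(rule)) return(rule)
  if (identical(rule, "paper")) return(function(n, m) n - m + 1)
  if (identical(rule, "inf")) return(function(n, m) Inf)
  width <- suppressWarnings(as.numeric(rule))
  if (length(width) == 1 && !is.na(width) && width >= 1) {
    return(function(n, m) width)
  }
  stop("beam_width_rule must be 'paper', 'inf', a positive integer, ",
       "or a function(n, m)")
}

#' Branch-and-bound search with level-wise feature selection
#'
#' Level-wise beam search over genotype combinations.  The first level
#' (`min_order`, default 2) is evaluated exhaustively; at each later level
#' the top-r surviving combinations per direction (r from the beam width
#' rule, default r = n - m + 1) are expanded by appending every unused SNP
#' with each of its three genotype codes, keeping the parent pattern fixed
#' (anchored expansion).  Children matching zero cases and zero controls are
#' cut off; children whose absolute bound does not exceed the cutoff bound B
#' are never winners, although they may ride in the beam.  Ranking and
#' tie-breaks are deterministic, so the output is a pure function of the
#' dataset and configuration.
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [search_config()].
#' @return object of class `ibbfs_result`: list with `config`, `n_snps`,
#'   `results` (nested: `results[[direction]][[as.character(level)]]`, each a
#'   `level_result`), and `nodes_evaluated` (data.frame direction x level).
#' @examples
#' p <- simulation_params(n_cases = 60, n_controls = 60, n_snps = 5,
#'                        planted = list(combo = snp_combination(c(1, 3), c(2, 2)),
#'                                       p_case = 0.6, p_control = 0.1),
#'                        seed = 7)
#' res <- ibbfs_search(simulate_dataset(p), search_config(max_order = 3))
#' res$results$high_risk[["2"]]$nodes[1, ]
#' @export
ibbfs_search <- function(dataset, config = search_config()) {
  check_dataset(dataset)
  if (!inherits(config, "search_config")) stop("expected a search_config")
  n <- n_snps(dataset)
  min_order <- config$min_order
  max_order <- if (is.null(config$max_order)) n else min(config$max_order, n)
  if (min_order > n) stop("min_order exceeds the number of SNPs (", n, ")")
  dirs <- if (config$direction == "both") c("low_risk", "high_risk") else config$direction
  B <- config$cutoff_bound

  # Exhaustive base level, shared by both directions.
  subsets <- combn(n, min_order)
  base_nodes <- do.call(rbind, lapply(seq_len(ncol(subsets)), function(s) {
    idx <- subsets[, s]
    subset_nodes(idx, eval_subset(dataset, idx))
  }))
  base_evaluated <- ncol(subsets) * 3^min_order

  results <- list()
  telemetry <- list()
  for (dir in dirs) {
    levels <- list()
    ranked <- rank_nodes(base_nodes, dir)
    if (config$prune_empty) {
      ranked <- ranked[ranked$controls_matched + ranked$cases_matched > 0, ,
                       drop = FALSE]
    }
    winners <- ranked[ranked$dv > B, , drop = FALSE]
    levels[[as.character(min_order)]] <-
      level_result(min_order, dir, winners, base_evaluated)
    telemetry[[length(telemetry) + 1]] <-
      data.frame(direction = dir, level = min_order,
                 nodes_evaluated = base_evaluated)

    beam <- beam_head(ranked, config$beam_fn(n, min_order))
    m <- min_order
    while (m < max_order && nrow(beam) > 0) {
      m <- m + 1L
      kids <- candidate_children(beam, n)
      if (nrow(kids) == 0) break
      evald <- evaluate_children(dataset, kids)
      n_eval <- nrow(evald)
      if (config$prune_empty) {
        evald <- evald[evald$controls_matched + evald$cases_matched > 0, ,
                       drop = FALSE]
      }
      ranked <- rank_nodes(evald, dir)
      winners <- ranked[ranked$dv > B, , drop = FALSE]
      levels[[as.character(m)]] <- level_result(m, dir, winners, n_eval)
      telemetry[[length(telemetry) + 1]] <-
        data.frame(direction = dir, level = m, nodes_evaluated = n_eval)
      beam <- beam_head(ranked, config$beam_fn(n, m))
    }
    results[[dir]] <- levels
  }
  structure(list(config = config, n_snps = n, results = results,
                 nodes_evaluated = do.call(rbind, telemetry)),
            class = "ibbfs_result")
}

beam_head <- function(ranked, width) {
  if (width < 1) stop("beam width rule returned a width < 1")
  if (is.infinite(width)) ranked else utils::head(ranked, floor(width))
}

# Distinct (subset, pattern) children of a beam: each parent extended by
# every unused SNP with each of its 3 codes, parent pattern preserved.
candidate_children <- function(beam, n) {
  if (nrow(beam) == 0) {
    return(data.frame(snps = character(), pattern = character()))
  }
  rows <- vector("list", nrow(beam))
  for (i in seq_len(nrow(beam))) {
    idx <- as.integer(strsplit(beam$snps[i], ",")[[1]])
    pat <- as.integer(strsplit(beam$pattern[i], ",")[[1]])
    unused <- setdiff(seq_len(n), idx)
    if (length(unused) == 0) next
    kid_list <- vector("list", length(unused) * 3L)
    k <- 1L
    for (j in unused) {
      pos <- findInterval(j, idx)  # insert after this many parent SNPs
      new_idx <- append(idx, j, after = pos)
      for (code in 1:3) {
        new_pat <- append(pat, code, after = pos)
        kid_list[[k]] <- c(paste(new_idx, collapse = ","),
                           paste(new_pat, collapse = ","))
        k <- k + 1L
      }
    }
    rows[[i]] <- do.call(rbind, kid_list)
  }
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows)) {
    return(data.frame(snps = character(), pattern = character()))
  }
  kids <- data.frame(snps = all_rows[, 1], pattern = all_rows[, 2],
                     stringsAsFactors = FALSE)
  kids[!duplicated(paste(kids$snps, kids$pattern, sep = "|")), , drop = FALSE]
}

# Count matches for a set of children, grouping by SNP subset so each
# subset's genotype table is tallied once.
evaluate_children <- function(dataset, kids) {
  out <- kids
  out$controls_matched <- NA_integer_
  out$cases_matched <- NA_integer_
  for (s in unique(kids$snps)) {
    rows <- which(kids$snps == s)
    idx <- as.integer(strsplit(s, ",")[[1]])
    ev <- eval_subset(dataset, idx)
    m <- length(idx)
    w <- 3^((m - 1):0)
    keys <- vapply(strsplit(kids$pattern[rows], ","), function(p)
      sum((as.integer(p) - 1) * w) + 1, numeric(1))
    out$controls_matched[rows] <- ev$controls[keys]
    out$cases_matched[rows] <- ev$cases[keys]
  }
  out
}

#' @export
print.ibbfs_result <- function(x, ...) {
  cat("ibbfs_result over", x$n_snps, "SNPs\n")
  for (dir in names(x$results)) {
    for (lev in names(x$results[[dir]])) {
      lr <- x$results[[dir]][[lev]]
      top <- if (nrow(lr$nodes) > 0) {
        paste0("SNPs (", gsub(",", ", ", lr$nodes$snps[1]), ") ",
               gsub(",", "-", lr$nodes$pattern[1]),
               " Diff. = ", lr$nodes$reported_diff[1])
      } else "none"
      cat(sprintf("  %-9s level %s: best %s (%d nodes evaluated)\n",
                  dir, lev, top, lr$nodes_evaluated))
    }
  }
  invisible(x)
}

#' Expand one search node
#'
#' Generates the children of a combination by appending every unused SNP
#' with each of its three genotype codes.  Child counts are tallied over the
#' parent's matched subjects only (matching is anti-monotone: a child can
#' only match a subset of its parent's matches), which makes expansion cost
#' proportional to the parent's support; the resulting counts are identical
#' to a full-dataset scan of each child.
#'
#' @param node a list with element `combo` (an [snp_combination()]); other
#'   elements are ignored.
#' @param dataset a [genotype_dataset()].
#' @param prune_empty drop children matching zero cases and zero controls.
#' @return list of child nodes, each a list with `combo`, `counts`
#'   (`match_counts`), `bound` (`bound_value`), `level`, `parent` (the
#'   parent combination).
#' @export
expand_node <- function(node, dataset, prune_empty = TRUE) {
  check_dataset(dataset)
  combo <- node$combo
  if (!inherits(combo, "snp_combination")) {
    stop("node$combo must be an snp_combination")
  }
  n <- n_snps(dataset)
  if (length(combo$snp_indices) >= n) stop("node is already at the maximum order")
  matched <- match_rows(dataset$genotypes, combo$snp_indices,
                        combo$genotype_pattern)
  is_case <- dataset$phenotype == "case"
  children <- list()
  for (j in setdiff(seq_len(n), combo$snp_indices)) {
    gj <- dataset$genotypes[matched, j]
    cj <- is_case[matched]
    for (code in 1:3) {
      controls <- sum(gj == code & !cj)
      cases <- sum(gj == code & cj)
      if (prune_empty && controls + cases == 0) next
      pos <- findInterval(j, combo$snp_indices)
      child_combo <- snp_combination(
        append(combo$snp_indices, j, after = pos),
        append(combo$genotype_pattern, code, after = pos)
      )
      counts <- new_match_counts(controls, cases)
      children[[length(children) + 1]] <- list(
        combo = child_combo, counts = counts, bound = bound_value(counts),
        level = length(child_combo$snp_indices), parent = combo
      )
    }
  }
  children
}
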