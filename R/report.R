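#' Run configuration for the command-line workflows
#'
#' Collects every setting the reporting entry points ([run_search()],
#' [run_exhaustive()], [run_pair_grid()], [run_simulate()]) need.  Flags of
#' the shell interface map 1:1 onto these fields.
#'
#' @param input path to a genotype table (not needed by `run_simulate`).
#' @param dialect input dialect, see [read_genotype_table()].
#' @param min_order,max_order,direction,beam_width_rule,prune_empty,cutoff_bound
#'   search settings, see [search_config()].
#' @param top_k winners reported per level (default 3, the "top three
#'   maximum difference combinations" convention).
#' @param ci_method,p_method,zero_correction statistics settings, see
#'   [combination_metrics()].
#' @param digits report rounding (decimal places, default 3).
#' @param out_dir directory for report files (created if absent).
#' @param seed seed for the simulate subcommand.
#' @param sim a [simulation_params()] object for [run_simulate()].
#' @param es_cap refuse exhaustive runs whose total combination count
#'   exceeds this cap (default 10^6).
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, dialect = "csv", min_order = 2,
                       max_order = NULL, direction = "both",
                       beam_width_rule = "paper", prune_empty = TRUE,
                       cutoff_bound = 0, top_k = 3, ci_method = "exact",
                       p_method = "fisher", zero_correction = FALSE,
                       digits = 3, out_dir = ".", seed = 1, sim = NULL,
                       es_cap = 1e6) {
  if (top_k < 1) stop("top_k must be >= 1")
  structure(list(
    input = input, dialect = dialect,
    search = search_config(min_order = min_order, max_order = max_order,
                           direction = direction,
                           beam_width_rule = beam_width_rule,
                           prune_empty = prune_empty,
                           cutoff_bound = cutoff_bound),
    top_k = as.integer(top_k), ci_method = ci_method, p_method = p_method,
    zero_correction = isTRUE(zero_correction), digits = as.integer(digits),
    out_dir = out_dir, seed = as.integer(seed), sim = sim, es_cap = es_cap
  ), class = "run_config")
}

load_input <- function(config) {
  if (is.null(config$input)) stop("config has no input path")
  read_genotype_table(config$input, config$dialect)
}

# One report row per winner: counts, "Other" row, diff, metric battery.
report_rows <- function(level_res, dataset, config, top_k) {
  nodes <- utils::head(level_res$nodes, top_k)
  C <- n_cases(dataset); N <- n_controls(dataset)
  d <- config$digits
  rows <- lapply(seq_len(nrow(nodes)), function(i) {
    node <- nodes[i, ]
    counts <- list(controls_matched = node$controls_matched,
                   cases_matched = node$cases_matched)
    met <- combination_metrics(
      pattern_vs_rest_table(counts, C, N),
      ci_method = config$ci_method, p_method = config$p_method,
      zero_correction = config$zero_correction
    )
    idx <- as.integer(strsplit(node$snps, ",")[[1]])
    data.frame(
      level = level_res$level,
      direction = level_res$direction,
      snp_indices = node$snps,
      snp_names = paste(dataset$snp_names[idx], collapse = ","),
      genotype_pattern = gsub(",", "-", node$pattern),
      controls_matched = node$controls_matched,
      cases_matched = node$cases_matched,
      other_controls = N - node$controls_matched,
      other_cases = C - node$cases_matched,
      diff = node$reported_diff,
      CC = format_ne(met$cc, d), SN = format_ne(met$sn, d),
      SP = format_ne(met$sp, d), Average = format_ne(met$average, d),
      OR = format_ne(met$odds_ratio, d),
      CI_low = format_ne(met$ci_lower, d),
      CI_high = format_ne(met$ci_upper, d),
      p_value = format_ne(met$p_value, d),
      nodes_evaluated = level_res$nodes_evaluated,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

write_report_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_sidecar <- function(path, extra = list()) {
  info <- c(list(package = "ibbfs",
                 version = as.character(packageVersion("ibbfs")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the branch-and-bound search and write per-direction reports
#'
#' Reads the configured genotype table, runs [ibbfs_search()], and writes
#' one TSV per direction (`search_low_risk.tsv` / `search_high_risk.tsv`)
#' listing the top winners per level with their full metric battery, plus a
#' JSON provenance sidecar.  "N.E" marks not-estimable statistics.
#'
#' @param config a [run_config()]; `dataset` may be passed directly to skip
#'   file input.
#' @param dataset optional [genotype_dataset()] overriding `config$input`.
#' @return invisibly, a list with the `ibbfs_result`, per-direction report
#'   data.frames (`reports`), and written file paths (`files`).
#' @export
run_search <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- load_input(config)
  check_dataset(dataset)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- ibbfs_search(dataset, config$search)
  reports <- list()
  files <- character()
  for (dir in names(result$results)) {
    rows <- lapply(result$results[[dir]],
                   report_rows, dataset = dataset, config = config,
                   top_k = config$top_k)
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0) {
      warning("no ", dir, " winners found (no variation in this direction)")
      df <- empty_report()
    }
    path <- file.path(config$out_dir, paste0("search_", dir, ".tsv"))
    write_report_tsv(df, path)
    reports[[dir]] <- df
    files <- c(files, path)
  }
  files <- c(files, write_sidecar(
    file.path(config$out_dir, "search_run.json"),
    list(input = if (is.null(config$input)) "in-memory" else config$input,
         n_subjects = length(dataset$subject_ids),
         n_cases = n_cases(dataset), n_controls = n_controls(dataset),
         n_snps = n_snps(dataset),
         nodes_evaluated = result$nodes_evaluated)
  ))
  invisible(list(result = result, reports = reports, files = files))
}

empty_report <- function() {
  cols <- c("level", "direction", "snp_indices", "snp_names",
            "genotype_pattern", "controls_matched", "cases_matched",
            "other_controls", "other_cases", "diff", "CC", "SN", "SP",
            "Average", "OR", "CI_low", "CI_high", "p_value",
            "nodes_evaluated")
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

#' 3x3 odds-ratio grid for one SNP pair
#'
#' For each of the nine genotype-code pairs of two SNPs, computes the
#' pattern-versus-rest odds ratio, exact CI and p-value, with "N.E" for
#' cells that are empty or have a zero contingency cell.  With no missing
#' data the nine (cases, controls) cells partition the cohort.
#'
#' @param config a [run_config()].
#' @param snp_a,snp_b distinct 1-based SNP indices.
#' @param dataset optional [genotype_dataset()] overriding `config$input`.
#' @return invisibly, the grid data.frame (also written to
#'   `pair_grid_<a>_<b>.tsv` under `config$out_dir`).
#' @export
run_pair_grid <- function(config, snp_a, snp_b, dataset = NULL) {
  if (is.null(dataset)) dataset <- load_input(config)
  check_dataset(dataset)
  snp_a <- as.integer(snp_a); snp_b <- as.integer(snp_b)
  if (snp_a == snp_b) stop("snp_a and snp_b must be distinct")
  if (max(snp_a, snp_b) > n_snps(dataset) || min(snp_a, snp_b) < 1) {
    stop("SNP index out of range")
  }
  C <- n_cases(dataset); N <- n_controls(dataset)
  d <- config$digits
  lo <- min(snp_a, snp_b); hi <- max(snp_a, snp_b)
  rows <- list()
  for (code_a in 1:3) for (code_b in 1:3) {
    pat <- if (snp_a < snp_b) c(code_a, code_b) else c(code_b, code_a)
    counts <- match_counts(dataset, snp_combination(c(lo, hi), pat))
    met <- combination_metrics(
      pattern_vs_rest_table(counts, C, N),
      ci_method = config$ci_method, p_method = config$p_method,
      zero_correction = config$zero_correction
    )
    rows[[length(rows) + 1]] <- data.frame(
      snp_a = dataset$snp_names[snp_a], genotype_a = code_a,
      snp_b = dataset$snp_names[snp_b], genotype_b = code_b,
      cases = counts$cases_matched, controls = counts$controls_matched,
      OR = format_ne(met$odds_ratio, d),
      CI_low = format_ne(met$ci_lower, d),
      CI_high = format_ne(met$ci_upper, d),
      p_value = format_ne(met$p_value, d),
      stringsAsFactors = FALSE
    )
  }
  grid <- do.call(rbind, rows)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir,
                    paste0("pair_grid_", snp_a, "_", snp_b, ".tsv"))
  write_report_tsv(grid, path)
  invisible(grid)
}

#' Exhaustive search with node-count comparison
#'
#' Runs [exhaustive_best()] for every order in the configured range and both
#' directions, writes the same report schema as [run_search()], and an
#' additional `nodes_comparison.tsv` contrasting the exhaustive node counts
#' with those of a branch-and-bound run under the configured beam.  Refuses
#' to run when the total exhaustive combination count exceeds
#' `config$es_cap`.
#'
#' @inheritParams run_search
#' @return invisibly, list with `reports`, `comparison` and `files`.
#' @export
run_exhaustive <- function(config, dataset = NULL) {
  if (is.null(dataset)) dataset <- load_input(config)
  check_dataset(dataset)
  n <- n_snps(dataset)
  min_order <- config$search$min_order
  max_order <- if (is.null(config$search$max_order)) n else
    min(config$search$max_order, n)
  total <- sum(vapply(min_order:max_order, function(m) es_count(n, m),
                      numeric(1)))
  if (total > config$es_cap) {
    stop("exhaustive search would evaluate ", total,
         " combinations, above the configured cap of ", config$es_cap)
  }
  dirs <- if (config$search$direction == "both") {
    c("low_risk", "high_risk")
  } else config$search$direction
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ibbfs <- ibbfs_search(dataset, config$search)
  reports <- list()
  files <- character()
  for (dir in dirs) {
    rows <- lapply(min_order:max_order, function(m) {
      report_rows(exhaustive_best(dataset, m, dir), dataset, config,
                  config$top_k)
    })
    df <- do.call(rbind, rows)
    path <- file.path(config$out_dir, paste0("exhaustive_", dir, ".tsv"))
    write_report_tsv(df, path)
    reports[[dir]] <- df
    files <- c(files, path)
  }
  comparison <- ibbfs$nodes_evaluated
  names(comparison)[names(comparison) == "nodes_evaluated"] <- "ibbfs_nodes"
  comparison$es_nodes <- vapply(comparison$level,
                                function(m) es_count(n, m), numeric(1))
  path <- file.path(config$out_dir, "nodes_comparison.tsv")
  write_report_tsv(comparison, path)
  files <- c(files, path)
  invisible(list(reports = reports, comparison = comparison, files = files))
}

#' Simulate a dataset and write it with a provenance sidecar
#'
#' @param config a [run_config()] whose `sim` field holds a
#'   [simulation_params()] object; `config$seed` overrides the params seed,
#'   and the output dialect follows `config$dialect`.
#' @return invisibly, list with the dataset and written file paths.
#' @export
run_simulate <- function(config) {
  if (!inherits(config$sim, "simulation_params")) {
    stop("config$sim must be a simulation_params object")
  }
  params <- config$sim
  params$seed <- config$seed
  dataset <- simulate_dataset(params)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(config$dialect, csv = "csv", tsv = "tsv", plink_raw = "raw")
  data_path <- file.path(config$out_dir, paste0("simulated.", ext))
  write_genotype_table(dataset, data_path, config$dialect)
  planted <- params$planted
  sidecar <- write_sidecar(
    file.path(config$out_dir, "simulated.json"),
    list(seed = params$seed, n_cases = params$n_cases,
         n_controls = params$n_controls, n_snps = params$n_snps,
         missing_rate = params$missing_rate,
         planted = if (is.null(planted)) NULL else list(
           snp_indices = planted$combo$snp_indices,
           genotype_pattern = planted$combo$genotype_pattern,
           p_case = planted$p_case, p_control = planted$p_control))
  )
  invisible(list(dataset = dataset, files = c(data_path, sidecar)))
}
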