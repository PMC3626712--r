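#' 2x2 contingency table
#'
#' Cells follow the epidemiological convention used throughout the package:
#' TP = cases in the exposed stratum (e.g. matching a genotype combination),
#' FP = controls in the exposed stratum, FN = the remaining ("Other") cases,
#' TN = the remaining controls.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  cells <- vapply(cells, as.integer, integer(1))
  if (anyNA(cells) || any(cells < 0)) {
    stop("all contingency cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(c("exposed", "other"), c("cases", "controls")))
  print(m)
  invisible(x)
}

as_table_matrix <- function(table) {
  matrix(c(table$tp, table$fn, table$fp, table$tn), nrow = 2)
}

#' Pattern-versus-rest contingency table
#'
#' Compares the subjects matching a genotype combination against everyone
#' else: TP = matching cases, FP = matching controls, FN = C - TP,
#' TN = N - FP, so rows re-sum to the cohort totals.
#'
#' @param counts a [match_counts()] result (or list with fields
#'   `controls_matched`, `cases_matched`).
#' @param n_cases cohort case total C.
#' @param n_controls cohort control total N.
#' @return a [contingency_table()].
#' @examples
#' pattern_vs_rest_table(list(controls_matched = 4, cases_matched = 11),
#'                       n_cases = 220, n_controls = 334)
#' @export
pattern_vs_rest_table <- function(counts, n_cases, n_controls) {
  tp <- as.integer(counts$cases_matched)
  fp <- as.integer(counts$controls_matched)
  if (tp > n_cases || fp > n_controls) {
    stop("matched counts exceed the cohort totals")
  }
  contingency_table(tp = tp, fp = fp, fn = n_cases - tp, tn = n_controls - fp)
}

#' Genotype-versus-reference contingency table
#'
#' Single-SNP association table comparing one genotype stratum against the
#' reference stratum (code 1 by default): TP = cases with `genotype_code`,
#' FP = controls with `genotype_code`, FN = cases with `reference_code`,
#' TN = controls with `reference_code`.  Subjects with any other code
#' (including missing) are excluded.
#'
#' @param dataset a [genotype_dataset()].
#' @param snp_index 1-based SNP column.
#' @param genotype_code code of the stratum under test, in 1:3.
#' @param reference_code reference stratum code, in 1:3 (default 1).
#' @return a [contingency_table()].
#' @export
genotype_vs_reference_table <- function(dataset, snp_index, genotype_code,
                                        reference_code = 1) {
  genotype_code <- as.integer(genotype_code)
  reference_code <- as.integer(reference_code)
  if (!genotype_code %in% 1:3 || !reference_code %in% 1:3) {
    stop("genotype codes must be in 1:3")
  }
  if (genotype_code == reference_code) {
    stop("genotype_code and reference_code must differ")
  }
  counts <- genotype_counts(dataset, snp_index)
  contingency_table(
    tp = counts$cases[counts$code == genotype_code],
    fp = counts$controls[counts$code == genotype_code],
    fn = counts$cases[counts$code == reference_code],
    tn = counts$controls[counts$code == reference_code]
  )
}

#' Classification metrics of a 2x2 table
#'
#' Correctness CC = (TP+TN)/(TP+FN+FP+TN), sensitivity SN = TP/(TP+FN),
#' specificity SP = TN/(TN+FP), and their unweighted mean ("Average").  A
#' metric with a zero denominator is not estimable and returned as `NA`;
#' the average is `NA` whenever any component is.
#'
#' @param table a [contingency_table()].
#' @return list with numeric fields `cc`, `sn`, `sp`, `average` (NA where
#'   not estimable).
#' @examples
#' classification_metrics(contingency_table(11, 4, 209, 330))
#' @export
classification_metrics <- function(table) {
  total <- table$tp + table$fn + table$fp + table$tn
  cc <- if (total > 0) (table$tp + table$tn) / total else NA_real_
  sn <- if (table$tp + table$fn > 0) table$tp / (table$tp + table$fn) else NA_real_
  sp <- if (table$tn + table$fp > 0) table$tn / (table$tn + table$fp) else NA_real_
  avg <- if (anyNA(c(cc, sn, sp))) NA_real_ else (cc + sn + sp) / 3
  list(cc = cc, sn = sn, sp = sp, average = avg)
}

#' Sample odds ratio
#'
#' OR = (TP x TN) / (FN x FP).  With `zero_correction = FALSE` (the default)
#' any zero cell makes the ratio not estimable (`NA`, rendered "N.E" in
#' reports); with the Haldane-Anscombe correction 0.5 is added to every cell
#' before the ratio is formed.
#'
#' @param table a [contingency_table()].
#' @param zero_correction apply the +0.5 continuity correction to all cells.
#' @return positive numeric, or `NA` when not estimable.
#' @examples
#' odds_ratio(contingency_table(11, 4, 209, 330))  # 4.342 to 3 d.p.
#' @export
odds_ratio <- function(table, zero_correction = FALSE) {
  cells <- c(table$tp, table$fp, table$fn, table$tn)
  if (zero_correction) cells <- cells + 0.5
  if (any(cells == 0)) return(NA_real_)
  (cells[1] * cells[4]) / (cells[3] * cells[2])
}

#' Confidence interval for the odds ratio
#'
#' `method = "woolf"` gives the asymptotic interval
#' exp(ln OR +/- z * sqrt(1/TP + 1/FP + 1/FN + 1/TN)); `method = "exact"`
#' the conditional exact (hypergeometric-based) interval of
#' [stats::fisher.test()], which brackets the conditional MLE odds ratio.
#' The Woolf interval is not estimable (`NA`s) when any cell is zero, unless
#' `zero_correction` adds 0.5 to every cell.
#'
#' @param table a [contingency_table()].
#' @param level confidence level (default 0.95).
#' @param method `"exact"` or `"woolf"`.
#' @param zero_correction apply the +0.5 correction (Woolf method only).
#' @return list with `lower`, `upper`, `method`.
#' @export
odds_ratio_ci <- function(table, level = 0.95, method = c("exact", "woolf"),
                          zero_correction = FALSE) {
  method <- match.arg(method)
  if (method == "woolf") {
    cells <- c(table$tp, table$fp, table$fn, table$tn)
    if (zero_correction) cells <- cells + 0.5
    if (any(cells == 0)) {
      return(list(lower = NA_real_, upper = NA_real_, method = "woolf"))
    }
    or <- (cells[1] * cells[4]) / (cells[3] * cells[2])
    z <- qnorm(1 - (1 - level) / 2)
    se <- sqrt(sum(1 / cells))
    list(lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
         method = "woolf")
  } else {
    degenerate <- (table$tp + table$fp == 0) || (table$fn + table$tn == 0) ||
      (table$tp + table$fn == 0) || (table$fp + table$tn == 0)
    if (degenerate) {
      return(list(lower = NA_real_, upper = NA_real_, method = "exact"))
    }
    ft <- fisher.test(as_table_matrix(table), conf.level = level)
    list(lower = unname(ft$conf.int[1]), upper = unname(ft$conf.int[2]),
         method = "exact")
  }
}

#' Two-sided association p-value for a 2x2 table
#'
#' @param table a [contingency_table()].
#' @param method `"fisher"` (two-sided Fisher exact test, the default),
#'   `"chi2"` (Pearson chi-squared without continuity correction) or
#'   `"chi2_yates"` (with Yates correction).
#' @return p-value in (0, 1], or `NA` when a margin is degenerate.
#' @examples
#' association_p_value(contingency_table(69, 137, 151, 197))  # ~0.025
#' @export
association_p_value <- function(table, method = c("fisher", "chi2", "chi2_yates")) {
  method <- match.arg(method)
  m <- as_table_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
  switch(method,
    fisher = fisher.test(m)$p.value,
    chi2 = suppressWarnings(chisq.test(m, correct = FALSE)$p.value),
    chi2_yates = suppressWarnings(chisq.test(m, correct = TRUE)$p.value)
  )
}

#' Full metric battery for one contingency table
#'
#' Bundles [classification_metrics()], [odds_ratio()], [odds_ratio_ci()] and
#' [association_p_value()] with the not-estimable (N.E) propagation used in
#' the printed reports: when the odds ratio is not estimable the Average,
#' CI and p-value fields are not estimable either, while CC/SN/SP keep any
#' values their own denominators allow.
#'
#' @param table a [contingency_table()].
#' @param ci_method `"exact"` or `"woolf"`.
#' @param p_method `"fisher"`, `"chi2"` or `"chi2_yates"`.
#' @param zero_correction see [odds_ratio()].
#' @param level confidence level for the CI.
#' @return list with fields `cc`, `sn`, `sp`, `average`, `odds_ratio`,
#'   `ci_lower`, `ci_upper`, `p_value`, `ci_method`, `p_method` (`NA` marks
#'   not-estimable values).
#' @export
combination_metrics <- function(table, ci_method = c("exact", "woolf"),
                                p_method = c("fisher", "chi2", "chi2_yates"),
                                zero_correction = FALSE, level = 0.95) {
  ci_method <- match.arg(ci_method)
  p_method <- match.arg(p_method)
  cls <- classification_metrics(table)
  or <- odds_ratio(table, zero_correction = zero_correction)
  if (is.na(or)) {
    ci <- list(lower = NA_real_, upper = NA_real_, method = ci_method)
    p <- NA_real_
    avg <- NA_real_
  } else {
    ci <- odds_ratio_ci(table, level = level, method = ci_method,
                        zero_correction = zero_correction)
    p <- association_p_value(table, method = p_method)
    avg <- cls$average
  }
  list(cc = cls$cc, sn = cls$sn, sp = cls$sp, average = avg,
       odds_ratio = or, ci_lower = ci$lower, ci_upper = ci$upper,
       p_value = p, ci_method = ci_method, p_method = p_method)
}

#' Round half away from zero
#'
#' Report rounding used for all printed tables (3 decimal places by
#' default).  Unlike [round()] (banker's rounding), exact halves move away
#' from zero, matching the convention of the reference tables.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# "N.E" rendering used by the TSV reports.
format_ne <- function(x, digits = 3) {
  ifelse(is.na(x), "N.E", formatC(round_half_away(x, digits),
                                  format = "f", digits = digits))
}
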