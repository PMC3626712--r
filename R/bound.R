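#' Count subjects matching a genotype combination
#'
#' A subject matches a combination iff its genotype code equals the pattern
#' code at every SNP of the combination.  The missing code 0 never matches,
#' but non-matching subjects stay in the case/control denominators.
#'
#' @param dataset a [genotype_dataset()].
#' @param combo a [snp_combination()] whose indices lie within the dataset's
#'   SNP columns.
#' @return An object of class `match_counts`: list with integer fields
#'   `controls_matched` and `cases_matched`.
#' @examples
#' d <- genotype_dataset(matrix(c(1, 1, 2, 1, 2, 2), nrow = 3),
#'                       c("case", "control", "case"))
#' match_counts(d, snp_combination(c(1, 2), c(1, 1)))
#' @export
match_counts <- function(dataset, combo) {
  check_dataset(dataset)
  if (!inherits(combo, "snp_combination")) stop("expected an snp_combination")
  if (max(combo$snp_indices) > n_snps(dataset)) {
    stop("combination index ", max(combo$snp_indices),
         " exceeds the dataset's ", n_snps(dataset), " SNPs")
  }
  matched <- match_rows(dataset$genotypes, combo$snp_indices,
                        combo$genotype_pattern)
  is_case <- dataset$phenotype == "case"
  new_match_counts(sum(matched & !is_case), sum(matched & is_case))
}

new_match_counts <- function(controls_matched, cases_matched) {
  structure(list(controls_matched = as.integer(controls_matched),
                 cases_matched = as.integer(cases_matched)),
            class = "match_counts")
}

# Logical vector: which rows of a genotype matrix match (idx, pattern).
match_rows <- function(genotypes, idx, pattern) {
  m <- length(idx)
  sub <- genotypes[, idx, drop = FALSE]
  target <- matrix(pattern, nrow = nrow(sub), ncol = m, byrow = TRUE)
  rowSums(sub == target) == m
}

#' @export
print.match_counts <- function(x, ...) {
  cat("match_counts: ", x$controls_matched, " controls / ",
      x$cases_matched, " cases\n", sep = "")
  invisible(x)
}

#' Bound value of a combination
#'
#' The bound value is the signed difference (matched controls) - (matched
#' cases).  A positive maximum marks a low-risk genotype pattern (relatively
#' enriched in controls), a negative maximum a high-risk pattern (enriched in
#' cases); a zero difference is classified neutral and ranks below any
#' nonzero bound in both directions.  `reported_diff` is the absolute
#' difference, the convention used when a winner is printed with its
#' direction ("Diff. = 68" for a low-risk pattern matching 137 controls and
#' 69 cases; "Diff. = 7" for a high-risk pattern matching 4 controls and 11
#' cases).
#'
#' @param counts a `match_counts` object (or a list with fields
#'   `controls_matched`, `cases_matched`).
#' @return An object of class `bound_value`: list with `signed_diff`
#'   (integer), `direction` (`"low_risk"`, `"high_risk"` or `"neutral"`) and
#'   `reported_diff` (non-negative integer).
#' @examples
#' bound_value(list(controls_matched = 137, cases_matched = 69))
#' @export
bound_value <- function(counts) {
  controls <- as.integer(counts$controls_matched)
  cases <- as.integer(counts$cases_matched)
  if (is.na(controls) || is.na(cases) || controls < 0 || cases < 0) {
    stop("counts must be non-negative integers")
  }
  signed <- controls - cases
  direction <- if (signed > 0) "low_risk" else if (signed < 0) "high_risk" else "neutral"
  structure(list(signed_diff = signed,
                 direction = direction,
                 reported_diff = abs(signed)),
            class = "bound_value")
}

#' @export
print.bound_value <- function(x, ...) {
  cat("bound_value: signed ", x$signed_diff, " (", x$direction,
      ", Diff. = ", x$reported_diff, ")\n", sep = "")
  invisible(x)
}
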