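#' Simulation parameters for case-control genotype data
#'
#' Defaults emulate the structure of the motivating breast-cancer cohort:
#' 220 cases, 334 controls, 7 biallelic SNPs.  Background genotype
#' frequencies default to Hardy-Weinberg proportions for a minor allele
#' frequency of 0.3 (0.49 / 0.42 / 0.09 for codes 1 / 2 / 3), a common
#' profile for candidate-gene SNPs.  SNPs are simulated independently: no
#' linkage disequilibrium is modeled (the search itself is LD-agnostic).
#'
#' @param n_cases,n_controls,n_snps cohort dimensions (positive integers).
#' @param background genotype frequencies for codes 1/2/3: a length-3
#'   non-negative vector summing to 1, or a `n_snps` x 3 matrix of per-SNP
#'   frequencies.
#' @param planted optional planted enrichment: a list with elements `combo`
#'   (an [snp_combination()]), `p_case` and `p_control` — the probability
#'   that a case (control) subject is forced to match the planted pattern.
#'   Subjects not forced to match are guaranteed NOT to match it (their
#'   pattern-position genotypes are redrawn from background until at least
#'   one differs), so `p_case` / `p_control` are exact per-subject match
#'   probabilities.
#' @param missing_rate per-cell probability of a missing genotype (code 0),
#'   in `[0, 1)`.
#' @param seed integer seed; identical parameters give identical datasets.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_cases = 220, n_controls = 334, n_snps = 7,
                              background = c(0.49, 0.42, 0.09),
                              planted = NULL, missing_rate = 0, seed = 1) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  n_snps <- as.integer(n_snps)
  if (n_cases < 1 || n_controls < 1 || n_snps < 1) {
    stop("n_cases, n_controls and n_snps must be positive")
  }
  if (is.matrix(background)) {
    if (nrow(background) != n_snps || ncol(background) != 3) {
      stop("background matrix must be n_snps x 3")
    }
  } else {
    if (length(background) != 3) stop("background must have 3 frequencies")
    background <- matrix(background, nrow = n_snps, ncol = 3, byrow = TRUE)
  }
  if (any(background < 0) || any(abs(rowSums(background) - 1) > 1e-8)) {
    stop("background frequencies must be non-negative and sum to 1 per SNP")
  }
  if (!is.null(planted)) {
    if (!inherits(planted$combo, "snp_combination")) {
      stop("planted$combo must be an snp_combination")
    }
    if (max(planted$combo$snp_indices) > n_snps) {
      stop("planted combination index exceeds n_snps")
    }
    for (f in c("p_case", "p_control")) {
      p <- planted[[f]]
      if (is.null(p) || p < 0 || p > 1) stop(f, " must be in [0, 1]")
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
                 background = background, planted = planted,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a case-control genotype dataset
#'
#' Draws genotypes i.i.d. per SNP from the background frequencies, then (if
#' a planted enrichment is configured) forces each subject to match the
#' planted pattern with probability `p_case` (cases) or `p_control`
#' (controls); subjects not forced are redrawn at the pattern positions
#' until they do not fully match, so the Bernoulli probabilities are exact
#' match probabilities.  Missing codes are sprinkled last, uniformly at
#' `missing_rate`.  Deterministic under a fixed seed.
#'
#' @param params a [simulation_params()] object.
#' @return a [genotype_dataset()] with cases first, then controls.
#' @examples
#' d <- simulate_dataset(simulation_params(n_cases = 50, n_controls = 80,
#'                                         n_snps = 4, seed = 42))
#' genotype_counts(d, 1)
#' @export
simulate_dataset <- function(params) {
  if (!inherits(params, "simulation_params")) {
    stop("expected a simulation_params object")
  }
  set.seed(params$seed)
  n_sub <- params$n_cases + params$n_controls
  geno <- matrix(0L, nrow = n_sub, ncol = params$n_snps)
  for (j in seq_len(params$n_snps)) {
    geno[, j] <- sample.int(3, n_sub, replace = TRUE,
                            prob = params$background[j, ])
  }
  phenotype <- c(rep("case", params$n_cases), rep("control", params$n_controls))
  if (!is.null(params$planted)) {
    combo <- params$planted$combo
    idx <- combo$snp_indices
    pat <- combo$genotype_pattern
    p <- ifelse(phenotype == "case", params$planted$p_case,
                params$planted$p_control)
    force_match <- runif(n_sub) < p
    if (any(force_match)) {
      geno[force_match, idx] <- matrix(pat, nrow = sum(force_match),
                                       ncol = length(idx), byrow = TRUE)
    }
    # Redraw accidental background matches so p is the exact match rate.
    for (i in which(!force_match)) {
      while (all(geno[i, idx] == pat)) {
        for (k in seq_along(idx)) {
          geno[i, idx[k]] <- sample.int(3, 1, prob = params$background[idx[k], ])
        }
      }
    }
  }
  if (params$missing_rate > 0) {
    drop <- matrix(runif(length(geno)) < params$missing_rate,
                   nrow = n_sub)
    geno[drop] <- 0L
  }
  genotype_dataset(geno, phenotype,
                   subject_ids = c(sprintf("case%03d", seq_len(params$n_cases)),
                                   sprintf("ctrl%03d", seq_len(params$n_controls))))
}

#' Reconstruct a dataset from printed match counts
#'
#' Builds a cohort in which exactly `cases_matched` cases and
#' `controls_matched` controls match a given combination, and every other
#' subject differs from the pattern at the combination's first SNP (its code
#' is cyclically shifted, a deterministic minimal perturbation).  SNPs
#' outside the combination are set to `filler_code`.  This is the fixture
#' builder used to reproduce published contingency tables whose underlying
#' subject-level data are not deposited; the resulting dataset is synthetic
#' and only guarantees the stated match counts.
#'
#' @param combo an [snp_combination()].
#' @param counts a [match_counts()] result or list with `controls_matched`,
#'   `cases_matched`.
#' @param n_cases,n_controls cohort totals C and N.
#' @param n_snps total SNP columns (default: largest combination index).
#' @param filler_code genotype code for SNPs outside the combination.
#' @return a [genotype_dataset()] satisfying
#'   `match_counts(result, combo) == counts` exactly.
#' @examples
#' d <- dataset_from_counts(snp_combination(c(3, 4), c(1, 1)),
#'                          list(controls_matched = 137, cases_matched = 69),
#'                          n_cases = 220, n_controls = 334, n_snps = 7)
#' match_counts(d, snp_combination(c(3, 4), c(1, 1)))
#' @export
dataset_from_counts <- function(combo, counts, n_cases, n_controls,
                                n_snps = NULL, filler_code = 1) {
  if (!inherits(combo, "snp_combination")) stop("expected an snp_combination")
  cm <- as.integer(counts$cases_matched)
  km <- as.integer(counts$controls_matched)
  if (cm < 0 || km < 0 || cm > n_cases || km > n_controls) {
    stop("infeasible counts: matched counts must lie within the cohort totals")
  }
  if (is.null(n_snps)) n_snps <- max(combo$snp_indices)
  if (max(combo$snp_indices) > n_snps) stop("combination index exceeds n_snps")
  n_sub <- n_cases + n_controls
  geno <- matrix(as.integer(filler_code), nrow = n_sub, ncol = n_snps)
  idx <- combo$snp_indices
  pat <- combo$genotype_pattern
  geno[, idx] <- matrix(pat, nrow = n_sub, ncol = length(idx), byrow = TRUE)
  phenotype <- c(rep("case", n_cases), rep("control", n_controls))
  # Break the match for the unmatched tail of each phenotype group.
  off_code <- pat[1] %% 3L + 1L
  non_matching <- c(if (cm < n_cases) (cm + 1):n_cases,
                    if (km < n_controls) n_cases + (km + 1):n_controls)
  geno[non_matching, idx[1]] <- off_code
  genotype_dataset(geno, phenotype)
}
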