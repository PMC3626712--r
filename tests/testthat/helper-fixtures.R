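# Shared fixtures and independent oracles used across test files.

# Random dataset straight from base R, independent of simulate_dataset().
random_dataset <- function(n_subjects = 30, n_snps = 4, missing_rate = 0,
                           seed = 1, p_case = 0.4) {
  set.seed(seed)
  geno <- matrix(sample(1:3, n_subjects * n_snps, replace = TRUE),
                 nrow = n_subjects)
  if (missing_rate > 0) {
    geno[matrix(runif(length(geno)) < missing_rate, nrow = n_subjects)] <- 0L
  }
  pheno <- ifelse(runif(n_subjects) < p_case, "case", "control")
  # guarantee both groups are populated
  pheno[1] <- "case"; pheno[2] <- "control"
  genotype_dataset(geno, pheno)
}

# Brute-force row-by-row oracle for match counts.
brute_match_counts <- function(dataset, idx, pattern) {
  controls <- 0L; cases <- 0L
  for (i in seq_along(dataset$subject_ids)) {
    if (all(dataset$genotypes[i, idx] == pattern)) {
      if (dataset$phenotype[i] == "case") cases <- cases + 1L
      else controls <- controls + 1L
    }
  }
  list(controls_matched = controls, cases_matched = cases)
}

# Naive double-loop exhaustive winner for one order and direction.
brute_exhaustive_best <- function(dataset, order, direction) {
  best <- NULL
  for (combo in enumerate_combinations(n_snps(dataset), order)) {
    mc <- brute_match_counts(dataset, combo$snp_indices,
                             combo$genotype_pattern)
    dv <- if (direction == "low_risk") {
      mc$controls_matched - mc$cases_matched
    } else {
      mc$cases_matched - mc$controls_matched
    }
    if (is.null(best) || dv > best$dv) {
      best <- list(combo = combo, counts = mc, dv = dv)
    }
  }
  best
}
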