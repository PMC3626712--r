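#' Case-control genotype dataset
#'
#' Container for unphased biallelic genotypes of a case-control cohort.
#' Genotype states are coded as opaque integers: 1, 2, 3 for the three
#' genotypes of a biallelic SNP (conventionally reference homozygote,
#' heterozygote, alternate homozygote) and 0 for missing.  The package never
#' infers allele identity from the codes; the search only needs state
#' equality.  A subject with a missing code at any SNP of a combination never
#' matches that combination but stays in the case/control denominators, so
#' the totals C (cases) and N (controls) are constants of the dataset.
#'
#' @param genotypes integer matrix, subjects x SNPs, every cell in 0:3.
#' @param phenotype character or numeric vector, one entry per subject;
#'   accepted spellings are `"case"`/`"control"` and `1`/`0` (also PLINK-style
#'   `2`/`1` via the reader).  Stored normalized as `"case"`/`"control"`.
#' @param subject_ids optional character vector of identifiers; defaults to
#'   `"S1"`, `"S2"`, ...
#' @param snp_names optional character vector of SNP labels (e.g. rsIDs);
#'   defaults to the matrix column names or `"SNP1"`, ...
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `phenotype`, `subject_ids`, `snp_names`.
#' @examples
#' g <- matrix(c(1, 2, 3, 1, 1, 2), nrow = 3)
#' d <- genotype_dataset(g, c("case", "control", "case"))
#' n_cases(d)     # 2
#' n_controls(d)  # 1
#' @export
genotype_dataset <- function(genotypes, phenotype, subject_ids = NULL,
                             snp_names = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (anyNA(genotypes) || !all(genotypes %in% 0:3)) {
    bad <- which(is.na(genotypes) | !(genotypes %in% 0:3), arr.ind = TRUE)[1, ]
    stop("invalid genotype code at row ", bad[1], ", column ", bad[2],
         ": cells must be integers in 0-3 (0 = missing)")
  }
  phenotype <- normalize_phenotype(phenotype)
  if (length(phenotype) != nrow(genotypes)) {
    stop("phenotype length (", length(phenotype),
         ") does not match number of subjects (", nrow(genotypes), ")")
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(genotypes)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(genotypes)))
  }
  if (length(subject_ids) != nrow(genotypes)) {
    stop("subject_ids length does not match number of subjects")
  }
  if (is.null(snp_names)) {
    snp_names <- colnames(genotypes)
    if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  if (length(snp_names) != ncol(genotypes)) {
    stop("snp_names length does not match number of SNP columns")
  }
  dimnames(genotypes) <- NULL
  structure(
    list(genotypes = genotypes,
         phenotype = phenotype,
         subject_ids = as.character(subject_ids),
         snp_names = as.character(snp_names)),
    class = "genotype_dataset"
  )
}

normalize_phenotype <- function(phenotype) {
  x <- tolower(trimws(as.character(phenotype)))
  out <- ifelse(x %in% c("case", "1"), "case",
                ifelse(x %in% c("control", "0"), "control", NA_character_))
  if (anyNA(out)) {
    stop("unrecognized phenotype label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected case/control or 1/0)")
  }
  out
}

#' @rdname genotype_dataset
#' @param dataset a `genotype_dataset`.
#' @export
n_cases <- function(dataset) sum(dataset$phenotype == "case")

#' @rdname genotype_dataset
#' @export
n_controls <- function(dataset) sum(dataset$phenotype == "control")

#' @rdname genotype_dataset
#' @export
n_snps <- function(dataset) ncol(dataset$genotypes)

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset: ", length(x$subject_ids), " subjects (",
      n_cases(x), " cases, ", n_controls(x), " controls), ",
      n_snps(x), " SNPs\n", sep = "")
  cat("SNPs:", paste(x$snp_names, collapse = ", "), "\n")
  invisible(x)
}

# Internal: verify a dataset is usable by the statistics/search operations.
check_dataset <- function(dataset) {
  if (!inherits(dataset, "genotype_dataset")) {
    stop("expected a genotype_dataset object")
  }
  if (n_cases(dataset) < 1 || n_controls(dataset) < 1) {
    stop("dataset must contain at least one case and one control")
  }
  invisible(dataset)
}

#' Multi-SNP genotype combination
#'
#' A combination fixes a genotype code (1, 2 or 3; never the missing code 0)
#' at each of an ordered set of SNP columns.  Printed as e.g. `SNPs (3, 4)`
#' genotype `1-1`.  Indices are 1-based column positions.
#'
#' @param snp_indices strictly increasing 1-based SNP column indices.
#' @param genotype_pattern integer codes in 1:3, one per SNP index.
#' @return An object of class `snp_combination`.
#' @examples
#' snp_combination(c(3, 4), c(1, 1))
#' @export
snp_combination <- function(snp_indices, genotype_pattern) {
  snp_indices <- as.integer(snp_indices)
  genotype_pattern <- as.integer(genotype_pattern)
  if (length(snp_indices) < 1) stop("combination must contain at least one SNP")
  if (length(snp_indices) != length(genotype_pattern)) {
    stop("snp_indices and genotype_pattern must have equal length")
  }
  if (is.unsorted(snp_indices, strictly = TRUE) || any(snp_indices < 1)) {
    stop("snp_indices must be strictly increasing positive integers")
  }
  if (!all(genotype_pattern %in% 1:3)) {
    stop("genotype_pattern codes must be in 1:3 (0/missing cannot be part of a pattern)")
  }
  structure(list(snp_indices = snp_indices,
                 genotype_pattern = genotype_pattern),
            class = "snp_combination")
}

#' @export
print.snp_combination <- function(x, ...) {
  cat("SNPs (", paste(x$snp_indices, collapse = ", "), ") genotype ",
      paste(x$genotype_pattern, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Read a case-control genotype table
#'
#' Reads a delimited genotype file into a [genotype_dataset()].  Two layouts
#' are supported:
#'
#' * `csv` / `tsv`: header `subject_id,phenotype,<snp1>,...,<snpK>`,
#'   phenotype in `{case, control, 1, 0}`, genotype cells in `{0,1,2,3}`.
#' * `plink_raw`: whitespace-delimited PLINK-`.raw`-like layout with leading
#'   columns `FID IID PAT MAT SEX PHENOTYPE` (phenotype 2 = case, 1 =
#'   control) and allele-dosage SNP columns in `{0,1,2, NA}`; dosages are
#'   recoded to genotype states 1/2/3 and `NA` to the missing code 0.
#'
#' @param path path to an existing file.
#' @param dialect one of `"csv"`, `"tsv"`, `"plink_raw"`.
#' @return a validated [genotype_dataset()]; subject row order is preserved.
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, dialect = c("csv", "tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plink_raw") return(read_plink_raw(path))
  df <- if (dialect == "csv") {
    read.csv(path, check.names = FALSE, colClasses = "character")
  } else {
    read.delim(path, check.names = FALSE, colClasses = "character")
  }
  cols <- tolower(names(df))
  pheno_col <- match(TRUE, cols %in% c("phenotype", "pheno", "status"))
  if (is.na(pheno_col)) stop("missing phenotype column (expected a column named 'phenotype')")
  id_col <- match(TRUE, cols %in% c("subject_id", "id", "sample", "iid"))
  snp_cols <- setdiff(seq_along(df), c(pheno_col, id_col))
  geno <- parse_genotype_cells(df[snp_cols], names(df)[snp_cols])
  dataset <- genotype_dataset(
    geno,
    phenotype = df[[pheno_col]],
    subject_ids = if (!is.na(id_col)) df[[id_col]] else NULL,
    snp_names = names(df)[snp_cols]
  )
  check_dataset(dataset)
}

# Strict integer parsing with row/column diagnostics.
parse_genotype_cells <- function(df, col_names, allowed = 0:3) {
  geno <- matrix(NA_integer_, nrow = nrow(df), ncol = length(df))
  for (j in seq_along(df)) {
    raw <- trimws(df[[j]])
    val <- suppressWarnings(as.integer(raw))
    bad <- which(is.na(val) | val != suppressWarnings(as.numeric(raw)) |
                   !(val %in% allowed))
    if (length(bad) > 0) {
      stop("malformed genotype cell at row ", bad[1], ", column '",
           col_names[j], "': '", raw[bad[1]], "' (expected integer in ",
           min(allowed), "-", max(allowed), ")")
    }
    geno[, j] <- val
  }
  geno
}

read_plink_raw <- function(path) {
  df <- read.table(path, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = "NA")
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(df))) {
    stop("missing phenotype column: plink_raw files need the header ",
         paste(fixed, collapse = " "))
  }
  snp_cols <- setdiff(names(df), fixed)
  dose <- matrix(NA_integer_, nrow = nrow(df), ncol = length(snp_cols))
  for (j in seq_along(snp_cols)) {
    raw <- df[[snp_cols[j]]]
    val <- suppressWarnings(as.integer(raw))
    bad <- which(!is.na(raw) & (is.na(val) | !(val %in% 0:2)))
    if (length(bad) > 0) {
      stop("malformed dosage cell at row ", bad[1], ", column '",
           snp_cols[j], "': '", raw[bad[1]], "' (expected 0/1/2 or NA)")
    }
    dose[, j] <- val
  }
  geno <- dose + 1L            # dosage 0/1/2 -> genotype state 1/2/3
  geno[is.na(geno)] <- 0L      # NA -> missing code
  pheno <- ifelse(df$PHENOTYPE == "2", "case",
                  ifelse(df$PHENOTYPE == "1", "control", NA))
  if (anyNA(pheno)) {
    stop("unrecognized PHENOTYPE value(s): ",
         paste(unique(df$PHENOTYPE[is.na(pheno)]), collapse = ", "),
         " (expected 2 = case, 1 = control)")
  }
  dataset <- genotype_dataset(geno, pheno, subject_ids = df$IID,
                              snp_names = snp_cols)
  check_dataset(dataset)
}

#' Write a case-control genotype table
#'
#' Inverse of [read_genotype_table()]: the written file reads back into an
#' identical dataset.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @param dialect one of `"csv"`, `"tsv"`, `"plink_raw"`.
#' @return invisibly, `path`.
#' @export
write_genotype_table <- function(dataset, path,
                                 dialect = c("csv", "tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!inherits(dataset, "genotype_dataset")) stop("expected a genotype_dataset")
  if (dialect == "plink_raw") {
    dose <- dataset$genotypes - 1L
    dose[dataset$genotypes == 0L] <- NA_integer_
    df <- data.frame(FID = dataset$subject_ids, IID = dataset$subject_ids,
                     PAT = 0L, MAT = 0L, SEX = 0L,
                     PHENOTYPE = ifelse(dataset$phenotype == "case", 2L, 1L),
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(dose))
    names(df) <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                   dataset$snp_names)
    write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    df <- data.frame(subject_id = dataset$subject_ids,
                     phenotype = dataset$phenotype, check.names = FALSE)
    if (n_snps(dataset) > 0) {
      geno <- as.data.frame(dataset$genotypes)
      names(geno) <- dataset$snp_names
      df <- cbind(df, geno)
    }
    write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Per-genotype counts for one SNP
#'
#' Tallies controls and cases carrying each genotype code (including the
#' missing code 0) at a single SNP.  For every SNP the four (controls, cases)
#' pairs sum to the dataset totals (N, C).
#'
#' @param dataset a [genotype_dataset()].
#' @param snp_index 1-based SNP column index.
#' @return data.frame with columns `code` (0:3), `controls`, `cases`.
#' @export
genotype_counts <- function(dataset, snp_index) {
  check_dataset(dataset)
  snp_index <- as.integer(snp_index)
  if (length(snp_index) != 1 || is.na(snp_index) ||
      snp_index < 1 || snp_index > n_snps(dataset)) {
    stop("snp_index out of range (dataset has ", n_snps(dataset), " SNPs)")
  }
  g <- dataset$genotypes[, snp_index]
  is_case <- dataset$phenotype == "case"
  data.frame(
    code = 0:3,
    controls = vapply(0:3, function(k) sum(g == k & !is_case), integer(1)),
    cases = vapply(0:3, function(k) sum(g == k & is_case), integer(1))
  )
}
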