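# Tabular readers/writers for genotype matrices, phenotype tables and
# SNP-to-gene annotation. All formats are plain delimited text so runs are
# portable and diffable.

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (length(line) == 0L) stop("empty file: ", path)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read a genotype matrix of 0/1/2 risk-allele counts
#'
#' Accepts delimited text (tab or comma, auto-detected) in either
#' orientation. The first column holds row identifiers; the header line holds
#' column identifiers. PLINK `.raw`-style dosage tables are read with
#' `orientation = "samples_by_snps"` by naming the non-genotype leading
#' columns in `id_columns` (the first of which is kept as the sample id).
#'
#' @param path file path.
#' @param orientation `"snps_by_samples"` (rows are SNPs) or
#'   `"samples_by_snps"` (rows are samples).
#' @param id_columns for `samples_by_snps` input, names of leading
#'   non-genotype columns (e.g. `c("FID","IID","PAT","MAT","SEX","PHENOTYPE")`
#'   for PLINK `.raw`); defaults to the first column only.
#' @return An integer matrix with samples in rows and SNPs in columns,
#'   dimnames preserved in input order. Values are 0, 1, 2 or `NA`; anything
#'   else is a format error naming the offending SNP and sample. Duplicate
#'   SNP ids are an error.
#' @seealso [write_genotypes()], [impute_genotypes()]
#' @export
read_genotypes <- function(path,
                           orientation = c("snps_by_samples", "samples_by_snps"),
                           id_columns = NULL) {
  orientation <- match.arg(orientation)
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("genotype file has no data: ", path)
  if (orientation == "snps_by_samples") {
    snp_ids <- as.character(df[[1L]])
    sample_ids <- colnames(df)[-1L]
    mat <- t(as.matrix(df[, -1L, drop = FALSE]))
    dimnames(mat) <- list(sample_ids, snp_ids)
  } else {
    if (is.null(id_columns)) id_columns <- colnames(df)[1L]
    missing_id <- setdiff(id_columns, colnames(df))
    if (length(missing_id)) {
      stop("id column(s) not found: ", paste(missing_id, collapse = ", "))
    }
    sample_ids <- as.character(df[[id_columns[1L]]])
    keep <- setdiff(colnames(df), id_columns)
    mat <- as.matrix(df[, keep, drop = FALSE])
    dimnames(mat) <- list(sample_ids, keep)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicated SNP id(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  }
  num <- suppressWarnings(as.numeric(mat))
  ok <- is.na(mat) | (!is.na(num) & num %in% c(0, 1, 2))
  dim(ok) <- dim(mat)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stop(sprintf("genotype value outside {0,1,2,NA} for SNP %s, sample %s",
                 colnames(mat)[bad[1L, 2L]], rownames(mat)[bad[1L, 1L]]))
  }
  out <- matrix(as.integer(num), nrow(mat), ncol(mat), dimnames = dimnames(mat))
  out
}

#' Write a genotype matrix as delimited text
#'
#' @param genotypes integer matrix as returned by [read_genotypes()]
#'   (samples x SNPs).
#' @param path output file.
#' @param orientation layout to write; see [read_genotypes()].
#' @param sep field separator.
#' @export
write_genotypes <- function(genotypes, path,
                            orientation = c("snps_by_samples", "samples_by_snps"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  if (orientation == "snps_by_samples") {
    df <- data.frame(snp_id = colnames(genotypes), t(genotypes),
                     check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(genotypes), genotypes,
                     check.names = FALSE)
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing genotypes by the rounded per-SNP mean
#'
#' Replaces `NA` entries of a 0/1/2 genotype matrix with the SNP-wise mean
#' rounded to the nearest integer. Downstream model fitting requires complete
#' genotypes; this utility is deliberately not applied automatically.
#'
#' @param genotypes integer matrix, samples x SNPs.
#' @return The completed matrix.
#' @export
impute_genotypes <- function(genotypes) {
  nas <- which(is.na(genotypes), arr.ind = TRUE)
  if (nrow(nas) == 0L) return(genotypes)
  means <- colMeans(genotypes, na.rm = TRUE)
  fill <- as.integer(pmin(2, pmax(0, round(unname(means)[nas[, 2L]]))))
  genotypes[nas] <- fill
  genotypes
}

#' Read a phenotype table into a cohort
#'
#' Expects a header naming a `time` column, a `status` column (values 0/1)
#' and zero or more numeric covariate columns, which become the mandatory
#' covariates in their input order.
#'
#' @param path file path (tab- or comma-delimited, auto-detected).
#' @return A [cohort()] object; sample ids (if a `sample_id` column is
#'   present) are kept as row names of the covariate matrix.
#' @export
read_phenotypes <- function(path) {
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  nm <- tolower(colnames(df))
  ti <- match("time", nm)
  si <- match("status", nm)
  if (is.na(ti) || is.na(si)) {
    stop("phenotype file must have 'time' and 'status' columns")
  }
  ids <- match("sample_id", nm)
  covn <- setdiff(seq_along(df), c(ti, si, if (!is.na(ids)) ids))
  covariates <- as.matrix(df[, covn, drop = FALSE])
  if (length(covn) && !is.numeric(covariates)) {
    stop("covariate columns must be numeric")
  }
  if (!is.na(ids)) rownames(covariates) <- as.character(df[[ids]])
  cohort(df[[ti]], df[[si]],
         if (length(covn)) covariates else NULL)
}

#' Write a cohort as a phenotype table
#'
#' @param cohort a [cohort()] object.
#' @param path output file.
#' @param sep field separator.
#' @export
write_phenotypes <- function(cohort, path, sep = "\t") {
  df <- data.frame(time = cohort$time, status = cohort$status)
  if (cohort$r > 0) df <- cbind(df, as.data.frame(cohort$covariates))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP-to-gene annotation table
#'
#' Two-column delimited text relating SNP ids to gene ids. The relation is
#' many-to-many: a SNP may map to several (e.g. overlapping or flanking)
#' genes and a gene typically maps to many SNPs. Duplicate rows in the file
#' are collapsed.
#'
#' @param path file path; a header line `snp_id gene_id` is recognized and
#'   skipped, otherwise the first row is treated as data.
#' @return A deduplicated data.frame with character columns `snp_id` and
#'   `gene_id`.
#' @export
read_snp_gene_map <- function(path) {
  sep <- detect_sep(path)
  df <- tryCatch(
    read.table(path, header = FALSE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read annotation table: ", conditionMessage(e))
  )
  if (ncol(df) < 2L) stop("annotation table needs two columns (snp_id, gene_id)")
  df <- df[, 1:2]
  colnames(df) <- c("snp_id", "gene_id")
  if (tolower(df$snp_id[1L]) == "snp_id") df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("annotation table is empty")
  df$snp_id <- as.character(df$snp_id)
  df$gene_id <- as.character(df$gene_id)
  if (any(!nzchar(df$snp_id)) || any(!nzchar(df$gene_id))) {
    stop("empty snp_id or gene_id in annotation table")
  }
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Write a SNP-to-gene annotation table
#' @param map data.frame with columns `snp_id`, `gene_id`.
#' @param path output file.
#' @export
write_snp_gene_map <- function(map, path) {
  write.table(map[, c("snp_id", "gene_id")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (or `key=value`); blank lines and lines
#' starting with `#` are ignored. Values that parse as numbers are returned
#' numeric.
#'
#' @param path file path.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Default run configuration
#'
#' Central defaults for the analysis pipeline: FDR level 0.05, B = 10000
#' permutations for the gene-level test, 100 subsamples of fraction 0.632 for
#' stability, 10-fold cross-validation for the boosting step count.
#'
#' @param fdr_level FDR level for univariate selection, in (0, 1).
#' @param n_permutations permutation count B for the min-P gene test.
#' @param n_subsamples number of stability subsamples.
#' @param subsample_fraction subsample size as a fraction of n, in (0, 1).
#' @param cv_folds cross-validation folds (>= 2).
#' @param lambda boosting penalty: positive number or `"auto"` (9 x events).
#' @param max_boost_steps upper end of the boosting step grid.
#' @param seed optional integer seed.
#' @return Named list of validated settings.
#' @export
run_config <- function(fdr_level = 0.05, n_permutations = 10000,
                       n_subsamples = 100, subsample_fraction = 0.632,
                       cv_folds = 10, lambda = "auto", max_boost_steps = 100,
                       seed = NULL) {
  stopifnot(fdr_level > 0, fdr_level < 1,
            subsample_fraction > 0, subsample_fraction < 1,
            n_permutations >= 1, cv_folds >= 2, max_boost_steps >= 0)
  if (!identical(lambda, "auto") && !(is.numeric(lambda) && lambda > 0)) {
    stop("'lambda' must be a positive number or \"auto\"")
  }
  list(fdr_level = fdr_level, n_permutations = as.integer(n_permutations),
       n_subsamples = as.integer(n_subsamples),
       subsample_fraction = subsample_fraction,
       cv_folds = as.integer(cv_folds), lambda = lambda,
       max_boost_steps = as.integer(max_boost_steps), seed = seed)
}

write_result_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
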