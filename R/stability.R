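# Subsampling stability: rerun a full selection procedure on subsamples of
# size 0.632n and count, per SNP and per gene, how many subsamples select it.

#' Draw index sets for subsampling without replacement
#'
#' @param n cohort size.
#' @param n_subsamples number of subsamples.
#' @param fraction subsample size as a fraction of n (subsample size is
#'   `floor(fraction * n)`); drawing is without replacement, so each set has
#'   distinct indices. Subsampling rather than bootstrap resampling is used
#'   because resampling with replacement biases procedures that rely on a
#'   tuning parameter.
#' @return List of sorted integer index vectors.
#' @export
draw_subsamples <- function(n, n_subsamples, fraction = 0.632) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  m <- floor(fraction * n)
  if (m < 2) stop("subsample size floor(fraction * n) must be at least 2")
  lapply(seq_len(n_subsamples), function(b) sort(sample.int(n, m)))
}

subset_cohort <- function(cohort, idx) {
  cohort(cohort$time[idx], cohort$status[idx],
         if (cohort$r > 0) cohort$covariates[idx, , drop = FALSE])
}

#' Subsampling stability analysis of a selection procedure
#'
#' Repeats the complete selection procedure of either track from scratch on
#' each of `n_subsamples` subsamples of size `floor(fraction * n)`:
#' `univariate_fdr` re-runs the adjusted screen and re-applies the BH cut on
#' each subsample's own p-values; `boost_cv` re-tunes the number of boosting
#' steps by cross-validation inside every subsample. The inclusion frequency
#' (IF) of a SNP is the number of subsamples selecting it; subsamples that
#' select nothing are legal and recorded. Each subsample run gets its own
#' seed derived from the current RNG state, so results do not depend on
#' execution order.
#'
#' @param cohort a [cohort()] object.
#' @param genotypes complete 0/1/2 matrix, samples x SNPs.
#' @param map optional SNP-to-gene annotation for gene-level inclusion
#'   frequencies.
#' @param method `"univariate_fdr"` or `"boost_cv"`.
#' @param n_subsamples number of subsamples.
#' @param fraction subsample fraction of n.
#' @param level FDR level for `univariate_fdr`.
#' @param lambda,max_steps,cv_folds boosting settings for `boost_cv`.
#' @param mode screening mode for `univariate_fdr`.
#' @return An object of class `"stability_report"`: per-SNP inclusion counts
#'   (`snp_if`), per-subsample selected sets (`sets`), selected-set sizes,
#'   per-gene counts (`gene_if`, if `map` given), the number of failed runs,
#'   `n_subsamples` and `method`.
#' @export
stability_run <- function(cohort, genotypes, map = NULL,
                          method = c("univariate_fdr", "boost_cv"),
                          n_subsamples = 100, fraction = 0.632, level = 0.05,
                          lambda = "auto", max_steps = 100, cv_folds = 10,
                          mode = c("offset_fast", "joint")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  genotypes <- check_genotypes(genotypes, cohort)
  subs <- draw_subsamples(cohort$n, n_subsamples, fraction)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subsamples)
  n_failed <- 0L
  sets <- vector("list", n_subsamples)
  for (b in seq_len(n_subsamples)) {
    set.seed(sub_seeds[b])
    idx <- subs[[b]]
    ch <- subset_cohort(cohort, idx)
    G <- genotypes[idx, , drop = FALSE]
    sel <- tryCatch({
      if (method == "univariate_fdr") {
        selected_snps(screen_snps(ch, G, mode = mode, level = level,
                                  warn = FALSE))
      } else {
        cv <- cv_select_steps(ch, G, lambda = lambda, max_steps = max_steps,
                              cv_folds = cv_folds)
        if (cv$best_steps == 0L) character(0) else {
          boost_fit(ch, G, lambda = lambda, n_steps = cv$best_steps)$selected
        }
      }
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      warning("subsample ", b, " failed: ", conditionMessage(e))
      character(0)
    })
    sets[[b]] <- sel
  }
  snp_if <- stats::setNames(integer(ncol(genotypes)), colnames(genotypes))
  tab <- table(unlist(sets))
  snp_if[names(tab)] <- as.integer(tab)
  report <- structure(
    list(snp_if = snp_if, sets = sets, set_sizes = lengths(sets),
         n_subsamples = n_subsamples, method = method, n_failed = n_failed,
         gene_if = NULL),
    class = "stability_report"
  )
  if (!is.null(map)) report$gene_if <- gene_inclusion(report, map)
  report
}

#' Gene-level inclusion frequencies from a stability report
#'
#' A gene counts as included in a subsample if at least one of its mapped
#' SNPs is selected there (union semantics: several selected SNPs of the
#' same gene in one subsample count once).
#'
#' @param report a [stability_run()] result.
#' @param map SNP-to-gene annotation (data.frame with `snp_id`, `gene_id`).
#' @return Named integer vector of gene inclusion counts over all genes in
#'   the map (unselected genes count 0).
#' @export
gene_inclusion <- function(report, map) {
  map <- unique(map[, c("snp_id", "gene_id")])
  genes <- sort(unique(map$gene_id))
  counts <- stats::setNames(integer(length(genes)), genes)
  for (sel in report$sets) {
    hit <- unique(map$gene_id[map$snp_id %in% sel])
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

if_summary <- function(counts, n_subsamples, thresholds = c(1L, 10L)) {
  if (length(counts) == 0L) {
    return(data.frame(if_gt0 = 0L, if_ge10 = 0L, max_if = 0L,
                      max_id = NA_character_))
  }
  data.frame(
    if_gt0 = sum(counts >= thresholds[1L]),
    if_ge10 = sum(counts >= thresholds[2L]),
    max_if = max(counts),
    max_id = if (max(counts) > 0) names(counts)[which.max(counts)] else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report (%s): %d subsamples, median selected-set size %g (range %d-%d), %d empty\n",
              x$method, x$n_subsamples, stats::median(x$set_sizes),
              min(x$set_sizes), max(x$set_sizes), sum(x$set_sizes == 0)))
  s <- if_summary(x$snp_if, x$n_subsamples)
  cat(sprintf("SNP level : IF > 0: %d, IF >= 10: %d, max IF %d (%s)\n",
              s$if_gt0, s$if_ge10, s$max_if, s$max_id))
  if (!is.null(x$gene_if)) {
    g <- if_summary(x$gene_if, x$n_subsamples)
    cat(sprintf("gene level: IF > 0: %d, IF >= 10: %d, max IF %d (%s)\n",
                g$if_gt0, g$if_ge10, g$max_if, g$max_id))
  }
  if (x$n_failed > 0) cat(x$n_failed, "subsample run(s) failed\n")
  invisible(x)
}

#' Overlap of two stability reports
#'
#' For each inclusion-frequency threshold, counts the SNPs passing it in
#' only the first report, only the second, and in both, mirroring the usual
#' side-by-side summary of a multivariable versus a univariate selection
#' track.
#'
#' @param report_a,report_b [stability_run()] results over the same SNP
#'   universe and number of subsamples.
#' @param thresholds inclusion-count thresholds; the default corresponds to
#'   IF > 0 and IF >= 10.
#' @param level compare `"snp"` or `"gene"` counts.
#' @return data.frame with columns `threshold`, `a_only`, `b_only`, `both`,
#'   plus attributes `max_a`/`max_b` (most frequently selected id per
#'   report).
#' @export
compare_methods <- function(report_a, report_b, thresholds = c(1L, 10L),
                            level = c("snp", "gene")) {
  level <- match.arg(level)
  ca <- if (level == "snp") report_a$snp_if else report_a$gene_if
  cb <- if (level == "snp") report_b$snp_if else report_b$gene_if
  if (is.null(ca) || is.null(cb)) stop("requested level not present in both reports")
  if (!identical(sort(names(ca)), sort(names(cb)))) {
    stop("reports cover different ", level, " universes")
  }
  if (report_a$n_subsamples != report_b$n_subsamples) {
    stop("reports use different numbers of subsamples")
  }
  cb <- cb[names(ca)]
  out <- do.call(rbind, lapply(thresholds, function(th) {
    ina <- ca >= th
    inb <- cb >= th
    data.frame(threshold = th, a_only = sum(ina & !inb),
               b_only = sum(!ina & inb), both = sum(ina & inb))
  }))
  attr(out, "max_a") <- names(ca)[which.max(ca)]
  attr(out, "max_b") <- names(cb)[which.max(cb)]
  out
}
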