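# Simulation-study harness: repeated data generation, method application and
# per-group type I error / per-SNP power summaries.

# One summary row from per-replicate selection sets and the truth partition.
# Type I error of a group is the mean over replicates of the within-group
# selected proportion; power of an informative SNP is the fraction of
# replicates selecting it.
power_from_selections <- function(sel_sets, truth) {
  n_rep <- length(sel_sets)
  cor_prop <- vapply(sel_sets, function(s)
    if (length(truth$cor_noise)) mean(truth$cor_noise %in% s) else 0, numeric(1))
  uncor_prop <- vapply(sel_sets, function(s)
    if (length(truth$uncor_noise)) mean(truth$uncor_noise %in% s) else 0, numeric(1))
  pow <- vapply(truth$informative$snp_id, function(id)
    mean(vapply(sel_sets, function(s) id %in% s, logical(1))), numeric(1))
  c(type1_cor = mean(cor_prop), type1_uncor = mean(uncor_prop), pow)
}

#' Run a type-I-error and power study over simulated replicates
#'
#' Generates `n_replicates` fresh data sets from `design` and applies each
#' requested selection method: `univariate_fdr` (adjusted screen, BH cut at
#' `level`), `boost_cv` (SNPs with nonzero coefficients at the
#' cross-validation-selected step count) and `boost_fixed` (nonzero
#' coefficients after `fixed_steps` steps). The two boosting variants share
#' one fitted path per replicate, since selection sets at any step count can
#' be read off a single run. Results are summarized as mean type I error
#' over the correlated-noise and uncorrelated-noise SNP groups and power per
#' informative SNP.
#'
#' @param design a [sim_design()] object.
#' @param n_replicates number of simulated data sets (>= 1).
#' @param methods subset of `c("univariate_fdr", "boost_cv", "boost_fixed")`.
#' @param fixed_steps step count for `boost_fixed`.
#' @param level FDR level for the univariate track.
#' @param lambda boosting penalty (`"auto"` = 9 x events).
#' @param cv_max_steps largest step count examined by cross-validation.
#' @param cv_folds cross-validation folds.
#' @param mode univariate screening mode; the genome-wide default is the
#'   offset approximation, see [screen_snps()].
#' @param seed optional integer seed; replicate streams are derived from it
#'   so the report is independent of evaluation order.
#' @return Object of class `"power_report"`: a data.frame with one row per
#'   method and columns `type1_cor`, `type1_uncor` and one power column per
#'   informative SNP; attributes `n_replicates`, `cv_steps`, `set_sizes`.
#' @export
run_study <- function(design, n_replicates,
                      methods = c("univariate_fdr", "boost_cv", "boost_fixed"),
                      fixed_steps = 500, level = 0.05, lambda = "auto",
                      cv_max_steps = 100, cv_folds = 10,
                      mode = c("offset_fast", "joint"), seed = NULL) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, several.ok = TRUE)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L) {
    stop("'n_replicates' must be at least 1")
  }
  truth <- classify_snps(design)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  sels <- lapply(methods, function(m) vector("list", n_replicates))
  names(sels) <- methods
  cv_steps <- rep(NA_integer_, n_replicates)
  need_boost <- any(c("boost_cv", "boost_fixed") %in% methods)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    G <- simulate_genotypes(design)
    ch <- simulate_survival(design, G)
    if ("univariate_fdr" %in% methods) {
      sels$univariate_fdr[[r]] <-
        selected_snps(screen_snps(ch, G, mode = mode, level = level,
                                  warn = FALSE))
    }
    if (need_boost) {
      best <- NA_integer_
      if ("boost_cv" %in% methods) {
        cv <- cv_select_steps(ch, G, lambda = lambda,
                              max_steps = cv_max_steps, cv_folds = cv_folds)
        best <- cv$best_steps
        cv_steps[r] <- best
      }
      path_steps <- max(if ("boost_fixed" %in% methods) fixed_steps else 0L,
                        if (is.na(best)) 0L else best)
      fit <- boost_fit(ch, G, lambda = lambda, n_steps = path_steps)
      if ("boost_cv" %in% methods) {
        sels$boost_cv[[r]] <- if (best > 0L) selected_at(fit, best) else character(0)
      }
      if ("boost_fixed" %in% methods) {
        sels$boost_fixed[[r]] <- selected_at(fit, fixed_steps)
      }
    }
    rm(G)
  }
  rows <- t(vapply(methods, function(m) power_from_selections(sels[[m]], truth),
                   numeric(2 + nrow(truth$informative))))
  out <- data.frame(method = methods, rows, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  class(out) <- c("power_report", "data.frame")
  attr(out, "n_replicates") <- n_replicates
  attr(out, "cv_steps") <- cv_steps
  attr(out, "set_sizes") <- vapply(methods, function(m)
    stats::median(lengths(sels[[m]])), numeric(1))
  out
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("Mean type I error and power over %d simulated replicates\n",
              attr(x, "n_replicates")))
  print.data.frame(x, digits = 3)
  cs <- attr(x, "cv_steps")
  if (any(!is.na(cs))) {
    cat(sprintf("CV-selected steps: median %g (range %d-%d)\n",
                stats::median(cs, na.rm = TRUE), min(cs, na.rm = TRUE),
                max(cs, na.rm = TRUE)))
  }
  invisible(x)
}

#' Pairwise r-squared between SNPs
#'
#' Squared Pearson correlation of 0/1/2 genotype columns (composite linkage
#' disequilibrium on unphased genotypes; no haplotype phasing is attempted).
#'
#' @param genotypes genotype matrix, samples x SNPs.
#' @param snp_ids SNP ids or column indices to include (default: all; at
#'   least 2).
#' @return Symmetric matrix of squared correlations with unit diagonal;
#'   zero-variance SNPs give an `NA` row/column with a warning.
#' @export
pairwise_r2 <- function(genotypes, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  X <- genotypes[, snp_ids, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least two SNPs")
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    warning("zero-variance SNP(s): ",
            paste(colnames(X)[v == 0], collapse = ", "))
  }
  r2 <- suppressWarnings(cor(X))^2
  diag(r2) <- 1
  if (any(v == 0)) {
    r2[v == 0, ] <- NA_real_
    r2[, v == 0] <- NA_real_
  }
  r2
}
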