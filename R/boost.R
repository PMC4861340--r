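# Track 2: componentwise likelihood-based boosting for the Cox model.
# Candidate SNPs are ranked by their unpenalized score statistic (which is
# invariant to the SNP's coding variance), the winning coefficient receives a
# penalized one-step Newton update, and the mandatory covariates are
# re-estimated unpenalized between steps.

resolve_lambda <- function(lambda, status) {
  if (identical(lambda, "auto")) lambda <- 9 * sum(status)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda <= 0) {
    stop("'lambda' must be a positive number or \"auto\"")
  }
  lambda
}

# Core boosting path. `full` (optional) carries the complete data set while
# the path is trained on a fold subset, so the cross-validated partial
# likelihood (Verweij-van Houwelingen: full-data log-likelihood at the
# fold-trained coefficients minus the held-in log-likelihood) can be tracked
# per step, including step 0.
boost_engine <- function(cohort, genotypes, lambda, n_steps,
                         mandatory_refit = "full", full = NULL) {
  n <- cohort$n
  r <- cohort$r
  L <- ncol(genotypes)
  Z <- cohort$covariates
  prep <- cox_prep(cohort$time, cohort$status)
  # genotypes transposed into decreasing-time order once, so the per-step
  # candidate scan streams through memory (see cpp_boost_scan)
  Xt <- t(genotypes[prep$ord, , drop = FALSE])

  fit_mand <- function(offset, init = NULL) {
    if (r == 0L) {
      return(list(coef = numeric(0), eta = numeric(n), converged = TRUE))
    }
    f <- fit_cox(Z, cohort, offset = offset, init = init)
    list(coef = f$coefficients, eta = as.vector(Z %*% f$coefficients),
         converged = f$converged)
  }

  beta_snp <- numeric(L)
  eta_snp <- numeric(n)
  mand <- fit_mand(eta_snp)
  mand_ok <- mand$converged

  sel <- integer(n_steps)
  gam <- numeric(n_steps)
  loglik <- numeric(n_steps + 1L)
  loglik[1L] <- pl_eta(mand$eta + eta_snp, prep)

  track <- !is.null(full)
  if (track) {
    full_prep <- cox_prep(full$time, full$status)
    eta_full_snp <- numeric(full$n)
    full_eta <- function(mand_coef) {
      m <- if (r > 0L) as.vector(full$covariates %*% mand_coef) else 0
      m + eta_full_snp
    }
    cvpl <- numeric(n_steps + 1L)
    cvpl[1L] <- pl_eta(full_eta(mand$coef), full_prep) - loglik[1L]
  }

  m_done <- 0L
  for (m in seq_len(n_steps)) {
    eta <- mand$eta + eta_snp
    w_s <- offset_weights(eta, prep)
    inv_s0 <- 1 / cumsum(w_s)[prep$grp_end][prep$grp]
    si <- cpp_boost_scan(Xt, prep$time_s, prep$status_s, w_s, inv_s0)
    stat <- si$U^2 / si$I
    stat[si$I <= 1e-10] <- -Inf
    if (!any(is.finite(stat))) {
      warning("no informative candidate left; stopping after ", m - 1L, " steps")
      break
    }
    j <- which.max(stat)  # ties resolved to the lowest column index
    gamma <- si$U[j] / (si$I[j] + lambda)
    beta_snp[j] <- beta_snp[j] + gamma
    eta_snp <- eta_snp + gamma * genotypes[, j]
    if (r > 0L) {
      if (mandatory_refit == "full") {
        mand_new <- fit_mand(eta_snp, init = mand$coef)
      } else {  # single damped Newton update from the current estimate
        si_m <- score_and_information(mand$coef, Z, cohort, offset = eta_snp)
        delta <- tryCatch(solve(si_m$I, si_m$U), error = function(e) NULL)
        mand_new <- if (is.null(delta)) {
          list(coef = mand$coef, eta = mand$eta, converged = FALSE)
        } else {
          cf <- mand$coef + delta
          list(coef = cf, eta = as.vector(Z %*% cf), converged = TRUE)
        }
      }
      mand_ok <- mand_ok && mand_new$converged
      mand <- mand_new
    }
    sel[m] <- j
    gam[m] <- gamma
    loglik[m + 1L] <- pl_eta(mand$eta + eta_snp, prep)
    if (track) {
      eta_full_snp <- eta_full_snp + gamma * full$genotypes[, j]
      cvpl[m + 1L] <- pl_eta(full_eta(mand$coef), full_prep) - loglik[m + 1L]
    }
    m_done <- m
  }
  keep <- seq_len(m_done)
  list(beta_snp = beta_snp, mand_coef = mand$coef, sel = sel[keep],
       gamma = gam[keep], loglik = loglik[c(1L, keep + 1L)],
       mand_converged = mand_ok, n_steps = m_done,
       cvpl = if (track) cvpl[seq_len(m_done + 1L)])
}

#' Componentwise likelihood-based Cox boosting
#'
#' Builds a sparse multivariable Cox model over all SNPs simultaneously while
#' keeping the mandatory covariates unpenalized. Starting from the plain
#' partial-likelihood fit of the mandatory covariates (all SNP coefficients
#' zero), each boosting step (a) scores every SNP by its one-dimensional
#' unpenalized score statistic U^2/I at the current linear predictor,
#' (b) selects the maximizer, (c) updates its coefficient by the penalized
#' one-step Newton estimate U/(I + lambda), and (d) re-estimates the
#' mandatory coefficients with the accumulated SNP contribution as fixed
#' offset. Score-statistic selection avoids preferential selection of
#' high-variance SNPs, which matters for 0/1/2-coded genotypes; the penalty
#' only sizes the updates, so larger `lambda` is offset by more steps.
#'
#' @param cohort a [cohort()] object.
#' @param genotypes complete 0/1/2 matrix, samples x SNPs.
#' @param lambda positive penalty, or `"auto"` for 9 x (number of events),
#'   which makes each update roughly a tenth of the unpenalized Newton step.
#' @param n_steps number of boosting steps (0 returns the mandatory-only
#'   model); typically chosen by [cv_select_steps()].
#' @param mandatory_refit `"full"` (Newton to convergence between steps) or
#'   `"onestep"` (a single Newton update, cheaper).
#' @return An object of class `"boost_fit"`: SNP and mandatory coefficients,
#'   the per-step selection history (`steps`: step, snp_id, gamma, loglik of
#'   the training data at the cumulated estimate), the distinct selected SNP
#'   ids, `lambda` and convergence flag for the mandatory refits.
#' @seealso [cv_select_steps()], [selected_at()]
#' @export
boost_fit <- function(cohort, genotypes, lambda = "auto", n_steps = 100,
                      mandatory_refit = c("full", "onestep")) {
  mandatory_refit <- match.arg(mandatory_refit)
  genotypes <- check_genotypes(genotypes, cohort)
  lambda <- resolve_lambda(lambda, cohort$status)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 0L) stop("'n_steps' must be >= 0")
  eng <- boost_engine(cohort, genotypes, lambda, n_steps,
                      mandatory_refit = mandatory_refit)
  snp_ids <- colnames(genotypes)
  names(eng$beta_snp) <- snp_ids
  steps <- data.frame(
    step = seq_len(eng$n_steps),
    snp_id = snp_ids[eng$sel],
    gamma = eng$gamma,
    loglik = eng$loglik[-1L],
    stringsAsFactors = FALSE
  )
  structure(
    list(snp_coefficients = eng$beta_snp,
         mandatory_coefficients = eng$mand_coef,
         steps = steps,
         selected = unique(steps$snp_id),
         loglik_path = eng$loglik,
         lambda = lambda, n_steps = eng$n_steps,
         mandatory_converged = eng$mand_converged),
    class = "boost_fit"
  )
}

#' @export
print.boost_fit <- function(x, ...) {
  cat(sprintf("Componentwise Cox boosting: %d steps, lambda = %g, %d SNP(s) selected\n",
              x$n_steps, x$lambda, length(x$selected)))
  nz <- x$snp_coefficients[x$snp_coefficients != 0]
  if (length(nz)) print(round(sort(nz, decreasing = TRUE), 5))
  if (length(x$mandatory_coefficients)) {
    cat("mandatory coefficients:\n")
    print(round(x$mandatory_coefficients, 5))
  }
  invisible(x)
}

#' SNPs selected within the first m boosting steps
#'
#' Because each step updates exactly one coefficient, the set of SNPs with
#' nonzero estimates after m steps is the set of distinct SNPs updated in
#' steps 1..m, so selection sets for any earlier step count can be read off
#' one fitted path.
#'
#' @param fit a [boost_fit()] object.
#' @param m step count (defaults to the fitted number of steps).
#' @return Character vector of SNP ids.
#' @export
selected_at <- function(fit, m = fit$n_steps) {
  unique(fit$steps$snp_id[fit$steps$step <= m])
}

#' As-data.frame method for boosting fits
#'
#' One row per model component: mandatory covariates first, then every SNP
#' with a nonzero coefficient.
#' @param x a [boost_fit()] object.
#' @param ... unused.
#' @export
as.data.frame.boost_fit <- function(x, ...) {
  first_step <- tapply(x$steps$step, x$steps$snp_id, min)
  n_upd <- table(x$steps$snp_id)
  nz <- names(x$snp_coefficients)[x$snp_coefficients != 0]
  data.frame(
    component_id = c(names(x$mandatory_coefficients), nz),
    type = c(rep("mandatory", length(x$mandatory_coefficients)),
             rep("snp", length(nz))),
    coefficient = c(unname(x$mandatory_coefficients),
                    unname(x$snp_coefficients[nz])),
    first_selected_step = c(rep(NA_integer_, length(x$mandatory_coefficients)),
                            as.integer(first_step[nz])),
    n_times_updated = c(rep(NA_integer_, length(x$mandatory_coefficients)),
                        as.integer(n_upd[nz])),
    stringsAsFactors = FALSE
  )
}

make_cv_folds <- function(status, k) {
  n <- length(status)
  fold <- integer(n)
  for (s in c(0L, 1L)) {
    idx <- which(status == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  # every training set (fold complement) must contain events
  ev_per_fold <- tapply(status, fold, sum)
  if (any(sum(status) - ev_per_fold < 1)) {
    stop("too few events to form ", k, " cross-validation folds")
  }
  fold
}

#' Select the number of boosting steps by cross-validated partial likelihood
#'
#' Partitions subjects into folds stratified by event status, runs the
#' boosting path on each fold complement, and accumulates the
#' Verweij-van Houwelingen cross-validated partial likelihood (full-data
#' log-likelihood at the fold-trained coefficients minus the held-in
#' log-likelihood) at every step in `step_grid`. The grid value maximizing
#' the sum over folds is returned; ties go to the smallest step count.
#'
#' @inheritParams boost_fit
#' @param max_steps largest step count considered.
#' @param cv_folds number of folds (>= 2).
#' @param step_grid increasing step counts to evaluate; must start at 0.
#'   Defaults to `0:max_steps`.
#' @return List of class `"boost_cv"`: `best_steps`, `cvpl` (named vector
#'   over the grid), `folds` (fold assignment), `lambda`.
#' @export
cv_select_steps <- function(cohort, genotypes, lambda = "auto",
                            max_steps = 100, cv_folds = 10, step_grid = NULL,
                            mandatory_refit = "full") {
  genotypes <- check_genotypes(genotypes, cohort)
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("'cv_folds' must be at least 2")
  if (is.null(step_grid)) step_grid <- 0:max_steps
  step_grid <- sort(unique(as.integer(step_grid)))
  if (step_grid[1L] != 0L) stop("'step_grid' must start at 0")
  max_m <- max(step_grid)
  fold <- make_cv_folds(cohort$status, cv_folds)
  full <- list(time = cohort$time, status = cohort$status,
               covariates = cohort$covariates, genotypes = genotypes,
               n = cohort$n)
  cv_total <- numeric(max_m + 1L)
  for (k in seq_len(cv_folds)) {
    tr <- which(fold != k)
    ch_tr <- cohort(cohort$time[tr], cohort$status[tr],
                    if (cohort$r > 0) cohort$covariates[tr, , drop = FALSE])
    lam_k <- resolve_lambda(lambda, ch_tr$status)
    eng <- boost_engine(ch_tr, genotypes[tr, , drop = FALSE], lam_k, max_m,
                        mandatory_refit = mandatory_refit, full = full)
    cv_k <- eng$cvpl
    if (length(cv_k) < max_m + 1L) {  # early stop: carry the last value
      cv_k <- c(cv_k, rep(cv_k[length(cv_k)], max_m + 1L - length(cv_k)))
    }
    cv_total <- cv_total + cv_k
  }
  cvpl <- cv_total[step_grid + 1L]
  names(cvpl) <- step_grid
  best <- step_grid[which.max(cvpl)]
  structure(list(best_steps = best, cvpl = cvpl, folds = fold,
                 lambda = lambda),
            class = "boost_cv")
}

#' @export
print.boost_cv <- function(x, ...) {
  cat(sprintf("Cross-validated boosting step selection: best = %d steps (CV partial likelihood %.3f)\n",
              x$best_steps, max(x$cvpl)))
  invisible(x)
}

#' Boosting fit with cross-validated step count
#'
#' Convenience wrapper: selects the number of steps by [cv_select_steps()],
#' then fits the boosting path on the complete data with that step count.
#'
#' @inheritParams cv_select_steps
#' @return A [boost_fit()] object with the CV result attached as attribute
#'   `"cv"`.
#' @export
boost_cv_fit <- function(cohort, genotypes, lambda = "auto", max_steps = 100,
                         cv_folds = 10, step_grid = NULL,
                         mandatory_refit = "full") {
  cv <- cv_select_steps(cohort, genotypes, lambda = lambda,
                        max_steps = max_steps, cv_folds = cv_folds,
                        step_grid = step_grid,
                        mandatory_refit = mandatory_refit)
  fit <- boost_fit(cohort, genotypes, lambda = lambda,
                   n_steps = cv$best_steps, mandatory_refit = mandatory_refit)
  attr(fit, "cv") <- cv
  fit
}
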