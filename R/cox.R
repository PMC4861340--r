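#' Construct a clinical cohort with a time-to-event endpoint
#'
#' Bundles observed times, event indicators and the mandatory (clinical)
#' covariates that every model in the package adjusts for.
#'
#' @param time positive observed times (minimum of survival and censoring
#'   time).
#' @param status event indicators: 1 if the event was observed, 0 if censored.
#' @param covariates optional numeric matrix (one row per subject) of
#'   mandatory covariates; may have zero columns.
#' @return An object of class `"cohort"`: a list with elements `time`,
#'   `status`, `covariates`, `n` and `r` (number of mandatory covariates).
#' @examples
#' cohort(c(2.3, 1.1, 5.0), c(1, 0, 1), cbind(age = c(61, 48, 55)))
#' @export
cohort <- function(time, status, covariates = NULL) {
  time <- as.numeric(time)
  status <- as.integer(status)
  n <- length(time)
  if (length(status) != n) {
    stop("'time' and 'status' must have equal length")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all observed times must be positive and finite")
  }
  if (!all(status %in% c(0L, 1L))) {
    stop("'status' must only contain 0 (censored) and 1 (event)")
  }
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n) {
    stop("'covariates' must have one row per subject")
  }
  if (anyNA(covariates)) stop("mandatory covariates must be complete")
  structure(
    list(time = time, status = status, covariates = covariates,
         n = n, r = ncol(covariates)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: n = %d subjects, %d events (%.1f%%), %d mandatory covariate(s)\n",
              x$n, sum(x$status), 100 * mean(x$status), x$r))
  invisible(x)
}

# Risk-set bookkeeping shared by the likelihood code and the C kernels:
# indices sorted by decreasing time so the risk set grows front-to-back,
# plus the tie-group structure for the Breslow convention.
cox_prep <- function(time, status) {
  o <- order(time, decreasing = TRUE)
  ts <- time[o]
  r <- rle(ts)
  grp_end <- cumsum(r$lengths)
  grp <- rep.int(seq_along(grp_end), r$lengths)
  list(ord = o, ord0 = as.integer(o - 1L), time_s = ts,
       status_s = as.integer(status[o]), grp = grp, grp_end = grp_end)
}

# Breslow partial log-likelihood from a precomputed linear predictor.
pl_eta <- function(eta, prep) {
  es <- eta[prep$ord]
  m <- max(es)
  denom <- cumsum(exp(es - m))[prep$grp_end][prep$grp]
  ev <- prep$status_s == 1L
  if (!any(ev)) return(0)
  sum(es[ev] - m - log(denom[ev]))
}

# Sorted offset weights for the C kernels: exp(offset - max) in `ord` order.
offset_weights <- function(offset, prep) {
  os <- offset[prep$ord]
  exp(os - max(os))
}

check_beta_inputs <- function(beta, X, cohort, offset) {
  if (!inherits(cohort, "cohort")) stop("'cohort' must be a cohort object")
  X <- as.matrix(X)
  if (nrow(X) != cohort$n) stop("X must have one row per subject")
  if (length(beta) != ncol(X)) stop("length(beta) must equal ncol(X)")
  offset <- rep_len(as.numeric(offset), cohort$n)
  if (anyNA(X) || anyNA(beta) || anyNA(offset) ||
      any(!is.finite(beta)) || any(!is.finite(offset))) {
    stop("NA/NaN/Inf in likelihood inputs")
  }
  list(X = X, offset = offset)
}

#' Cox partial log-likelihood
#'
#' Evaluates the Breslow partial log-likelihood of a Cox proportional hazards
#' model at `beta`, with an optional fixed offset added to the linear
#' predictor. The baseline hazard is left unspecified throughout; only the
#' event-time ordering enters.
#'
#' @param beta coefficient vector (length `ncol(X)`; may be length 0).
#' @param X covariate matrix, one row per subject.
#' @param cohort a [cohort()] object.
#' @param offset fixed per-subject contribution to the linear predictor
#'   (recycled scalar allowed).
#' @return The partial log-likelihood value (0 when there are no events).
#' @export
partial_loglik <- function(beta, X, cohort, offset = 0) {
  inp <- check_beta_inputs(beta, X, cohort, offset)
  prep <- cox_prep(cohort$time, cohort$status)
  eta <- if (ncol(inp$X) > 0L) {
    as.vector(inp$X %*% beta) + inp$offset
  } else {
    inp$offset
  }
  pl_eta(eta, prep)
}

#' Score vector and observed information of the Cox partial likelihood
#'
#' First and second derivatives of [partial_loglik()] at `beta`, with offset
#' support. The information returned is minus the Hessian, accumulated over
#' risk sets (Breslow convention for ties).
#'
#' @inheritParams partial_loglik
#' @return A list with `U` (score vector, length q) and `I` (q x q observed
#'   information matrix).
#' @export
score_and_information <- function(beta, X, cohort, offset = 0) {
  inp <- check_beta_inputs(beta, X, cohort, offset)
  X <- inp$X
  q <- ncol(X)
  prep <- cox_prep(cohort$time, cohort$status)
  if (q == 0L) {
    return(list(U = numeric(0), I = matrix(0, 0, 0)))
  }
  eta <- as.vector(X %*% beta) + inp$offset
  es <- eta[prep$ord]
  w <- exp(es - max(es))
  Xs <- X[prep$ord, , drop = FALSE]
  grp <- prep$grp
  # cumulative risk-set sums per tie group (risk sets are nested in
  # decreasing time, so cumulating group totals walks the risk sets)
  s0 <- cumsum(rowsum(w, grp))
  S1 <- apply(rowsum(Xs * w, grp), 2, cumsum)
  S1 <- matrix(S1, ncol = q)
  pr <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  Xp <- Xs[, pr[, 1], drop = FALSE] * Xs[, pr[, 2], drop = FALSE] * w
  S2 <- apply(rowsum(Xp, grp), 2, cumsum)
  S2 <- matrix(S2, ncol = nrow(pr))
  ne <- rowsum(prep$status_s, grp)[, 1]
  Sxe <- rowsum(Xs * (prep$status_s == 1L), grp)
  evg <- ne > 0
  xbar <- S1 / s0
  U <- colSums(Sxe[evg, , drop = FALSE]) -
    colSums(ne[evg] * xbar[evg, , drop = FALSE])
  I <- matrix(0, q, q)
  for (k in seq_len(nrow(pr))) {
    a <- pr[k, 1]; b <- pr[k, 2]
    val <- sum(ne[evg] * (S2[evg, k] / s0[evg] - xbar[evg, a] * xbar[evg, b]))
    I[a, b] <- val
    I[b, a] <- val
  }
  list(U = U, I = I)
}

#' Fit a Cox proportional hazards model by Newton-Raphson
#'
#' Maximum partial likelihood estimation starting from `beta = 0`, with
#' step-halving whenever a Newton update would decrease the likelihood and an
#' optional fixed offset. Intended for the low-dimensional fits in this
#' package (mandatory covariates, single SNPs); the high-dimensional SNP part
#' is handled by [boost_fit()].
#'
#' @inheritParams partial_loglik
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   update.
#' @param max_iter maximum number of Newton iterations.
#' @param init optional starting coefficient vector (default: zeros); a warm
#'   start from a nearby solution saves iterations in repeated refits.
#' @return An object of class `"cox_fit"`: list with `coefficients`, `se`,
#'   `loglik`, `converged`, `n_iter` and the `offset` used. With zero
#'   covariate columns the coefficient vector is empty and `loglik` is the
#'   offset-only partial log-likelihood.
#' @export
fit_cox <- function(X, cohort, offset = 0, tol = 1e-8, max_iter = 50,
                    init = NULL) {
  inp <- check_beta_inputs(numeric(ncol(as.matrix(X))), X, cohort, offset)
  X <- inp$X
  offset <- inp$offset
  q <- ncol(X)
  prep <- cox_prep(cohort$time, cohort$status)
  if (q == 0L) {
    return(structure(
      list(coefficients = numeric(0), se = numeric(0),
           loglik = pl_eta(offset, prep), converged = TRUE, n_iter = 0L,
           offset = offset),
      class = "cox_fit"
    ))
  }
  rng <- apply(X, 2, function(col) diff(range(col)))
  if (any(rng == 0)) {
    stop("constant covariate column(s): ",
         paste(colnames(X)[rng == 0], collapse = ", "))
  }
  if (q >= sum(cohort$status)) {
    stop("more coefficients than events")
  }
  beta <- if (is.null(init)) numeric(q) else {
    stopifnot(length(init) == q)
    as.numeric(init)
  }
  ll <- pl_eta(as.vector(X %*% beta) + offset, prep)
  converged <- FALSE
  iter <- 0L
  I <- NULL
  for (iter in seq_len(max_iter)) {
    si <- score_and_information(beta, X, cohort, offset)
    I <- si$I
    delta <- tryCatch(solve(si$I, si$U), error = function(e) NULL)
    if (is.null(delta) || anyNA(delta) || any(!is.finite(delta))) {
      converged <- FALSE
      break
    }
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pl_eta(as.vector(X %*% cand) + offset, prep)
      if (ll_new >= ll - 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll <- ll_new
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  se <- rep(NA_real_, q)
  if (!is.null(I)) {
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (!is.null(Iinv)) se <- sqrt(pmax(diag(Iinv), 0))
  }
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  structure(
    list(coefficients = beta, se = se, loglik = ll, converged = converged,
         n_iter = iter, offset = offset),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model fit (%s, %d Newton iteration(s))\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (length(x$coefficients)) {
    print(data.frame(coef = x$coefficients, se = x$se,
                     p = wald_pvalue(x$coefficients, x$se)))
  }
  cat(sprintf("partial log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Two-sided Wald test p-value
#'
#' @param coef estimated coefficient(s).
#' @param se corresponding standard error(s); must be positive.
#' @return Two-sided p-value(s) from the standard normal reference for
#'   `coef / se`.
#' @examples
#' wald_pvalue(0.53, 0.21)
#' @export
wald_pvalue <- function(coef, se) {
  if (any(!is.na(se) & se <= 0)) stop("standard errors must be positive")
  2 * pnorm(-abs(coef / se))
}
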