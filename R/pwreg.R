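#' Fit the proportional win-fractions (PW) model
#'
#' Solves the U-statistic estimating equation
#' `sum_{i<j} (Z_i - Z_j) M_ij(Inf; beta) = 0` by Newton-Raphson with the
#' exact Jacobian. The score is the gradient of a concave pairwise
#' pseudo-likelihood, so iteration from `beta = 0` is stable. Alongside the
#' coefficient estimate, the fit stores the Hessian-type matrix `A_hat`,
#' the per-subject projection terms `kappa_hat` and the robust sandwich
#' variance of `beta_hat`, all of which feed the influence-function
#' variance of downstream win-loss predictions.
#'
#' @param cohort a `wl_cohort`.
#' @param stratified when the cohort carries strata, restrict comparisons
#'   to within-stratum pairs while sharing `beta` across strata
#'   (default `TRUE`).
#' @param tol convergence tolerance on the max-norm of the score divided by
#'   the number of pairs.
#' @param max_iter maximum Newton iterations.
#' @return object of class `pw_fit`: list with `beta` (named p-vector of
#'   log win ratios), `var` (sandwich variance of `beta`), `A` (the
#'   negative-semidefinite limiting Jacobian, normalized by `choose(n, 2)`),
#'   `kappa` (n x p matrix of per-subject terms), `pairs` (the pairwise
#'   table at `t = Inf`), `iterations`, `score_norm`, and the cohort.
#' @examples
#' cfg <- sim_config(n = 100)
#' ch <- simulate_cohort(cfg, seed = 1)
#' fit <- fit_pw(ch)
#' summary(fit)
#' @export
fit_pw <- function(cohort, stratified = TRUE, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(cohort, "wl_cohort"))
  n <- cohort$n
  if (stratified && nlevels(cohort$stratum) > 1L) {
    small <- table(cohort$stratum) < 2L
    if (any(small))
      warning("strata with fewer than 2 subjects contribute no comparisons: ",
              paste(names(small)[small], collapse = ", "))
  }
  pairs <- pairwise_table(cohort, t = Inf, stratified = stratified)
  if (sum(pairs$R) == 0L)
    stop("no comparable pairs: every pairwise comparison is a tie", call. = FALSE)
  comp <- pairs$R == 1L
  if (all(abs(pairs$Zd[comp, , drop = FALSE]) < 1e-12))
    stop("degenerate design: no covariate variation among comparable pairs",
         call. = FALSE)

  npairs <- choose(n, 2)
  p <- cohort$p
  beta <- numeric(p)
  Zd <- pairs$Zd
  iter <- 0L
  converged <- FALSE
  repeat {
    mu <- drop(stats::plogis(Zd %*% beta))
    M <- pairs$dij - pairs$R * mu
    score <- drop(crossprod(Zd, M))
    if (max(abs(score)) / npairs < tol) {
      if (converged) break
      converged <- TRUE  # one polishing step past the tolerance
    }
    if (!converged && iter >= max_iter)
      stop("PW estimating equation did not converge in ", max_iter,
           " iterations", call. = FALSE)
    w <- pairs$R * mu * (1 - mu)
    J <- -crossprod(Zd * w, Zd)
    qrJ <- qr(J)
    if (qrJ$rank < p)
      stop("singular Jacobian: collinear covariates or degenerate design",
           call. = FALSE)
    beta <- beta - drop(solve(qrJ, score))
    iter <- iter + 1L
  }

  mu <- drop(stats::plogis(Zd %*% beta))
  M <- pairs$dij - pairs$R * mu
  w <- pairs$R * mu * (1 - mu)
  A <- -crossprod(Zd * w, Zd) / npairs
  # each unordered pair contributes (Z_i - Z_j) M_ij to both endpoints
  contrib <- Zd * M
  kappa <- rowsum(rbind(contrib, contrib),
                  group = c(pairs$i, pairs$j), reorder = TRUE) / (n - 1)
  B <- crossprod(kappa) / n
  Ainv <- solve(A)
  V <- (4 / n) * Ainv %*% B %*% Ainv

  nm <- colnames(cohort$Z)
  names(beta) <- nm
  dimnames(V) <- dimnames(A) <- list(nm, nm)
  colnames(kappa) <- nm

  structure(list(beta = beta, var = V, A = A, kappa = kappa, pairs = pairs,
                 iterations = iter, score_norm = max(abs(pw_score(beta, pairs))) / npairs,
                 n = n, p = p, cohort = cohort,
                 fingerprint = cohort_fingerprint(cohort),
                 stratified = stratified && nlevels(cohort$stratum) > 1L),
            class = "pw_fit")
}

#' @export
print.pw_fit <- function(x, ...) {
  cat("Proportional win-fractions model fit (n =", x$n, ")\n")
  if (x$stratified) cat("  stratified:", nlevels(x$cohort$stratum), "strata\n")
  print(summary(x)$table, digits = 4)
  invisible(x)
}

#' Summarize a PW model fit
#'
#' @param object a `pw_fit`.
#' @param level confidence level for the win-ratio intervals.
#' @param ... ignored.
#' @return object of class `summary.pw_fit` containing a coefficient table
#'   with estimates, robust standard errors, win ratios with confidence
#'   limits and Wald p-values.
#' @export
summary.pw_fit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$var))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  zval <- object$beta / se
  tab <- data.frame(estimate = object$beta, se = se,
                    win_ratio = exp(object$beta),
                    wr_lower = exp(object$beta - zc * se),
                    wr_upper = exp(object$beta + zc * se),
                    p_value = 2 * stats::pnorm(-abs(zval)))
  rownames(tab) <- names(object$beta)
  structure(list(table = tab, level = level, n = object$n,
                 iterations = object$iterations),
            class = "summary.pw_fit")
}

#' @export
print.summary.pw_fit <- function(x, ...) {
  cat("PW model coefficient summary (", 100 * x$level, "% CI):\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}
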