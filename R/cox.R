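#' Fit the Cox model for the time to first event
#'
#' Fits a (optionally stratified) Cox proportional-hazards model for the
#' time to the first component event (death or first nonfatal event), the
#' endpoint whose survival function determines the pairwise tie
#' probability. The partial-likelihood maximizer is obtained through
#' [survival::coxph()] with Breslow tie handling; all risk-set aggregates
#' needed by the influence-function variance of win-loss predictions
#' (Breslow baseline, `s^(k)` sums, information matrix, martingale and
#' score integrals) are computed here at the observed event times,
#' stratum by stratum.
#'
#' @param cohort a `wl_cohort`.
#' @param stratified fit stratum-specific baselines when the cohort carries
#'   strata (default `TRUE`); the covariate effect is shared.
#' @return object of class `cox_tfe`: list with `gamma` (coefficients),
#'   `info` (information matrix divided by n), `strata` (per-stratum
#'   baseline tables: event times, event counts, normalized risk sums
#'   `s0`, risk-weighted covariate means `E`, Breslow increments `dL`),
#'   per-subject data (`time`, `status`, `risk_score`, `stratum_idx`),
#'   and the underlying `coxph` fit.
#' @examples
#' ch <- simulate_cohort(sim_config(n = 100), seed = 1)
#' fit <- fit_cox_tfe(ch)
#' fit$gamma
#' @export
fit_cox_tfe <- function(cohort, stratified = TRUE) {
  stopifnot(inherits(cohort, "wl_cohort"))
  tfe <- derive_tfe(cohort)
  if (sum(tfe$status) == 0L)
    stop("no observed events: cannot fit the time-to-first-event model",
         call. = FALSE)
  n <- cohort$n
  p <- cohort$p
  Z <- cohort$Z
  use_strata <- stratified && nlevels(cohort$stratum) > 1L
  df <- data.frame(.time = tfe$time, .status = tfe$status)
  df <- cbind(df, as.data.frame(Z))
  zn <- colnames(Z)
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(sprintf("`%s`", zn), collapse = " + "),
                                 if (use_strata) "+ survival::strata(.strat)" else ""))
  if (use_strata) df$.strat <- cohort$stratum
  cph <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow"),
    warning = function(w) {
      if (grepl("did not converge|infinite|out of iterations",
                conditionMessage(w)))
        stop("Cox partial likelihood did not converge ",
             "(monotone likelihood / divergent coefficient?)", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!is.null(cph$fail) || any(!is.finite(stats::coef(cph))))
    stop("Cox partial likelihood maximization failed", call. = FALSE)
  gamma <- unname(stats::coef(cph))
  risk <- drop(exp(Z %*% gamma))

  strat_levels <- if (use_strata) levels(cohort$stratum) else "1"
  strat_idx <- if (use_strata) as.integer(cohort$stratum) else rep(1L, n)

  info <- matrix(0, p, p)
  strata_tabs <- vector("list", length(strat_levels))
  for (l in seq_along(strat_levels)) {
    sel <- which(strat_idx == l)
    nl <- length(sel)
    tl <- tfe$time[sel]; dl <- tfe$status[sel]
    rl <- risk[sel]; Zl <- Z[sel, , drop = FALSE]
    ut <- sort(unique(tl[dl == 1L]))
    K <- length(ut)
    s0 <- numeric(K); E <- matrix(0, K, p); dcount <- numeric(K); dL <- numeric(K)
    for (k in seq_len(K)) {
      at_risk <- tl >= ut[k]
      S0 <- sum(rl[at_risk])
      S1 <- drop(crossprod(Zl[at_risk, , drop = FALSE], rl[at_risk]))
      Zr <- Zl[at_risk, , drop = FALSE]
      S2 <- crossprod(Zr * rl[at_risk], Zr)
      dk <- sum(dl == 1L & tl == ut[k])
      s0[k] <- S0 / nl
      E[k, ] <- S1 / S0
      dL[k] <- dk / S0
      dcount[k] <- dk
      info <- info + (S2 / S0 - tcrossprod(S1 / S0)) * dk
    }
    strata_tabs[[l]] <- list(time = ut, dcount = dcount, s0 = s0, E = E,
                             dL = dL, n_l = nl, max_time = max(tl),
                             cumL = cumsum(dL),
                             cumEdL = matrix(apply(E * dL, 2, cumsum), K, p))
  }
  info <- info / n
  names(gamma) <- zn
  dimnames(info) <- list(zn, zn)

  structure(list(gamma = gamma, info = info, strata = strata_tabs,
                 strat_levels = strat_levels, strat_idx = strat_idx,
                 time = tfe$time, status = tfe$status, risk_score = risk,
                 Z = Z, n = n, p = p, coxph = cph,
                 fingerprint = cohort_fingerprint(cohort)),
            class = "cox_tfe")
}

#' @export
print.cox_tfe <- function(x, ...) {
  cat("Cox time-to-first-event fit (Breslow baseline), n =", x$n,
      ", events =", sum(x$status), "\n")
  print(data.frame(gamma = x$gamma,
                   se = sqrt(diag(solve(x$info * x$n)))), digits = 4)
  invisible(x)
}

resolve_stratum <- function(fit, stratum) {
  if (is.null(stratum)) {
    if (length(fit$strat_levels) > 1L)
      stop("a stratum must be specified for a stratified fit", call. = FALSE)
    return(1L)
  }
  l <- match(as.character(stratum), fit$strat_levels)
  if (is.na(l)) stop("unknown stratum: ", stratum, call. = FALSE)
  l
}

# cumulative baseline hazard at times t (vectorized), step function,
# carried forward beyond the last event time
baseline_cumhaz <- function(fit, t, stratum_l = 1L) {
  st <- fit$strata[[stratum_l]]
  idx <- findInterval(t, st$time)
  c(0, st$cumL)[idx + 1L]
}

#' Predicted survival function from a Cox TFE fit
#'
#' `S(t | z) = exp(-exp(gamma'z) * Lambda_0(t))`, evaluated as a
#' right-continuous step function; beyond the last observed time in the
#' stratum the baseline is carried forward and the result carries an
#' `extrapolated` attribute.
#'
#' @param fit a `cox_tfe` fit.
#' @param z covariate vector.
#' @param t time(s), `>= 0`.
#' @param stratum stratum label (required for stratified fits).
#' @return vector of survival probabilities with attribute `extrapolated`.
#' @export
predict_survival <- function(fit, z, t, stratum = NULL) {
  stopifnot(inherits(fit, "cox_tfe"), all(t >= 0))
  l <- resolve_stratum(fit, stratum)
  L <- baseline_cumhaz(fit, t, l)
  s <- exp(-exp(sum(fit$gamma * z)) * L)
  attr(s, "extrapolated") <- t > fit$strata[[l]]$max_time
  s
}

#' Influence-function building blocks of the Cox fit
#'
#' Computes, at horizon `t` and profile `z`, the three ingredients of the
#' influence expansion of the predicted survival probability:
#' `H(t; z) = exp(gamma'z) * int_0^t (z - E(u)) dLambda_0(u)`, the
#' per-subject score integrals `int (Z_i - E(u)) dM_i(u)` over all time,
#' and the per-subject Breslow integrals `int_0^t s0(u)^-1 dM_i(u)`, where
#' `M_i` is the subject's martingale residual process. In stratified fits
#' each subject's integrals use its own stratum's baseline and risk sets
#' (with a stratum-size rescaling on the Breslow part), while `H` and the
#' `s0` integrals are reported for the requested stratum.
#'
#' @param fit a `cox_tfe` fit.
#' @param z covariate profile for `H`.
#' @param t nonnegative horizon.
#' @param stratum stratum label for `H` and the Breslow-part truncation.
#' @return list with `H` (p-vector), `score_int` (n x p matrix) and
#'   `s0_int` (n-vector).
#' @export
cox_influence_pieces <- function(fit, z, t, stratum = NULL) {
  stopifnot(inherits(fit, "cox_tfe"))
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  l <- resolve_stratum(fit, stratum)
  n <- fit$n; p <- fit$p
  st <- fit$strata[[l]]
  upto <- st$time <= t
  H <- exp(sum(fit$gamma * z)) *
    (z * sum(st$dL[upto]) -
       (if (any(upto)) drop(crossprod(st$E[upto, , drop = FALSE], st$dL[upto]))
        else numeric(p)))

  score_int <- matrix(0, n, p)
  s0_int <- numeric(n)
  for (ll in seq_along(fit$strata)) {
    sel <- which(fit$strat_idx == ll)
    stl <- fit$strata[[ll]]
    K <- length(stl$time)
    if (K == 0L) next
    ti <- fit$time[sel]; di <- fit$status[sel]; ri <- fit$risk_score[sel]
    Zi <- fit$Z[sel, , drop = FALSE]
    pos <- findInterval(ti, stl$time)        # index of last event time <= X_i
    cumL <- c(0, stl$cumL); cumEdL <- rbind(0, stl$cumEdL)
    # score residual: d_i (Z_i - E(X_i)) - r_i [Z_i L0(X_i) - int E dL0]
    ev_at <- match(ti, stl$time)             # defined where d_i = 1
    Ei <- matrix(0, length(sel), p)
    has <- di == 1L & !is.na(ev_at)
    if (any(has)) Ei[has, ] <- stl$E[ev_at[has], , drop = FALSE]
    score_int[sel, ] <- di * (Zi - Ei) -
      ri * (Zi * cumL[pos + 1L] - cumEdL[pos + 1L, , drop = FALSE])
    if (ll == l) {
      # Breslow part, truncated at t; stratified fits rescale by n / n_l so
      # that n^-1 * sum over the stratum reproduces the Breslow influence
      cum_s0 <- c(0, cumsum(stl$dL / stl$s0))
      pos_t <- findInterval(pmin(ti, t), stl$time)
      jump <- ifelse(di == 1L & ti <= t & !is.na(ev_at),
                     1 / stl$s0[ifelse(is.na(ev_at), 1L, ev_at)], 0)
      s0_int[sel] <- (n / stl$n_l) * (jump - ri * cum_s0[pos_t + 1L])
    }
  }
  list(H = H, score_int = score_int, s0_int = s0_int)
}

#' Martingale residuals of the Cox TFE fit
#'
#' `M_i(Inf) = d_i - exp(gamma'Z_i) Lambda_0(X_i)`; useful for checking
#' the functional form of quantitative covariates in the TFE model.
#'
#' @param fit a `cox_tfe` fit.
#' @return n-vector summing to zero.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_tfe"))
  out <- numeric(fit$n)
  for (l in seq_along(fit$strata)) {
    sel <- which(fit$strat_idx == l)
    out[sel] <- fit$status[sel] -
      fit$risk_score[sel] * baseline_cumhaz(fit, fit$time[sel], l)
  }
  out
}

#' Schoenfeld residuals of the Cox TFE fit
#'
#' `Z_(i) - E(u_i)` at each observed event, the standard proportional-
#' hazards diagnostic: residuals sum to zero and should show no trend in
#' time under proportional hazards.
#'
#' @param fit a `cox_tfe` fit.
#' @return data.frame with `time`, `stratum` and one column per covariate.
#' @export
schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_tfe"))
  rows <- list()
  for (l in seq_along(fit$strata)) {
    sel <- fit$strat_idx == l & fit$status == 1L
    if (!any(sel)) next
    ti <- fit$time[sel]
    Ei <- fit$strata[[l]]$E[match(ti, fit$strata[[l]]$time), , drop = FALSE]
    res <- fit$Z[sel, , drop = FALSE] - Ei
    rows[[l]] <- data.frame(time = ti, stratum = fit$strat_levels[l], res)
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- colnames(fit$Z)
  out[order(out$time), ]
}
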