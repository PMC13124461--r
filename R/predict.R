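#' Pairwise tie probability from the TFE model
#'
#' A pair is tied at time t exactly when both subjects are free of any
#' component event, so the tie probability factorizes as the product of
#' two time-to-first-event survival functions:
#' `nu(t | z, z*) = S(t | z) * S(t | z*)`.
#'
#' @param fit a `cox_tfe` fit.
#' @param z,z_star covariate profiles.
#' @param t time(s).
#' @param stratum stratum label (stratified fits).
#' @return tie probability, nonincreasing in `t`, equal to 1 at `t = 0`.
#' @export
tie_probability <- function(fit, z, z_star, t, stratum = NULL) {
  as.numeric(predict_survival(fit, z, t, stratum) *
               predict_survival(fit, z_star, t, stratum))
}

#' Per-subject influence contributions for a predicted win probability
#'
#' Assembles the estimated influence function of `w_hat(t | z, z*)`, the
#' predicted probability that a subject with profile `z` beats one with
#' profile `z*` by time `t`. Each subject's contribution combines (i) the
#' Cox-model part — the gradient of the tie probability propagated through
#' the partial-likelihood score and Breslow-baseline influences — and
#' (ii) the PW-model part, `-2 w (1 - mu) (z - z*)' A^-1 kappa_i`. The
#' empirical second moment of the contributions divided by n^2 estimates
#' the variance of `w_hat`.
#'
#' @param pw a `pw_fit`.
#' @param cox a `cox_tfe` fit on the same cohort.
#' @param z,z_star covariate profiles.
#' @param t single nonnegative time.
#' @param stratum stratum label (stratified fits).
#' @return n-vector of influence contributions (mean approximately zero).
#' @export
influence_w <- function(pw, cox, z, z_star, t, stratum = NULL) {
  check_same_cohort(pw, cox)
  mu0 <- drop(stats::plogis(sum(pw$beta * (z - z_star))))
  l <- resolve_stratum(cox, stratum)
  Sz <- as.numeric(predict_survival(cox, z, t, stratum))
  Szs <- as.numeric(predict_survival(cox, z_star, t, stratum))
  pz <- cox_influence_pieces(cox, z, t, stratum)
  pzs <- cox_influence_pieces(cox, z_star, t, stratum)
  H <- pz$H + pzs$H
  what <- (1 - Sz * Szs) * mu0
  cox_part <- mu0 * Sz * Szs *
    (drop(pz$score_int %*% solve(cox$info, H)) +
       (exp(sum(cox$gamma * z)) + exp(sum(cox$gamma * z_star))) * pz$s0_int)
  pw_part <- -2 * what * (1 - mu0) *
    drop(pw$kappa %*% solve(pw$A, z - z_star))
  unname(cox_part + pw_part)
}

#' Robust covariance of a win and a loss probability estimate
#'
#' `n^-2 * sum_i IF_w(i) * IF_l(i)`, combining the per-subject influence
#' contributions of the two estimates from the same fitted models.
#'
#' @param influences_w,influences_l n-vectors of influence contributions.
#' @return scalar covariance estimate.
#' @export
winloss_covariance <- function(influences_w, influences_l) {
  if (length(influences_w) != length(influences_l))
    stop("influence vectors have different lengths", call. = FALSE)
  sum(influences_w * influences_l) / length(influences_w)^2
}

check_same_cohort <- function(pw, cox) {
  if (!isTRUE(all.equal(pw$fingerprint, cox$fingerprint)))
    stop("the PW and Cox fits do not come from the same cohort", call. = FALSE)
}

#' Predict absolute win-loss probabilities over time
#'
#' Combines a proportional win-fractions fit (which pins down the constant
#' win/loss ratio `exp(beta'(z - z*))`) with a Cox time-to-first-event fit
#' (which supplies the tie probability) to produce the full trinomial
#' win / loss / tie probability curves for a pair of covariate profiles:
#' `w(t | z, z*) = {1 - S(t|z) S(t|z*)} * expit(beta'(z - z*))`.
#' Pointwise standard errors come from the estimated influence expansion,
#' and confidence intervals use the logit transformation so they stay in
#' `[0, 1]`.
#'
#' @param pw a `pw_fit`.
#' @param cox a `cox_tfe` fit on the same cohort.
#' @param z,z_star covariate profiles (length-p vectors).
#' @param times evaluation time grid; defaults to the observed TFE event
#'   times. Times beyond the last observed time are flagged as
#'   extrapolated (baseline carried forward).
#' @param level confidence level (default 0.95).
#' @param stratum stratum label (stratified fits).
#' @return object of class `winloss_curve`: a data.frame with columns
#'   `t`, `w`, `l`, `tie`, `se_w`, `se_l`, `cov_wl`, `w_lower`, `w_upper`,
#'   `l_lower`, `l_upper`, `degenerate`, `extrapolated`; attributes carry
#'   the per-subject influence matrices (for contrast variance), the
#'   profiles and the fits.
#' @examples
#' ch <- simulate_cohort(sim_config(n = 150), seed = 7)
#' pw <- fit_pw(ch)
#' cox <- fit_cox_tfe(ch)
#' cv <- predict_winloss(pw, cox, z = c(1, 0, 0), z_star = c(0, 0, 0),
#'                       times = c(0.5, 1, 2, 4))
#' cv
#' @export
predict_winloss <- function(pw, cox, z, z_star, times = NULL, level = 0.95,
                            stratum = NULL) {
  check_same_cohort(pw, cox)
  if (length(z) != pw$p || length(z_star) != pw$p)
    stop("covariate profiles must have length p = ", pw$p, call. = FALSE)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  l <- resolve_stratum(cox, stratum)
  if (is.null(times)) times <- cox$strata[[l]]$time
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  times <- sort(times)
  n <- pw$n
  mu0 <- drop(stats::plogis(sum(pw$beta * (z - z_star))))
  zc <- stats::qnorm(1 - (1 - level) / 2)

  Tn <- length(times)
  w <- l_ <- tie <- se_w <- se_l <- cov_wl <- numeric(Tn)
  IFw <- IFl <- matrix(0, n, Tn)
  extrap <- logical(Tn)
  for (k in seq_len(Tn)) {
    Sz <- predict_survival(cox, z, times[k], stratum)
    Szs <- predict_survival(cox, z_star, times[k], stratum)
    extrap[k] <- any(attr(Sz, "extrapolated"))
    tie[k] <- as.numeric(Sz) * as.numeric(Szs)
    w[k] <- (1 - tie[k]) * mu0
    l_[k] <- (1 - tie[k]) * (1 - mu0)
    IFw[, k] <- influence_w(pw, cox, z, z_star, times[k], stratum)
    IFl[, k] <- influence_w(pw, cox, z_star, z, times[k], stratum)
    se_w[k] <- sqrt(sum(IFw[, k]^2)) / n
    se_l[k] <- sqrt(sum(IFl[, k]^2)) / n
    cov_wl[k] <- winloss_covariance(IFw[, k], IFl[, k])
  }

  ci_w <- logit_ci(w, se_w, zc)
  ci_l <- logit_ci(l_, se_l, zc)
  out <- data.frame(t = times, w = w, l = l_, tie = tie,
                    se_w = se_w, se_l = se_l, cov_wl = cov_wl,
                    w_lower = ci_w$lower, w_upper = ci_w$upper,
                    l_lower = ci_l$lower, l_upper = ci_l$upper,
                    degenerate = ci_w$degenerate | ci_l$degenerate,
                    extrapolated = extrap)
  structure(out, class = c("winloss_curve", "data.frame"),
            influence_w = IFw, influence_l = IFl,
            z = z, z_star = z_star, level = level, mu = mu0,
            pw = pw, n = n)
}

# logit-transformed interval; degenerate at p in {0, 1} (transform
# undefined) where the interval collapses to the point estimate and is
# flagged
logit_ci <- function(p, se, zc) {
  degenerate <- p <= 0 | p >= 1 | se == 0
  lower <- upper <- p
  ok <- !degenerate
  sl <- se[ok] / (p[ok] * (1 - p[ok]))
  lower[ok] <- stats::plogis(stats::qlogis(p[ok]) - zc * sl)
  upper[ok] <- stats::plogis(stats::qlogis(p[ok]) + zc * sl)
  list(lower = lower, upper = upper, degenerate = degenerate)
}

#' @export
print.winloss_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Win-loss probability curve (%d time point%s, %.0f%% CI)\n",
              nrow(x), if (nrow(x) == 1) "" else "s",
              100 * attr(x, "level")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Contrast measures along a win-loss curve
#'
#' From a fitted win-loss curve, computes the three standard contrasts:
#' the win ratio `WR = exp(beta'(z - z*))` (constant over time under the
#' PW model, with a lognormal interval from the sandwich variance of
#' `beta`), the net benefit `NB(t) = w(t) - l(t)` with an
#' arctanh-transformed interval, and the win odds
#' `WO(t) = (1 + NB)/(1 - NB)` whose interval is the exponential of twice
#' the arctanh interval — so the NB and WO intervals are images of one
#' another under the monotone map and always respect `[-1, 1]` and
#' `[0, Inf)`.
#'
#' @param curve a `winloss_curve` from [predict_winloss()].
#' @return object of class `contrast_curve`: data.frame with columns `t`,
#'   `nb`, `se_nb`, `nb_lower`, `nb_upper`, `wo`, `wo_lower`, `wo_upper`,
#'   `degenerate`; attributes `wr`, `wr_lower`, `wr_upper`, `level`.
#' @export
contrast_curves <- function(curve) {
  stopifnot(inherits(curve, "winloss_curve"))
  pw <- attr(curve, "pw")
  z <- attr(curve, "z"); zs <- attr(curve, "z_star")
  level <- attr(curve, "level")
  zc <- stats::qnorm(1 - (1 - level) / 2)
  n <- attr(curve, "n")

  dz <- z - zs
  lwr <- sum(pw$beta * dz)
  se_lwr <- sqrt(drop(t(dz) %*% pw$var %*% dz))
  wr <- exp(lwr); wr_lo <- exp(lwr - zc * se_lwr); wr_hi <- exp(lwr + zc * se_lwr)

  IFw <- attr(curve, "influence_w"); IFl <- attr(curve, "influence_l")
  nb <- curve$w - curve$l
  se_nb <- sqrt(pmax(curve$se_w^2 + curve$se_l^2 - 2 * curve$cov_wl, 0))
  degen <- abs(nb) >= 1 | se_nb == 0
  nb_lo <- nb_hi <- nb
  ok <- !degen
  half <- zc * se_nb[ok] / (1 - nb[ok]^2)
  nb_lo[ok] <- tanh(atanh(nb[ok]) - half)
  nb_hi[ok] <- tanh(atanh(nb[ok]) + half)
  wo <- (1 + nb) / (1 - nb)
  wo_lo <- (1 + nb_lo) / (1 - nb_lo)
  wo_hi <- (1 + nb_hi) / (1 - nb_hi)

  out <- data.frame(t = curve$t, nb = nb, se_nb = se_nb,
                    nb_lower = nb_lo, nb_upper = nb_hi,
                    wo = wo, wo_lower = wo_lo, wo_upper = wo_hi,
                    degenerate = degen)
  structure(out, class = c("contrast_curve", "data.frame"),
            wr = wr, wr_lower = wr_lo, wr_upper = wr_hi, level = level)
}

#' @export
print.contrast_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Win ratio (constant): %.4g [%.4g, %.4g] (%.0f%% CI)\n",
              attr(x, "wr"), attr(x, "wr_lower"), attr(x, "wr_upper"),
              100 * attr(x, "level")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Export a win-loss or contrast curve as delimited text
#'
#' Writes one row per grid point with all point estimates, standard errors
#' and interval bounds at 6 significant digits (or full precision).
#'
#' @param curve a `winloss_curve` or `contrast_curve`.
#' @param path output file path.
#' @param sep field separator.
#' @param full_precision write full double precision instead of 6
#'   significant digits.
#' @return the path, invisibly.
#' @export
export_curve <- function(curve, path, sep = ",", full_precision = FALSE) {
  df <- as.data.frame(curve)
  if (!full_precision)
    df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 6) else col)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
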