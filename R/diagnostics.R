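#' Subject-specific win residuals
#'
#' `Mhat_i = (n-1)^-1 sum_{j != i} M_ij(Inf; beta_hat)`: the observed
#' minus model-predicted proportion of wins for subject i against the rest
#' of the cohort. Plotted against a quantitative covariate, a systematic
#' trend indicates a misspecified functional form (e.g. a ceiling effect
#' fitted linearly shows residuals drifting negative beyond the plateau).
#' The residuals sum to zero exactly by pairwise antisymmetry.
#'
#' @param pw a `pw_fit`.
#' @return data.frame with `id`, `residual` and the covariate columns.
#' @export
subject_win_residuals <- function(pw) {
  stopifnot(inherits(pw, "pw_fit"))
  pairs <- pw$pairs
  M <- pairwise_residual(pairs, pw$beta)
  # M_ji = -M_ij: subject j's running sum takes the pair with flipped sign
  r <- rowsum(c(M, -M), group = c(pairs$i, pairs$j), reorder = TRUE) /
    (pw$n - 1)
  out <- data.frame(id = pw$cohort$id, residual = unname(drop(r)))
  cbind(out, as.data.frame(pw$cohort$Z))
}

#' Cumulative score-residual process of the PW model
#'
#' `U(t) = choose(n, 2)^-1 sum_{i<j} (Z_i - Z_j) M_ij(t; beta_hat)`,
#' evaluated over a time grid. Under the proportional win-fractions
#' assumption the process fluctuates around zero; it equals zero exactly
#' at `t = 0` and (by the estimating equation) at the maximum follow-up.
#' A standardized version divides each component by the root sum of
#' squares of its pairwise increments,
#' `{sum_{i<j} (Z_i - Z_j)_k^2 M_ij(Inf)^2}^{1/2}`, for scale-free visual
#' trend detection; formal invariants are on the unstandardized process.
#'
#' @param pw a `pw_fit`.
#' @param grid evaluation times; defaults to the observed TFE event times
#'   (thinned to at most `max_points`), with 0 and the maximum follow-up
#'   appended.
#' @param max_points cap on the default grid size.
#' @return data.frame with `t`, one column per covariate (unstandardized),
#'   and matching `*_std` columns.
#' @export
score_process <- function(pw, grid = NULL, max_points = 100L) {
  stopifnot(inherits(pw, "pw_fit"))
  cohort <- pw$cohort
  if (is.null(grid)) {
    tfe <- derive_tfe(cohort)
    ev <- sort(unique(tfe$time[tfe$status == 1L]))
    if (length(ev) > max_points)
      ev <- stats::quantile(ev, seq(0, 1, length.out = max_points),
                            type = 1, names = FALSE)
    grid <- sort(unique(c(0, ev, max(cohort$X))))
  }
  grid <- sort(grid)
  npairs <- choose(pw$n, 2)
  p <- pw$p
  U <- matrix(0, length(grid), p)
  # pair-level data computed once; only the horizon changes across the grid
  pairs0 <- pw$pairs
  i <- pairs0$i; j <- pairs0$j
  dtime <- ifelse(cohort$death, cohort$X, Inf)
  di <- dtime[i]; dj <- dtime[j]
  ti <- cohort$tnf[i]; tj <- cohort$tnf[j]
  Xij <- pmin(cohort$X[i], cohort$X[j])
  mu <- drop(stats::plogis(pairs0$Zd %*% pw$beta))
  cross <- if (pw$stratified) cohort$stratum[i] != cohort$stratum[j] else
    rep(FALSE, length(i))
  for (k in seq_along(grid)) {
    if (grid[k] <= 0) next
    u <- pmin(grid[k], Xij)
    d <- win_delta_core(u, di, dj, ti, tj)
    dij <- d$dij; dji <- d$dji
    if (any(cross)) { dij[cross] <- 0L; dji[cross] <- 0L }
    M <- dij - (dij + dji) * mu
    U[k, ] <- crossprod(pairs0$Zd, M) / npairs
  }
  Minf <- pairwise_residual(pw$pairs, pw$beta)
  scale <- sqrt(colSums(pw$pairs$Zd^2 * Minf^2))
  scale[scale == 0] <- 1
  Ustd <- sweep(U, 2, scale, "/") * npairs
  nm <- colnames(cohort$Z)
  out <- data.frame(t = grid)
  out[nm] <- U
  out[paste0(nm, "_std")] <- Ustd
  out
}
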