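# Pairwise win/loss determination under the prioritized composite rule:
# death first, then first nonfatal event, evaluated over the pair's shared
# observation window.

pair_indices <- function(n) {
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  list(i = rep.int(seq_len(n - 1L), (n - 1L):1L),
       j = sequence((n - 1L):1L, from = 2:n))
}

# vectorized core: all inputs are parallel vectors over pairs.
# dtime = death time (Inf if no death observed), tnf = first nonfatal time
# (Inf if none), u = shared-window horizon t ^ X_i ^ X_j.
# The window is closed: an event at exactly u counts (a decedent's follow-up
# ends at the death time, which always sits on the window boundary).
win_delta_core <- function(u, di, dj, ti, tj) {
  no_death <- di > u & dj > u
  dij <- (dj <= u & di > dj) | (no_death & tj <= u & ti > tj)
  dji <- (di <= u & dj > di) | (no_death & ti <= u & tj > ti)
  list(dij = as.integer(dij), dji = as.integer(dji))
}

#' Pairwise win indicators for two subjects
#'
#' Evaluates the prioritized win rule for subjects i and j at horizon
#' `t`: first compare survival over the shared window `[0, t ^ X_i ^ X_j]`
#' (the subject surviving the other's death wins), and if neither dies
#' within the window, compare first nonfatal event times. Exact ties in the
#' deciding event time yield a mutual tie (0, 0).
#'
#' @param cohort a `wl_cohort`.
#' @param i,j subject indices (or ids).
#' @param t evaluation horizon; `Inf` means no time cap, i.e. all observed
#'   events up to the maximum follow-up count.
#' @return named integer vector `c(dij, dji)` with `dij + dji <= 1`.
#' @export
win_delta <- function(cohort, i, j, t = Inf) {
  stopifnot(inherits(cohort, "wl_cohort"), t > 0)
  if (is.character(i)) i <- match(i, cohort$id)
  if (is.character(j)) j <- match(j, cohort$id)
  dtime <- ifelse(cohort$death, cohort$X, Inf)
  u <- pmin(t, cohort$X[i], cohort$X[j])
  r <- win_delta_core(u, dtime[i], dtime[j], cohort$tnf[i], cohort$tnf[j])
  c(dij = r$dij, dji = r$dji)
}

#' Build the full pairwise win/loss table
#'
#' Evaluates all n(n-1)/2 unordered pairs at horizon `t`. When
#' `stratified = TRUE` and the cohort has more than one stratum, pairs from
#' different strata are treated as non-comparable (`R_ij = 0`), which is how
#' the stratified model restricts comparisons to within-stratum pairs.
#'
#' @param cohort a `wl_cohort`.
#' @param t evaluation horizon (default `Inf` = maximum follow-up).
#' @param stratified restrict comparability to within-stratum pairs?
#' @return object of class `pairwise_table`: list with pair index vectors
#'   `i`, `j`, win indicators `dij`, `dji`, comparability `R`, covariate
#'   difference matrix `Zd` (= Z_i - Z_j) and `n`.
#' @export
pairwise_table <- function(cohort, t = Inf, stratified = TRUE) {
  stopifnot(inherits(cohort, "wl_cohort"))
  n <- cohort$n
  px <- pair_indices(n)
  i <- px$i; j <- px$j
  dtime <- ifelse(cohort$death, cohort$X, Inf)
  u <- pmin(t, cohort$X[i], cohort$X[j])
  r <- win_delta_core(u, dtime[i], dtime[j], cohort$tnf[i], cohort$tnf[j])
  dij <- r$dij; dji <- r$dji
  if (stratified && nlevels(cohort$stratum) > 1L) {
    cross <- cohort$stratum[i] != cohort$stratum[j]
    dij[cross] <- 0L
    dji[cross] <- 0L
  }
  structure(list(i = i, j = j, dij = dij, dji = dji, R = dij + dji,
                 Zd = cohort$Z[i, , drop = FALSE] - cohort$Z[j, , drop = FALSE],
                 n = n, t = t),
            class = "pairwise_table")
}

#' Model win probability given comparability
#'
#' Under the proportional win-fractions model the probability that subject
#' i beats subject j, given that the pair is comparable, is
#' `exp(beta'z_i) / {exp(beta'z_i) + exp(beta'z_j)}`, computed
#' overflow-safely as the logistic function of `beta'(z_i - z_j)`.
#'
#' @param z_i,z_j covariate vectors (or matrices with one row per pair).
#' @param beta coefficient vector (log win ratios per unit covariate).
#' @return win probability (or vector thereof) in (0, 1).
#' @export
mu_win <- function(z_i, z_j, beta) {
  z_i <- rbind(z_i); z_j <- rbind(z_j)
  if (ncol(z_i) != length(beta) || ncol(z_j) != length(beta))
    stop("dimension mismatch between covariates and beta", call. = FALSE)
  if (any(!is.finite(z_i)) || any(!is.finite(z_j)) || any(!is.finite(beta)))
    stop("non-finite inputs", call. = FALSE)
  unname(drop(stats::plogis((z_i - z_j) %*% beta)))
}

#' Pairwise win residual
#'
#' `M_ij(t) = delta_ij(t) - R_ij(t) * mu(z_i, z_j; beta)`, the observed
#' minus model-predicted win indicator; always in `[-1, 1]` and exactly
#' antisymmetric (`M_ij = -M_ji`).
#'
#' @param pairs a `pairwise_table` (built at the desired horizon).
#' @param beta coefficient vector.
#' @return numeric vector of residuals, one per unordered pair (i, j) in
#'   the table's order.
#' @export
pairwise_residual <- function(pairs, beta) {
  stopifnot(inherits(pairs, "pairwise_table"))
  mu <- drop(stats::plogis(pairs$Zd %*% beta))
  pairs$dij - pairs$R * mu
}

#' PW estimating function
#'
#' The U-statistic score `sum_{i<j} (Z_i - Z_j) M_ij(Inf; beta)` whose root
#' defines the PW estimator of the log win ratios.
#'
#' @param beta coefficient vector.
#' @param pairs a `pairwise_table` built at `t = Inf`.
#' @return p-vector.
#' @export
pw_score <- function(beta, pairs) {
  unname(drop(crossprod(pairs$Zd, pairwise_residual(pairs, beta))))
}
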