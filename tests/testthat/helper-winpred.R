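# Shared fixtures and a cached replicate study used by several tests.

# long-format builder for hand-constructed cohorts
long_rows <- function(...) {
  specs <- list(...)
  do.call(rbind, lapply(specs, function(s) {
    k <- length(s$time)
    df <- data.frame(id = rep(s$id, k), time = s$time, status = s$status)
    for (nm in setdiff(names(s), c("id", "time", "status")))
      df[[nm]] <- rep(s[[nm]], k)
    df
  }))
}

# the three-subject toy cohort from the win-rule examples, plus one fully
# censored subject:
#   a: death at 2
#   b: nonfatal at 1, censored at 3
#   c: nonfatal at 2.5, censored at 3   (vs d: nonfatal 1, censored 4)
#   d: nonfatal at 1, censored at 4
toy_cohort <- function() {
  wl_cohort(long_rows(
    list(id = "a", time = 2, status = 1, z = 1),
    list(id = "b", time = c(1, 3), status = c(2, 0), z = 0),
    list(id = "c", time = c(2.5, 3), status = c(2, 0), z = 1),
    list(id = "d", time = c(1, 4), status = c(2, 0), z = 0)),
    covariates = "z")
}

# two-sample cohort with binary covariate and inter-group win counts 3:2
# (all deaths; subject pair b1/e0 dies simultaneously -> tie)
two_sample_cohort <- function() {
  wl_cohort(data.frame(
    id = c("a1", "b1", "c0", "d0", "e0"),
    time = c(10, 1, 5, 2, 1),
    status = 1,
    grp = c(1, 1, 0, 0, 0)), covariates = "grp")
}

# brute-force inter-group win counts for a binary covariate (oracle for the
# two-sample reduction of the PW model)
count_wins <- function(cohort, covariate = 1L) {
  pt <- pairwise_table(cohort)
  g <- cohort$Z[, covariate]
  inter <- g[pt$i] != g[pt$j]
  w1 <- sum(pt$dij[inter & g[pt$i] == 1]) + sum(pt$dji[inter & g[pt$j] == 1])
  w0 <- sum(pt$R[inter]) - w1
  c(w1 = w1, w0 = w0)
}

# nonparametric bootstrap of the predicted win probability / net benefit at
# a single time for a fitted cohort
bootstrap_winloss <- function(cohort, z, z_star, t, B, seed) {
  set.seed(seed)
  out <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("w", "nb")))
  for (b in seq_len(B)) {
    chb <- winpred:::resample_cohort(cohort, sample.int(cohort$n, replace = TRUE))
    fit <- tryCatch({
      pwb <- fit_pw(chb)
      coxb <- fit_cox_tfe(chb)
      cv <- predict_winloss(pwb, coxb, z, z_star, times = t)
      c(cv$w, cv$w - cv$l)
    }, error = function(e) c(NA_real_, NA_real_))
    out[b, ] <- fit
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

# Cached 500-replicate study at n = 200 under the default design, evaluated
# at the four standard times for covariate pair z = (1,0,0) vs z* = (0,0,0).
# Computed once per test run and shared across the statistical tests.
.study_cache <- new.env(parent = emptyenv())
replicate_study_cached <- function() {
  if (!is.null(.study_cache$res)) return(.study_cache$res)
  cfg <- sim_config(n = 200)
  set.seed(20260921)
  seeds <- sample.int(.Machine$integer.max - 1L, 500)
  pairs <- list(list(z = c(1, 0, 0), z_star = c(0, 0, 0)))
  res <- winpred:::replicate_study(cfg, seeds, eval_times = c(0.05, 0.1, 1, 4),
                                   pairs = pairs, level = 0.95)
  res <- res[!vapply(res, is.null, logical(1))]
  .study_cache$res <- res
  res
}

study_field <- function(res, field, len = 4L) {
  t(vapply(res, function(r) r$pairs[[1]][[field]], numeric(len)))
}
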