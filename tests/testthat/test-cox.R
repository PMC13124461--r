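test_that("the TFE partial likelihood maximizer matches direct numeric maximization", {
  # 4 subjects, binary covariate, all events at distinct times
  ch <- wl_cohort(data.frame(id = c("a", "b", "c", "d"),
                             time = c(1, 2, 3, 4), status = 1,
                             z = c(1, 0, 1, 0)), covariates = "z")
  fit <- fit_cox_tfe(ch)
  # hand-written log partial likelihood for event order a(z=1), b(0), c(1), d(0)
  logpl <- function(g) {
    r <- exp(g * c(1, 0, 1, 0))
    log(r[1] / sum(r)) + log(r[2] / sum(r[2:4])) + log(r[3] / sum(r[3:4])) +
      log(r[4] / r[4])
  }
  opt <- optimize(logpl, c(-5, 5), maximum = TRUE)
  expect_equal(unname(fit$gamma), opt$maximum, tolerance = 1e-4)
})

test_that("baseline, information and residuals agree with the survival package", {
  ch <- simulate_cohort(sim_config(n = 300), seed = 11)
  fit <- fit_cox_tfe(ch)
  tfe <- derive_tfe(ch)
  cf <- survival::coxph(survival::Surv(time, status) ~ z1 + z2 + z3,
                        data = tfe, ties = "breslow")
  expect_equal(unname(fit$gamma), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(fit$info * ch$n), unname(solve(cf$var)), tolerance = 1e-6,
               ignore_attr = TRUE)
  bh <- survival::basehaz(cf, centered = FALSE)
  expect_equal(winpred:::baseline_cumhaz(fit, bh$time), bh$hazard,
               tolerance = 1e-8)
  expect_equal(martingale_residuals(fit),
               unname(residuals(cf, type = "martingale")), tolerance = 1e-8)
})

test_that("survival prediction is a proper monotone step function", {
  ch <- simulate_cohort(sim_config(n = 150), seed = 4)
  fit <- fit_cox_tfe(ch)
  z <- c(0.5, -1, 1)
  expect_equal(as.numeric(predict_survival(fit, z, 0)), 1)
  tt <- seq(0, 5, by = 0.1)
  s <- as.numeric(predict_survival(fit, z, tt))
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
  ext <- attr(predict_survival(fit, z, c(1, 10)), "extrapolated")
  expect_equal(ext, c(FALSE, TRUE))
  # gamma = 0 / known baseline closed form
  expect_equal(exp(-0.7), 0.4966, tolerance = 1e-4)
})

test_that("influence pieces vanish at t = 0 and the scores sum to zero", {
  ch <- simulate_cohort(sim_config(n = 200), seed = 6)
  fit <- fit_cox_tfe(ch)
  z <- c(1, 0, 0)
  p0 <- cox_influence_pieces(fit, z, 0)
  expect_equal(p0$H, rep(0, 3), ignore_attr = TRUE)
  expect_equal(p0$s0_int, rep(0, 200))
  # score equation: per-subject score integrals sum to ~0 at gamma-hat
  expect_equal(colSums(p0$score_int), rep(0, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(cox_influence_pieces(fit, z, -1), "nonnegative")
})

test_that("score integrals match the survival package's score residuals", {
  ch <- simulate_cohort(sim_config(n = 150), seed = 19)
  fit <- fit_cox_tfe(ch)
  tfe <- derive_tfe(ch)
  cf <- survival::coxph(survival::Surv(time, status) ~ z1 + z2 + z3,
                        data = tfe, ties = "breslow")
  sc <- residuals(cf, type = "score")
  mine <- cox_influence_pieces(fit, c(0, 0, 0), 1)$score_int
  expect_equal(unname(mine), unname(as.matrix(sc)), tolerance = 1e-6)
})

test_that("Schoenfeld residuals sum to zero at every covariate", {
  ch <- simulate_cohort(sim_config(n = 120), seed = 8)
  fit <- fit_cox_tfe(ch)
  sr <- schoenfeld_residuals(fit)
  expect_equal(colSums(sr[, c("z1", "z2", "z3")]), rep(0, 3),
               tolerance = 1e-8, ignore_attr = TRUE)
  # first event: residual is the covariate minus the risk-weighted mean
  ch1 <- wl_cohort(data.frame(id = c("a", "b", "c"), time = c(1, 2, 3),
                              status = c(1, 1, 0), z = c(1, 0, 1)),
                   covariates = "z")
  f1 <- fit_cox_tfe(ch1)
  r <- exp(f1$gamma * c(1, 0, 1))
  expect_equal(schoenfeld_residuals(f1)$z[1],
               1 - sum(c(1, 0, 1) * r) / sum(r), tolerance = 1e-8)
})

test_that("a monotone partial likelihood is reported as non-convergence", {
  ch <- wl_cohort(data.frame(id = c("a", "b", "c"), time = c(1, 2, 3),
                             status = c(1, 0, 0), z = c(1, 0, 1)),
                  covariates = "z")
  expect_error(fit_cox_tfe(ch), "did not converge")
})

test_that("a one-stratum stratified fit equals the unstratified fit", {
  df <- as.data.frame(simulate_cohort(sim_config(n = 100), seed = 23))
  df$site <- "only"
  ch <- wl_cohort(df, covariates = c("z1", "z2", "z3"), stratum = "site")
  f1 <- fit_cox_tfe(ch, stratified = TRUE)
  f2 <- fit_cox_tfe(ch, stratified = FALSE)
  expect_equal(f1$gamma, f2$gamma)
  expect_equal(f1$strata[[1]]$cumL, f2$strata[[1]]$cumL)
})

test_that("stratified baselines match stratum-specific survival fits", {
  df <- as.data.frame(simulate_cohort(sim_config(n = 160), seed = 29))
  df$site <- ave(rep(c("u", "v"), length.out = nrow(df)), df$id,
                 FUN = function(x) x[1])
  ch <- wl_cohort(df, covariates = c("z1", "z2", "z3"), stratum = "site")
  fit <- fit_cox_tfe(ch)
  tfe <- derive_tfe(ch)
  cf <- survival::coxph(
    survival::Surv(time, status) ~ z1 + z2 + z3 + survival::strata(stratum),
    data = tfe, ties = "breslow")
  expect_equal(unname(fit$gamma), unname(coef(cf)), tolerance = 1e-6)
  bh <- survival::basehaz(cf, centered = FALSE)
  for (l in seq_along(fit$strat_levels)) {
    sel <- bh$strata == paste0("survival::strata(stratum)=", fit$strat_levels[l])
    if (!any(sel))
      sel <- grepl(fit$strat_levels[l], as.character(bh$strata))
    expect_equal(winpred:::baseline_cumhaz(fit, bh$time[sel], l),
                 bh$hazard[sel], tolerance = 1e-8)
  }
  expect_error(predict_survival(fit, c(0, 0, 0), 1, stratum = "w"), "unknown stratum")
})

test_that("an event-free cohort cannot support a TFE fit", {
  ch <- wl_cohort(data.frame(id = c("x", "y"), time = 5, status = 0,
                             z = c(1, 0)), covariates = "z")
  expect_error(fit_cox_tfe(ch), "no observed events")
})
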