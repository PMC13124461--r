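fit_both <- function(n = 150, seed = 7) {
  ch <- simulate_cohort(sim_config(n = n), seed = seed)
  list(ch = ch, pw = fit_pw(ch), cox = fit_cox_tfe(ch))
}

test_that("tie probability is the product of two TFE survival curves", {
  f <- fit_both()
  z <- c(1, 0, 0); zs <- c(0, 1, 1)
  expect_equal(tie_probability(f$cox, z, zs, 0), 1)
  tt <- c(0.2, 0.8, 2)
  expect_equal(tie_probability(f$cox, z, zs, tt),
               as.numeric(predict_survival(f$cox, z, tt)) *
                 as.numeric(predict_survival(f$cox, zs, tt)))
  expect_true(all(diff(tie_probability(f$cox, z, zs, seq(0, 4, 0.1))) <= 0))
})

test_that("win, loss and tie probabilities form an exact trinomial with constant ratio", {
  f <- fit_both()
  z <- c(1, 0, 0); zs <- c(0, 0, 0)
  cv <- predict_winloss(f$pw, f$cox, z, zs, times = c(0.05, 0.5, 1, 2, 3.5))
  expect_equal(cv$w + cv$l + cv$tie, rep(1, 5))
  wr <- exp(sum(f$pw$beta * (z - zs)))
  expect_equal(cv$w / cv$l, rep(wr, 5), tolerance = 1e-12)
  expect_true(all(cv$w >= 0 & cv$w <= 1 & cv$l >= 0 & cv$l <= 1))
  expect_true(all(cv$w_lower >= 0 & cv$w_upper <= 1))
  expect_true(all(cv$w_lower <= cv$w & cv$w <= cv$w_upper))
})

test_that("identical profiles split the non-tie probability evenly", {
  f <- fit_both()
  z <- c(0.5, -1, 1)
  cv <- predict_winloss(f$pw, f$cox, z, z, times = c(0.5, 1, 2))
  expect_equal(cv$w, cv$l)
  expect_equal(cv$w, (1 - cv$tie) / 2)
  # influence vectors coincide, so the covariance equals the variance
  expect_equal(cv$cov_wl, cv$se_w^2)
})

test_that("influence contributions are centred, zero at t = 0, and obey Cauchy-Schwarz", {
  f <- fit_both(n = 200, seed = 3)
  z <- c(1, 0, 0); zs <- c(0, 0, 0)
  expect_equal(influence_w(f$pw, f$cox, z, zs, 0), rep(0, 200))
  iw <- influence_w(f$pw, f$cox, z, zs, 1)
  il <- influence_w(f$pw, f$cox, zs, z, 1)
  expect_lt(abs(mean(iw)), 3 * sd(iw) / sqrt(200))
  cov12 <- winloss_covariance(iw, il)
  expect_lte(abs(cov12),
             sqrt(sum(iw^2)) / 200 * sqrt(sum(il^2)) / 200 + 1e-15)
  expect_error(winloss_covariance(iw, il[-1]), "different lengths")
})

test_that("fits from different cohorts or wrong dimensions are rejected", {
  f1 <- fit_both(seed = 1)
  f2 <- fit_both(seed = 2)
  expect_error(predict_winloss(f1$pw, f2$cox, c(1, 0, 0), c(0, 0, 0), times = 1),
               "same cohort")
  expect_error(predict_winloss(f1$pw, f1$cox, c(1, 0), c(0, 0), times = 1),
               "length p")
})

test_that("degenerate probabilities collapse the interval and are flagged", {
  f <- fit_both()
  cv <- predict_winloss(f$pw, f$cox, c(1, 0, 0), c(0, 0, 0), times = 0)
  expect_true(cv$degenerate)
  expect_equal(cv$w_lower, cv$w)
  expect_equal(cv$w_upper, cv$w)
  expect_equal(cv$se_w, 0)
})

test_that("plug-in standard errors track the bootstrap on one dataset", {
  f <- fit_both(n = 120, seed = 25)
  z <- c(1, 0, 0); zs <- c(0, 0, 0)
  cv <- predict_winloss(f$pw, f$cox, z, zs, times = 1)
  boot <- bootstrap_winloss(f$ch, z, zs, t = 1, B = 150, seed = 99)
  expect_gt(nrow(boot), 140)
  expect_lt(abs(cv$se_w / sd(boot[, "w"]) - 1), 0.4)
  se_nb <- contrast_curves(cv)$se_nb
  expect_lt(abs(se_nb / sd(boot[, "nb"]) - 1), 0.4)
})

test_that("contrast curves obey their algebraic identities", {
  f <- fit_both()
  z <- c(1, 0, 0); zs <- c(0, 0, 0)
  cv <- predict_winloss(f$pw, f$cox, z, zs, times = c(0.25, 1, 3))
  cc <- contrast_curves(cv)
  expect_equal(cc$nb, cv$w - cv$l)
  expect_equal(cc$wo, (1 + cc$nb) / (1 - cc$nb))
  # WO interval is the monotone image of the NB interval
  expect_equal(cc$wo_lower, (1 + cc$nb_lower) / (1 - cc$nb_lower))
  expect_equal(cc$wo_upper, (1 + cc$nb_upper) / (1 - cc$nb_upper))
  expect_equal(cc$wo_lower, exp(2 * atanh(cc$nb_lower)))
  expect_true(all(cc$nb_lower >= -1 & cc$nb_upper <= 1))
  expect_true(all(cc$wo_lower >= 0))
  expect_equal(attr(cc, "wr"), exp(sum(f$pw$beta * (z - zs))))
  # sigma_nb^2 = se_w^2 + se_l^2 - 2 cov
  expect_equal(cc$se_nb^2, cv$se_w^2 + cv$se_l^2 - 2 * cv$cov_wl,
               tolerance = 1e-12)
})

test_that("a null contrast has win odds one and a symmetric interval", {
  f <- fit_both()
  z <- c(0.3, -0.7, 1)
  cv <- predict_winloss(f$pw, f$cox, z, z, times = 1)
  cc <- contrast_curves(cv)
  expect_equal(cc$nb, 0)
  expect_equal(cc$wo, 1)
  zc <- qnorm(0.975)
  expect_equal(cc$wo_upper, exp(2 * zc * cc$se_nb))
  expect_equal(cc$wo_lower, exp(-2 * zc * cc$se_nb))
})

test_that("extreme uncertainty keeps transformed intervals inside their ranges", {
  f <- fit_both(n = 60, seed = 41)  # small n: large SEs
  cv <- predict_winloss(f$pw, f$cox, c(3, 0, 0), c(-3, 0, 0),
                        times = c(0.05, 4))
  cc <- contrast_curves(cv)
  expect_true(all(cv$w_lower >= 0 & cv$w_upper <= 1))
  expect_true(all(cc$nb_lower >= -1 & cc$nb_upper <= 1))
  expect_true(all(cc$wo_lower >= 0 & is.finite(cc$wo_upper)))
})

test_that("curves export as readable delimited text", {
  f <- fit_both()
  cv <- predict_winloss(f$pw, f$cox, c(1, 0, 0), c(0, 0, 0), times = c(0.5, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  export_curve(cv, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$w, signif(cv$w, 6))
})

test_that("stratified prediction variance is corroborated by a stratified bootstrap", {
  df <- as.data.frame(simulate_cohort(sim_config(n = 200), seed = 55))
  df$site <- ave(rep(c("u", "v"), length.out = nrow(df)), df$id,
                 FUN = function(x) x[1])
  ch <- wl_cohort(df, covariates = c("z1", "z2", "z3"), stratum = "site")
  pw <- fit_pw(ch); cox <- fit_cox_tfe(ch)
  z <- c(1, 0, 0); zs <- c(0, 0, 0)
  cv <- predict_winloss(pw, cox, z, zs, times = 1, stratum = "u")
  # resample subjects within each stratum
  set.seed(77)
  B <- 150
  wb <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(split(seq_len(ch$n), ch$stratum),
                         function(ix) sample(ix, replace = TRUE)))
    chb <- winpred:::resample_cohort(ch, idx)
    wb[b] <- tryCatch({
      cvb <- predict_winloss(fit_pw(chb), fit_cox_tfe(chb), z, zs,
                             times = 1, stratum = "u")
      cvb$w
    }, error = function(e) NA_real_)
  }
  wb <- wb[!is.na(wb)]
  expect_gt(length(wb), 140)
  expect_lt(abs(cv$se_w / sd(wb) - 1), 0.5)
})
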