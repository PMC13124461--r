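#' Operating characteristics of the win-loss prediction procedure
#'
#' Runs a replicate study under a copula design: for each replicate a
#' cohort is simulated, the PW and Cox TFE models are fitted, the win-loss
#' probabilities and contrasts are predicted for the requested covariate
#' pairs and times, and estimates, standard errors and confidence-interval
#' coverage of the closed-form truth are recorded. Aggregation mirrors the
#' usual simulation-table layout: Bias = mean estimate minus truth,
#' SE = empirical standard deviation of the estimates, SEE = mean of the
#' standard-error estimates, CP = fraction of intervals covering the
#' truth. By construction the net-benefit and win-odds intervals cover
#' jointly, so they share one coverage column.
#'
#' @param cfg a correctly specified `sim_config` (its `n` is the
#'   per-replicate sample size).
#' @param reps number of replicates (>= 100 recommended for stable CP).
#' @param eval_times evaluation times.
#' @param pairs list of covariate pairs, each a `list(z = , z_star = )`.
#' @param level confidence level.
#' @param seed master seed; spawns one independent sub-seed per replicate
#'   so any replicate is reproducible in isolation.
#' @return object of class `oc_study`: list with `w` (data.frame of
#'   pair/time rows with True, Bias, SE, SEE, CP for the win probability),
#'   `contrasts` (same for NB and WO with their shared CP), `beta`
#'   (recovery summary for the PW coefficients), `failures` (count of
#'   failed replicates) and `reps`.
#' @export
operating_characteristics <- function(cfg, reps = 500, eval_times = c(0.1, 0.5, 1, 4),
                                      pairs = list(
                                        list(z = c(1, 0, 0), z_star = c(0, 0, 0)),
                                        list(z = c(0, 0, 0), z_star = c(-1, 0, 0))),
                                      level = 0.95, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$correct)
    stop("operating characteristics require the closed-form truth; ",
         "use a correctly specified design", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  res <- replicate_study(cfg, sub_seeds, eval_times, pairs, level)
  summarize_oc(res, cfg, eval_times, pairs, reps)
}

# run the replicates; returns a list of per-replicate records (NULL on
# fit failure)
replicate_study <- function(cfg, sub_seeds, eval_times, pairs, level) {
  lapply(sub_seeds, function(s) {
    tryCatch({
      ch <- simulate_cohort(cfg, seed = s)
      pw <- fit_pw(ch)
      cox <- fit_cox_tfe(ch)
      per_pair <- lapply(pairs, function(pr) {
        cv <- predict_winloss(pw, cox, pr$z, pr$z_star, times = eval_times,
                              level = level)
        cc <- contrast_curves(cv)
        list(w = cv$w, se_w = cv$se_w,
             w_lower = cv$w_lower, w_upper = cv$w_upper,
             nb = cc$nb, se_nb = cc$se_nb,
             nb_lower = cc$nb_lower, nb_upper = cc$nb_upper,
             wo = cc$wo, wo_lower = cc$wo_lower, wo_upper = cc$wo_upper)
      })
      list(beta = pw$beta, se_beta = sqrt(diag(pw$var)), pairs = per_pair)
    }, error = function(e) NULL)
  })
}

summarize_oc <- function(res, cfg, eval_times, pairs, reps) {
  ok <- !vapply(res, is.null, logical(1))
  failures <- sum(!ok)
  if (failures / reps > 0.01)
    warning(failures, " of ", reps, " replicates failed to fit and were excluded")
  res <- res[ok]
  R <- length(res)

  bmat <- t(vapply(res, `[[`, numeric(cfg$p), "beta"))
  bse <- t(vapply(res, `[[`, numeric(cfg$p), "se_beta"))
  beta_tab <- data.frame(coef = colnames(bmat),
                         true = cfg$beta_death,
                         mean = colMeans(bmat),
                         bias = colMeans(bmat) - cfg$beta_death,
                         se = apply(bmat, 2, stats::sd),
                         see = colMeans(bse))

  w_rows <- list(); c_rows <- list()
  for (ip in seq_along(pairs)) {
    truth <- true_win_prob(cfg, pairs[[ip]]$z, pairs[[ip]]$z_star, eval_times)
    get <- function(field) t(vapply(res, function(r) r$pairs[[ip]][[field]],
                                    numeric(length(eval_times))))
    w <- get("w"); se_w <- get("se_w")
    wlo <- get("w_lower"); whi <- get("w_upper")
    nb <- get("nb"); se_nb <- get("se_nb")
    nlo <- get("nb_lower"); nhi <- get("nb_upper")
    wo <- get("wo")
    w_rows[[ip]] <- data.frame(
      pair = ip, t = eval_times, true = truth$w,
      bias = colMeans(w) - truth$w,
      se = apply(w, 2, stats::sd), see = colMeans(se_w),
      cp = colMeans(sweep(wlo, 2, truth$w, "<=") &
                      sweep(whi, 2, truth$w, ">=")))
    c_rows[[ip]] <- data.frame(
      pair = ip, t = eval_times,
      nb_true = truth$nb, nb_bias = colMeans(nb) - truth$nb,
      nb_se = apply(nb, 2, stats::sd), nb_see = colMeans(se_nb),
      wo_true = truth$wo, wo_bias = colMeans(wo) - truth$wo,
      cp = colMeans(sweep(nlo, 2, truth$nb, "<=") &
                      sweep(nhi, 2, truth$nb, ">=")))
  }
  structure(list(w = do.call(rbind, w_rows),
                 contrasts = do.call(rbind, c_rows),
                 beta = beta_tab, failures = failures, reps = reps,
                 used = R, n = cfg$n),
            class = "oc_study")
}

#' @export
print.oc_study <- function(x, digits = 3, ...) {
  cat(sprintf("Operating characteristics: %d replicates (n = %d per replicate", x$used, x$n))
  if (x$failures > 0) cat(",", x$failures, "failures")
  cat(")\n\nWin probability:\n")
  print(x$w, digits = digits, row.names = FALSE)
  cat("\nNet benefit / win odds:\n")
  print(x$contrasts, digits = digits, row.names = FALSE)
  cat("\nPW coefficients:\n")
  print(x$beta, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write operating-characteristics tables as delimited text
#'
#' Writes the win-probability table to `path` and the net-benefit /
#' win-odds table to `path` with a `.contrasts` suffix, both at 6
#' significant digits.
#'
#' @param x an `oc_study`.
#' @param path output file path.
#' @param sep field separator.
#' @return the path, invisibly.
#' @export
export_oc <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "oc_study"))
  utils::write.table(signif_df(x$w), path, sep = sep, row.names = FALSE, quote = FALSE)
  utils::write.table(signif_df(x$contrasts), paste0(path, ".contrasts"),
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

signif_df <- function(df, digits = 6) {
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, digits) else col)
  df
}
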