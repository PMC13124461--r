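#' Build a composite-outcome cohort from long-format records
#'
#' Converts subject-level long-format event records into a validated
#' analysis-ready cohort for prioritized composite time-to-event outcomes.
#' Each subject contributes zero or more nonfatal-event rows followed by
#' exactly one terminal row (death or censoring). Death is the top-priority
#' component; only the first nonfatal event enters the default win rule,
#' but later nonfatal events are retained.
#'
#' @param data a data.frame in long format with one row per event.
#' @param id,time,status names of the subject identifier, event time and
#'   status columns.
#' @param covariates character vector of covariate column names. If `NULL`,
#'   all remaining numeric columns (other than id/time/status/stratum) are
#'   used, in their order of appearance.
#' @param stratum optional name of a stratum column.
#' @param status_codes named vector giving the coding of the status column;
#'   must have entries `censor`, `death`, `nonfatal`. Default follows the
#'   common convention 0 = censoring, 1 = death, 2 = nonfatal event.
#'
#' @return An object of class `wl_cohort`: a list with components
#'   `id` (character), `X` (follow-up time, i.e. death or censoring time),
#'   `death` (logical), `tnf` (time of first nonfatal event, `Inf` if none),
#'   `nonfatal_times` (list of all nonfatal event times per subject),
#'   `Z` (n x p covariate matrix), `stratum` (factor), `n`, `p`, and
#'   `status_codes`.
#' @examples
#' rows <- data.frame(id = c("B", "B", "A"), time = c(1, 3, 2),
#'                    status = c(2, 0, 1), z = c(0, 0, 1))
#' ch <- wl_cohort(rows, covariates = "z")
#' ch$X      # follow-up times
#' ch$tnf    # first nonfatal event times
#' @export
wl_cohort <- function(data, id = "id", time = "time", status = "status",
                      covariates = NULL, stratum = NULL,
                      status_codes = c(censor = 0, death = 1, nonfatal = 2)) {
  data <- as.data.frame(data)
  for (col in c(id, time, status, covariates, stratum)) {
    if (!col %in% names(data))
      stop("column '", col, "' not found in input data", call. = FALSE)
  }
  if (!all(c("censor", "death", "nonfatal") %in% names(status_codes)))
    stop("'status_codes' must name censor, death and nonfatal codes", call. = FALSE)

  if (is.null(covariates)) {
    cand <- setdiff(names(data), c(id, time, status, stratum))
    covariates <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  if (length(covariates) == 0L)
    stop("no covariate columns identified", call. = FALSE)

  ids_raw <- as.character(data[[id]])
  tm <- as.numeric(data[[time]])
  st <- data[[status]]

  if (anyNA(tm) || any(!is.finite(tm)))
    stop("validation error: event times must be finite and non-missing", call. = FALSE)
  if (any(tm < 0))
    stop("validation error: negative event time", call. = FALSE)
  if (!all(st %in% status_codes))
    stop("validation error: unknown status code(s): ",
         paste(unique(st[!st %in% status_codes]), collapse = ", "), call. = FALSE)

  Zall <- as.matrix(data[covariates])
  storage.mode(Zall) <- "double"
  if (anyNA(Zall) || any(!is.finite(Zall)))
    stop("validation error: covariates must be finite and non-missing", call. = FALSE)

  strat_all <- if (is.null(stratum)) rep("1", nrow(data)) else as.character(data[[stratum]])

  # canonical order: id, then time, terminal rows after nonfatal rows at ties
  terminal <- st %in% status_codes[c("censor", "death")]
  o <- order(ids_raw, tm, terminal)
  ids_raw <- ids_raw[o]; tm <- tm[o]; st <- st[o]
  Zall <- Zall[o, , drop = FALSE]; strat_all <- strat_all[o]
  terminal <- terminal[o]

  uid <- unique(ids_raw)
  n <- length(uid)
  idx <- split(seq_along(ids_raw), factor(ids_raw, levels = uid))

  X <- numeric(n); death <- logical(n); tnf <- rep(Inf, n)
  nonfatal_times <- vector("list", n)
  Z <- matrix(0, n, ncol(Zall), dimnames = list(NULL, colnames(Zall)))
  strat <- character(n)

  for (k in seq_len(n)) {
    rows <- idx[[k]]
    last <- rows[length(rows)]
    if (!terminal[last] || any(terminal[rows[-length(rows)]]))
      stop("validation error: subject '", uid[k],
           if (any(terminal[rows]))
             "' has events recorded after a terminal record" else
             "' has no terminal (death/censoring) record", call. = FALSE)
    zi <- Zall[rows, , drop = FALSE]
    if (nrow(zi) > 1L && any(abs(zi - rep(zi[1L, ], each = nrow(zi))) > 0))
      stop("validation error: covariates not constant within subject '",
           uid[k], "'", call. = FALSE)
    if (length(unique(strat_all[rows])) > 1L)
      stop("validation error: stratum not constant within subject '",
           uid[k], "'", call. = FALSE)
    X[k] <- tm[last]
    if (X[k] <= 0)
      stop("validation error: subject '", uid[k],
           "' has zero follow-up time", call. = FALSE)
    death[k] <- st[last] == status_codes[["death"]]
    nf <- tm[rows[-length(rows)]]
    if (any(nf > X[k]))
      stop("validation error: nonfatal event after follow-up end for subject '",
           uid[k], "'", call. = FALSE)
    nonfatal_times[[k]] <- nf
    if (length(nf)) tnf[k] <- nf[1L]
    Z[k, ] <- zi[1L, ]
    strat[k] <- strat_all[rows[1L]]
  }

  structure(list(id = uid, X = X, death = death, tnf = tnf,
                 nonfatal_times = nonfatal_times, Z = Z,
                 stratum = factor(strat), n = n, p = ncol(Z),
                 status_codes = status_codes),
            class = "wl_cohort")
}

#' @export
print.wl_cohort <- function(x, ...) {
  cat("Composite-outcome cohort: n =", x$n, ", p =", x$p, "covariate(s)\n")
  cat(sprintf("  deaths: %d (%.1f%%), subjects with nonfatal event: %d (%.1f%%)\n",
              sum(x$death), 100 * mean(x$death),
              sum(is.finite(x$tnf)), 100 * mean(is.finite(x$tnf))))
  if (nlevels(x$stratum) > 1L)
    cat("  strata:", nlevels(x$stratum), "\n")
  invisible(x)
}

#' Convert a cohort back to long format
#'
#' Inverse of [wl_cohort()]: emits one row per recorded event in the
#' cohort's own status coding, sorted by (id, time). Re-parsing the result
#' reproduces the cohort exactly.
#'
#' @param x a `wl_cohort` object.
#' @param row.names,optional ignored (S3 signature).
#' @param ... ignored.
#' @return data.frame with columns `id`, `time`, `status`, covariates and
#'   (when more than one stratum is present) `stratum`.
#' @export
as.data.frame.wl_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  codes <- x$status_codes
  nev <- lengths(x$nonfatal_times) + 1L
  rep_i <- rep(seq_len(x$n), nev)
  time <- unlist(Map(function(nf, xi) c(nf, xi), x$nonfatal_times, x$X),
                 use.names = FALSE)
  status <- unlist(Map(function(nf, d) c(rep(codes[["nonfatal"]], length(nf)),
                                         if (d) codes[["death"]] else codes[["censor"]]),
                       x$nonfatal_times, x$death), use.names = FALSE)
  out <- data.frame(id = x$id[rep_i], time = time, status = status)
  out <- cbind(out, as.data.frame(x$Z[rep_i, , drop = FALSE]))
  if (nlevels(x$stratum) > 1L)
    out$stratum <- as.character(x$stratum)[rep_i]
  rownames(out) <- NULL
  out
}

#' Time to first event used for tie-breaking
#'
#' For the default win rule (death prioritized over one nonfatal event),
#' a pair is tied at time t exactly when both subjects are free of *any*
#' component event by t, so the relevant univariate endpoint is the time to
#' the first event (TFE), the minimum of the death and first-nonfatal times.
#'
#' @param cohort a `wl_cohort`.
#' @return data.frame with per-subject columns `id`, `time` (observed TFE,
#'   i.e. first event or censoring time), `status` (1 = event, 0 = censored),
#'   the covariates, and `stratum`.
#' @export
derive_tfe <- function(cohort) {
  stopifnot(inherits(cohort, "wl_cohort"))
  tfe <- pmin(cohort$tnf, cohort$X)
  delta <- as.integer(is.finite(cohort$tnf) | cohort$death)
  out <- data.frame(id = cohort$id, time = tfe, status = delta)
  out <- cbind(out, as.data.frame(cohort$Z))
  out$stratum <- cohort$stratum
  out
}

# fast subject-level resample (nonparametric bootstrap); bypasses the
# long-format round trip
resample_cohort <- function(cohort, idx) {
  out <- cohort
  out$id <- sprintf("b%0*d", nchar(length(idx)), seq_along(idx))
  out$X <- cohort$X[idx]
  out$death <- cohort$death[idx]
  out$tnf <- cohort$tnf[idx]
  out$nonfatal_times <- cohort$nonfatal_times[idx]
  out$Z <- cohort$Z[idx, , drop = FALSE]
  out$stratum <- factor(as.character(cohort$stratum)[idx],
                        levels = levels(cohort$stratum))
  out$n <- length(idx)
  out
}

# lightweight identity check used to guard against mixing fits from
# different datasets
cohort_fingerprint <- function(cohort) {
  c(n = cohort$n, p = cohort$p, zsum = sum(cohort$Z),
    zss = sum(cohort$Z^2), xsum = sum(cohort$X))
}

#' Read / write a cohort as delimited text
#'
#' @param path file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @param ... passed on to [wl_cohort()] (column names, status coding).
#' @return `read_cohort_csv` returns a `wl_cohort`; `write_cohort_csv`
#'   invisibly returns the file path.
#' @export
read_cohort_csv <- function(path, sep = ",", ...) {
  wl_cohort(utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE), ...)
}

#' @rdname read_cohort_csv
#' @param cohort a `wl_cohort`.
#' @export
write_cohort_csv <- function(cohort, path, sep = ",") {
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
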