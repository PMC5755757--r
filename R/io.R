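#' Scan-path CSV schema
#'
#' One row per fixation step. Columns: `subject_id` (string), `block`,
#' `trial` (integers, 1-based), `step` (integer, 0 at the initial central
#' fixation), `location` and `outcome` (closed token vocabularies),
#' `choice` (context token on the categorisation row, empty otherwise),
#' `correct` (0/1 on the categorisation row), `score_delta` (points, on the
#' final row of a trial), `isi_ms` (optional externally supplied
#' inter-saccade interval in milliseconds). UTF-8, comma separated, `.`
#' decimal, header required, upper-case tokens.
#'
#' @name scanpath_schema
NULL

SCANPATH_COLUMNS <- c("subject_id", "block", "trial", "step", "location",
                      "outcome", "choice", "correct", "score_delta", "isi_ms")

#' Convert a list of trial records to the scan-path table
#'
#' @param records list of `trial_record`s from [run_trial()].
#' @param subject_id subject label.
#' @param block block number.
#' @param isi_ms optional function(n) returning n inter-saccade intervals in
#'   ms for a trial with n saccade rows (synthetic timing), or `NULL`.
#' @return data frame in the scan-path schema.
#' @export
records_to_scanpaths <- function(records, subject_id = "S01", block = 1L,
                                 isi_ms = NULL) {
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    n <- nrow(r$path)
    df <- data.frame(subject_id = subject_id, block = as.integer(block),
                     trial = i, step = r$path$step,
                     location = r$path$location, outcome = r$path$outcome,
                     choice = "", correct = NA_integer_,
                     score_delta = NA_real_, isi_ms = NA_real_,
                     stringsAsFactors = FALSE)
    if (!is.na(r$choice)) {
      df$choice[n] <- r$choice
      df$correct[n] <- as.integer(r$feedback == "RIGHT")
    }
    df$score_delta[n] <- r$score_delta
    if (!is.null(isi_ms) && n > 1L) df$isi_ms[2:n] <- isi_ms(n - 1L)
    out[[i]] <- df
  }
  do.call(rbind, out)
}

#' Write a scan-path table to CSV
#'
#' @param df data frame in the scan-path schema.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scanpaths <- function(df, path) {
  utils::write.csv(df[, SCANPATH_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a scan-path CSV
#'
#' Checks the header, token vocabularies, per-trial sort order and that each
#' trial starts at central fixation (step 0, location FIX). Validation
#' failures are errors naming the offending row.
#'
#' @param path CSV file in the scan-path schema.
#' @return validated data frame of class `scanpath_set`.
#' @export
read_scanpaths <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  validate_scanpaths(df)
}

#' Validate an in-memory scan-path table
#'
#' @param df data frame in the scan-path schema.
#' @return `df` with class `scanpath_set`, or an error naming the first
#'   offending row.
#' @export
validate_scanpaths <- function(df) {
  missing_cols <- setdiff(setdiff(SCANPATH_COLUMNS, "isi_ms"), names(df))
  if (length(missing_cols))
    stop("scan-path table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"isi_ms" %in% names(df)) df$isi_ms <- NA_real_
  bad <- which(!df$location %in% LOCATIONS)
  if (length(bad))
    stop("row ", bad[1], ": unknown location token ",
         deparse(df$location[bad[1]]))
  bad <- which(!df$outcome %in% WHAT_OUTCOMES)
  if (length(bad))
    stop("row ", bad[1], ": unknown outcome token ",
         deparse(df$outcome[bad[1]]))
  bad <- which(!(df$choice %in% c("", CONTEXTS) | is.na(df$choice)))
  if (length(bad))
    stop("row ", bad[1], ": unknown choice token ", deparse(df$choice[bad[1]]))
  key <- paste(df$subject_id, df$block, df$trial)
  ord <- order(df$subject_id, df$block, df$trial, df$step)
  if (!identical(ord, seq_len(nrow(df)))) {
    first_bad <- which(ord != seq_len(nrow(df)))[1]
    stop("rows are not sorted by (subject, block, trial, step); first ",
         "offending row: ", first_bad)
  }
  starts <- !duplicated(key)
  bad <- which(starts & (df$step != 0L | df$location != "FIX"))
  if (length(bad))
    stop("row ", bad[1], ": trial does not start at step 0 on FIX")
  class(df) <- c("scanpath_set", class(df))
  df
}

#' Split a scan-path table into per-trial paths grouped by subject and block
#'
#' @param df a validated scan-path table.
#' @return nested list: `[[subject_id]][[block]]` is a list of per-trial
#'   data frames with columns `step`, `location`, `outcome`.
#' @export
split_trials <- function(df) {
  out <- list()
  for (sid in unique(df$subject_id)) {
    dsub <- df[df$subject_id == sid, ]
    out[[sid]] <- list()
    for (b in sort(unique(dsub$block))) {
      dblk <- dsub[dsub$block == b, ]
      out[[sid]][[as.character(b)]] <-
        lapply(split(dblk, factor(dblk$trial, levels = unique(dblk$trial))),
               function(d) d[, c("step", "location", "outcome")])
    }
  }
  out
}

#' Write a Gaussian posterior (subject/block fit) to JSON
#'
#' @param fit a `gaussian_posterior`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_posterior_json <- function(fit, path) {
  obj <- list(mu = as.list(fit$mu),
              Sigma = list(shape = dim(fit$Sigma),
                           values = as.vector(fit$Sigma)),
              log_evidence = fit$log_evidence,
              n_trials = fit$n_trials,
              converged = isTRUE(fit$converged),
              flags = as.list(fit$flags %||% character()))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Gaussian posterior written by [write_posterior_json()]
#'
#' @param path JSON file.
#' @return a `gaussian_posterior`.
#' @export
read_posterior_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Sigma <- matrix(obj$Sigma$values, obj$Sigma$shape[1], obj$Sigma$shape[2])
  mu <- unlist(obj$mu)
  dimnames(Sigma) <- list(names(mu), names(mu))
  structure(list(mu = mu, Sigma = Sigma, log_evidence = obj$log_evidence,
                 n_trials = obj$n_trials, converged = obj$converged,
                 flags = unlist(obj$flags)),
            class = "gaussian_posterior")
}
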