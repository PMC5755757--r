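#' Fit every subject and block of a scan-path table
#'
#' For each subject the heuristic kernel is first estimated from that
#' subject's own saccade transition frequencies (the most frequent successor
#' of each location), then each block is inverted independently with
#' [fit_subject()], giving the per-subject-per-block posteriors that feed
#' the between-block analysis.
#'
#' @param scanpaths validated scan-path table (see [read_scanpaths()]).
#' @param priors a [fit_priors()] object.
#' @param include_epistemic `FALSE` fits the extrinsic-only model
#'   throughout.
#' @param progress print one line per subject.
#' @return list with `fits` (nested list `[[subject]][[block]]` of
#'   `gaussian_posterior`), `table` (flat data frame with posterior means,
#'   SDs and log evidence per subject and block), and `kernels` (estimated
#'   heuristic kernel per subject).
#' @export
fit_cohort <- function(scanpaths, priors = fit_priors(),
                       include_epistemic = TRUE, progress = FALSE) {
  by_subject <- split_trials(validate_scanpaths(as.data.frame(scanpaths)))
  fits <- list(); kernels <- list(); rows <- list()
  for (sid in names(by_subject)) {
    all_trials <- unlist(by_subject[[sid]], recursive = FALSE)
    H <- estimate_heuristic_map(all_trials)
    model <- scene_model(T = 6L, H = H)
    kernels[[sid]] <- H
    fits[[sid]] <- list()
    for (b in names(by_subject[[sid]])) {
      rp <- replay_scanpaths(model, by_subject[[sid]][[b]])
      f <- suppressWarnings(
        fit_subject(model, priors = priors, replay = rp,
                    include_epistemic = include_epistemic))
      fits[[sid]][[b]] <- f
      v <- c(f$mu, sqrt(diag(f$Sigma)))
      names(v) <- c(paste0(PARAM_NAMES, "_mean"), paste0(PARAM_NAMES, "_sd"))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, block = as.integer(b), t(v),
        log_evidence = f$log_evidence, converged = f$converged,
        stringsAsFactors = FALSE)
    }
    if (progress) message("fitted ", sid)
  }
  list(fits = fits, table = do.call(rbind, rows), kernels = kernels)
}

#' Between-block analysis of a fitted cohort
#'
#' Runs parametric empirical Bayes per subject over its block posteriors,
#' searches the 256 combinations of between-block effects by Bayesian model
#' reduction with evidence pooled over subjects, and returns the Bayesian
#' model averages per subject.
#'
#' @param cohort_fits result of [fit_cohort()].
#' @param eta_prior second-level prior, from [peb_prior()].
#' @param between_cov fixed between-block covariance.
#' @return list with `peb_models`, `model_space`, `bma` (per-subject means
#'   and covariances over the 8 effects).
#' @export
cohort_peb <- function(cohort_fits, eta_prior = peb_prior(),
                       between_cov = diag(1 / 16, 4)) {
  pebs <- lapply(cohort_fits$fits, function(blocks)
    peb_fit(blocks[order(as.integer(names(blocks)))],
            X = peb_design(length(blocks)), eta_prior = eta_prior,
            between_cov = between_cov))
  ms <- search_model_space(pebs)
  list(peb_models = pebs, model_space = ms, bma = bma(ms))
}

#' Per-subject epistemic versus extrinsic-only model comparison
#'
#' @param scanpaths validated scan-path table.
#' @param priors a [fit_priors()] object.
#' @return data frame with one row per subject: `delta_f` (nats, positive
#'   favours the epistemic model) and the two log evidences, plus the
#'   pooled (summed) difference as attribute `pooled_delta_f`.
#' @export
compare_cohort <- function(scanpaths, priors = fit_priors()) {
  by_subject <- split_trials(validate_scanpaths(as.data.frame(scanpaths)))
  rows <- lapply(names(by_subject), function(sid) {
    all_trials <- unlist(by_subject[[sid]], recursive = FALSE)
    H <- estimate_heuristic_map(all_trials)
    model <- scene_model(T = 6L, H = H)
    rp <- replay_scanpaths(model, all_trials)
    cmp <- suppressWarnings(
      evidence_epistemic_vs_extrinsic(model, priors = priors, replay = rp))
    data.frame(subject_id = sid, delta_f = cmp$delta_f,
               log_evidence_full = cmp$fit_full$log_evidence,
               log_evidence_extrinsic = cmp$fit_extrinsic$log_evidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pooled_delta_f") <- sum(out$delta_f)
  out
}

#' Canonical correlation phenotyping of a cohort
#'
#' Correlates the per-subject parameter estimates (by default the Bayesian
#' model averages of the four constants plus the two preference decay
#' terms) with the behavioural measures, mirroring the computational
#' phenotyping analysis.
#'
#' @param param_matrix subjects x parameters matrix.
#' @param behaviour subjects x measures data frame or matrix (a
#'   `subject_id` column, if present, is dropped after aligning order).
#' @return a [cva()] result.
#' @export
phenotype_cva <- function(param_matrix, behaviour) {
  if (is.data.frame(behaviour) && "subject_id" %in% names(behaviour))
    behaviour <- behaviour[, setdiff(names(behaviour), "subject_id")]
  cva(as.matrix(param_matrix), as.matrix(behaviour))
}

#' Default parameter matrix for phenotyping
#'
#' The four constant effects plus the two preference decay terms from the
#' Bayesian model averages.
#'
#' @param bma_result `bma` element of [cohort_peb()].
#' @return subjects x 6 matrix.
#' @export
bma_param_matrix <- function(bma_result) {
  bma_result$mean[, c("ln_beta_const", "E_h_const", "ln_C_cor_const",
                      "ln_C_q_const", "ln_C_cor_decay", "ln_C_q_decay"),
                  drop = FALSE]
}
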