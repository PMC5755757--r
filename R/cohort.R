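#' Configuration of a synthetic cohort
#'
#' Defaults emulate the study design: 22 subjects, five blocks of one
#' hundred trials of the 2x2 gaze-contingent scene task. Subject parameters
#' are drawn from a Gaussian population on the log scale (SD 0.5 per
#' coordinate; SD 1 for the heuristic bias, spanning heuristic and
#' epistemic phenotypes). Block-wise drift follows a constant plus an
#' exponential decay with a one-block time constant, planted by default
#' only on the two preference-scaling parameters: a negative decay
#' coefficient makes the preference precisions rise over blocks and plateau.
#' Each subject is assigned a fixed-form exploration order; reading-like and
#' clockwise orders dominate the assignment probabilities.
#'
#' The population couples the heuristic bias with policy-selection
#' imprecision (`rho_eh_beta`, the correlation between `E_h` and `ln_beta`):
#' heuristic reliance alone does not mechanically reduce categorisation
#' accuracy in this agent (extra heuristic saccades disclose extra cues), so
#' the empirically observed heuristic-bias/accuracy phenotype is induced as
#' a population covariance, which the phenotyping stage is designed to
#' detect.
#'
#' @param n_subjects,n_blocks,n_trials design counts.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param theta_mean,theta_sd population mean and SD of
#'   `(ln_beta, E_h, ln_C_cor, ln_C_q)`.
#' @param decay per-parameter decay coefficients; block b adds
#'   `decay * exp(-(b - 1))`.
#' @param rho_eh_beta population correlation between `E_h` and `ln_beta`.
#' @param p_reading,p_clockwise assignment probability of the reading-like
#'   and clockwise orders (the remaining mass is uniform over the other 22).
#' @param mode action selection mode for the simulated agents.
#' @param synthetic_timing add a synthetic-timing `isi_ms` column (subject
#'   level log-normal; purely so a four-column behavioural interface can be
#'   exercised — timing is never modelled).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 22L, n_blocks = 5L, n_trials = 100L,
                          seed = 1L,
                          theta_mean = c(ln_beta = 0, E_h = 0,
                                         ln_C_cor = 0, ln_C_q = 0),
                          theta_sd = c(ln_beta = 0.5, E_h = 1,
                                       ln_C_cor = 0.5, ln_C_q = 0.5),
                          decay = c(ln_beta = 0, E_h = 0,
                                    ln_C_cor = -0.5, ln_C_q = -0.5),
                          rho_eh_beta = 0.7,
                          p_reading = 0.5, p_clockwise = 0.3,
                          mode = "sample", synthetic_timing = TRUE) {
  stopifnot(n_subjects >= 1L, n_blocks >= 1L, n_trials >= 1L,
            all(theta_sd >= 0), abs(rho_eh_beta) <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_blocks = as.integer(n_blocks),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 decay = decay, rho_eh_beta = rho_eh_beta,
                 p_reading = p_reading,
                 p_clockwise = p_clockwise, mode = mode,
                 synthetic_timing = synthetic_timing),
            class = "cohort_config")
}

READING_ORDER <- c("TL", "TR", "BL", "BR")
CLOCKWISE_ORDER <- c("TL", "TR", "BR", "BL")

sample_order <- function(config) {
  orders <- enumerate_fixed_orders()
  labels <- vapply(orders, function(o) paste(o$order, collapse = ","), "")
  probs <- rep((1 - config$p_reading - config$p_clockwise) / 22, 24)
  probs[labels == paste(READING_ORDER, collapse = ",")] <- config$p_reading
  probs[labels == paste(CLOCKWISE_ORDER, collapse = ",")] <- config$p_clockwise
  orders[[sample.int(24L, 1L, prob = probs)]]$order
}

#' Generate a synthetic cohort of scan-paths with known ground truth
#'
#' Draws subject parameters from the population, applies block-wise
#' exponential drift, simulates every trial through the task simulator, and
#' returns the scan-path table together with the ground-truth parameter
#' table and per-block behavioural summaries.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort`: `scanpaths` (scan-path schema
#'   data frame), `truth` (subject x block parameter table, with the
#'   subject-level constants and decay coefficients), `summaries`
#'   (subject x block behavioural summaries), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  sp <- list(); truth <- list(); summ <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%0*d", max(2L, nchar(config$n_subjects)), s)
    theta <- stats::rnorm(4, config$theta_mean, config$theta_sd)
    names(theta) <- PARAM_NAMES
    # couple heuristic bias with policy imprecision (see cohort_config)
    rho <- config$rho_eh_beta
    z_eh <- if (config$theta_sd[["E_h"]] > 0)
      (theta[["E_h"]] - config$theta_mean[["E_h"]]) /
        config$theta_sd[["E_h"]] else 0
    theta[["ln_beta"]] <- config$theta_mean[["ln_beta"]] +
      config$theta_sd[["ln_beta"]] *
        (rho * z_eh + sqrt(1 - rho^2) * stats::rnorm(1))
    order <- sample_order(config)
    model <- scene_model(T = 6L, H = heuristic_map(order))
    isi_meanlog <- if (config$synthetic_timing)
      stats::rnorm(1, log(0.35), 0.2) else NA_real_
    for (b in seq_len(config$n_blocks)) {
      theta_b <- theta + config$decay * exp(-(b - 1))
      params <- subject_params(theta_b[["ln_beta"]], theta_b[["E_h"]],
                               theta_b[["ln_C_cor"]], theta_b[["ln_C_q"]])
      blk <- run_block(model, params, n_trials = config$n_trials,
                       mode = config$mode)
      isi_fun <- if (config$synthetic_timing)
        function(n) 1000 * stats::rlnorm(n, isi_meanlog, 0.2) else NULL
      df <- records_to_scanpaths(blk$records, subject_id = sid, block = b,
                                 isi_ms = isi_fun)
      sp[[length(sp) + 1L]] <- df
      sm <- blk$summary
      sm$mean_isi_ms <- if (config$synthetic_timing)
        mean(df$isi_ms, na.rm = TRUE) else NA_real_
      summ[[length(summ) + 1L]] <- cbind(
        data.frame(subject_id = sid, block = b), sm)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = sid, block = b,
        ln_beta = theta_b[["ln_beta"]], E_h = theta_b[["E_h"]],
        ln_C_cor = theta_b[["ln_C_cor"]], ln_C_q = theta_b[["ln_C_q"]],
        ln_beta_const = theta[["ln_beta"]], E_h_const = theta[["E_h"]],
        ln_C_cor_const = theta[["ln_C_cor"]],
        ln_C_q_const = theta[["ln_C_q"]],
        ln_beta_decay = config$decay[["ln_beta"]],
        E_h_decay = config$decay[["E_h"]],
        ln_C_cor_decay = config$decay[["ln_C_cor"]],
        ln_C_q_decay = config$decay[["ln_C_q"]],
        order = paste(order, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(scanpaths = validate_scanpaths(do.call(rbind, sp)),
                 truth = do.call(rbind, truth),
                 summaries = do.call(rbind, summ),
                 config = config),
            class = "synthetic_cohort")
}

#' Write a cohort to disk (scan-paths, ground truth, config echo)
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scanpaths(cohort$scanpaths, file.path(dir, "scanpaths.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Behavioural measures per subject
#'
#' Aggregates block summaries to the subject level: mean score per trial,
#' percentage correct, mean saccades per trial and (when present) mean time
#' between saccades.
#'
#' @param summaries the `summaries` element of a cohort.
#' @return data frame, one row per subject.
#' @export
behavioural_measures <- function(summaries) {
  agg <- function(v) tapply(v, summaries$subject_id, mean)
  out <- data.frame(subject_id = sort(unique(summaries$subject_id)),
                    mean_score_per_trial = as.vector(agg(summaries$mean_score_per_trial)),
                    pct_correct = as.vector(agg(summaries$pct_correct)),
                    mean_saccades_per_trial = as.vector(agg(summaries$mean_saccades_per_trial)),
                    stringsAsFactors = FALSE)
  if ("mean_isi_ms" %in% names(summaries) &&
      !all(is.na(summaries$mean_isi_ms)))
    out$mean_isi_ms <- as.vector(agg(summaries$mean_isi_ms))
  out
}

#' Truth-versus-estimate recovery table
#'
#' @param truth the `truth` table of a cohort (or any subject x block table
#'   with the four parameter columns).
#' @param fits data frame with columns `subject_id`, `block`, and for each
#'   parameter `<name>_mean` and `<name>_sd` (as produced by the fitting
#'   drivers), or a list of `gaussian_posterior` aligned with `truth` rows.
#' @param level credible level (default 0.9).
#' @return data frame per parameter: coverage of the credible intervals,
#'   bias and RMSE of the posterior means.
#' @export
recovery_report <- function(truth, fits, level = 0.9) {
  if (is.list(fits) && !is.data.frame(fits)) {
    if (length(fits) != nrow(truth))
      stop("fits and truth rows do not match")
    fits <- data.frame(
      subject_id = truth$subject_id, block = truth$block,
      do.call(rbind, lapply(fits, function(f) {
        v <- c(f$mu, sqrt(diag(f$Sigma)))
        names(v) <- c(paste0(PARAM_NAMES, "_mean"),
                      paste0(PARAM_NAMES, "_sd"))
        v
      })))
  }
  key_t <- paste(truth$subject_id, truth$block)
  key_f <- paste(fits$subject_id, fits$block)
  if (!setequal(key_t, key_f)) stop("fits and truth subject/blocks differ")
  fits <- fits[match(key_t, key_f), ]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(PARAM_NAMES, function(p) {
    tr <- truth[[p]]
    m <- fits[[paste0(p, "_mean")]]
    sd <- fits[[paste0(p, "_sd")]]
    data.frame(parameter = p,
               coverage = mean(tr >= m - z * sd & tr <= m + z * sd),
               bias = mean(m - tr),
               rmse = sqrt(mean((m - tr)^2)))
  })
  do.call(rbind, out)
}
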