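#' Priors for subject-level parameter estimation
#'
#' Weakly informative Gaussian prior on
#' `(ln_beta, E_h, ln_C_cor, ln_C_q)`.
#'
#' @param mu0 prior mean (length 4).
#' @param Sigma0 prior covariance (4 x 4, symmetric positive definite).
#' @return object of class `fit_priors`.
#' @export
fit_priors <- function(mu0 = rep(0, 4), Sigma0 = diag(0.25, 4)) {
  stopifnot(length(mu0) == 4L, all(dim(Sigma0) == c(4L, 4L)))
  chol(Sigma0)  # errors if not SPD
  names(mu0) <- PARAM_NAMES
  dimnames(Sigma0) <- list(PARAM_NAMES, PARAM_NAMES)
  structure(list(mu0 = mu0, Sigma0 = Sigma0), class = "fit_priors")
}

#' Precompute the theta-independent part of the scan-path likelihood
#'
#' For a fixed set of scan-paths, the belief trajectory and the per-policy
#' epistemic values do not depend on the subject parameters: theta enters
#' the policy posterior only through the policy prior `E`, the inverse
#' precision `beta`, and the two preference scales. This function replays
#' each trial once, recording per observed saccade the nine epistemic
#' values, the nine base-utility components (what-preference expectation at
#' unit scale, where-preference at unit scale), and the indicator of which
#' policies produce the observed location (the policy targeting it, plus the
#' heuristic policy when its kernel agrees). [action_loglik()] then scores
#' any theta from these matrices; the result is identical to evaluating the
#' policy posterior step by step.
#'
#' @param model a [scene_model()].
#' @param trials list of per-trial data frames with columns `step`,
#'   `location`, `outcome` (tokens), e.g. from [split_trials()].
#' @return object of class `scanpath_replay`.
#' @export
replay_scanpaths <- function(model, trials) {
  rows_epi <- list(); rows_pw <- list(); rows_pl <- list(); rows_m <- list()
  n_steps <- 0L
  base_prefs <- build_preferences(0, 0, model$T)
  for (ti in seq_along(trials)) {
    p <- trials[[ti]]
    loc <- loc_index(p$location)
    out <- what_index(p$outcome)
    if (anyNA(loc) || anyNA(out))
      stop("trial ", ti, ": unknown token in scan-path")
    if (nrow(p) < 2L) next
    hist <- data.frame(location = loc[1], outcome = out[1])
    for (i in 2:nrow(p)) {
      tau <- p$step[i]           # action chosen at time step tau
      if (tau + 1 > model$T)
        stop("trial ", ti, ": step beyond the trial horizon")
      beliefs <- tryCatch(
        update_beliefs(model, hist),
        epiforage_inconsistent_scanpath = function(e)
          stop("trial ", ti, ": ", conditionMessage(e)))
      cur <- loc[i - 1]
      h9 <- model$H[cur]  # heuristic policy target
      q <- joint_from_marginals(beliefs$context, beliefs$vflip, beliefs$hflip)
      epi_loc <- vapply(1:8, function(l) epistemic_value_q(model, q, l), 0)
      pw_loc <- vapply(1:8, function(l)
        sum(as.vector(model$A_joint[[l]] %*% q) *
              base_prefs$C_what[, tau + 1]), 0)
      epi <- c(epi_loc, epi_loc[h9])
      pw <- c(pw_loc, pw_loc[h9])
      pl <- unname(base_prefs$C_where[c(1:8, h9), tau + 1])
      m <- numeric(9L)
      m[loc[i]] <- 1  # policy a targets location a, for a in 1..8
      if (h9 == loc[i]) m[9] <- 1
      n_steps <- n_steps + 1L
      rows_epi[[n_steps]] <- epi; rows_pw[[n_steps]] <- pw
      rows_pl[[n_steps]] <- pl; rows_m[[n_steps]] <- m
      hist <- rbind(hist, data.frame(location = loc[i], outcome = out[i]))
    }
    if (max(history_loglik(model, hist)) < LOG_FLOOR / 2)
      stop("trial ", ti,
           ": observation history is inconsistent with every joint state")
  }
  if (n_steps == 0L) stop("no saccades to score in the scan-paths")
  structure(list(EPI = do.call(rbind, rows_epi),
                 PW = do.call(rbind, rows_pw),
                 PL = do.call(rbind, rows_pl),
                 M = do.call(rbind, rows_m),
                 n_steps = n_steps, n_trials = length(trials)),
            class = "scanpath_replay")
}

#' Log likelihood of observed saccade locations under the model
#'
#' For each observed saccade the policy posterior (softmax of
#' `E - F - G / beta`) is marginalised to the location level: the
#' probability of the observed location is the probability of the policy
#' targeting it plus, when the heuristic kernel agrees, the probability of
#' the heuristic policy. Per-step probabilities are floored at 1e-12.
#'
#' @param model a [scene_model()].
#' @param params a [subject_params()] vector.
#' @param trials list of trial paths (ignored when `replay` is given).
#' @param replay optional precomputed [replay_scanpaths()] object.
#' @param include_epistemic `FALSE` scores the extrinsic-only model.
#' @return total log likelihood in nats.
#' @export
action_loglik <- function(model, params, trials = NULL, replay = NULL,
                          include_epistemic = TRUE) {
  if (is.null(replay)) replay <- replay_scanpaths(model, trials)
  beta <- exp(params[["ln_beta"]])
  kc <- exp(params[["ln_C_cor"]])
  kq <- exp(params[["ln_C_q"]])
  EPI <- if (include_epistemic) replay$EPI else 0
  G <- -EPI - kc * replay$PW - kq * replay$PL
  logits <- -G / beta
  logits[, 9] <- logits[, 9] + params[["E_h"]]
  mx <- apply(logits, 1L, max)
  P <- exp(logits - mx)
  P <- P / rowSums(P)
  pobs <- rowSums(P * replay$M)
  sum(log(pmax(pobs, 1e-12)))
}

# finite-difference Hessian (central differences, default step 1e-3)
fd_hessian <- function(f, x, h = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

#' Fit subject parameters to scan-paths (MAP with Laplace evidence)
#'
#' Maximum a posteriori estimation of `(ln_beta, E_h, ln_C_cor, ln_C_q)` by
#' quasi-Newton ascent on the log joint from the prior mean, with the
#' posterior covariance taken as the inverse of the finite-difference
#' Hessian of the negative log joint at the optimum (symmetrised, jittered
#' to positive definite when needed). The log evidence is the Laplace
#' approximation
#' `loglik + log prior + (d/2) log 2 pi + 0.5 log det Sigma`.
#'
#' @param model a [scene_model()].
#' @param trials list of trial paths, or `NULL` when `replay` is given.
#' @param priors a [fit_priors()] object.
#' @param replay optional precomputed replay (shared between model
#'   variants).
#' @param start optimiser starting point (defaults to the prior mean).
#' @param include_epistemic `FALSE` fits the extrinsic-only reduction.
#' @return object of class `gaussian_posterior`: `mu`, `Sigma`,
#'   `log_evidence`, `log_lik`, `n_trials`, `converged`, `flags`.
#' @export
fit_subject <- function(model, trials = NULL, priors = fit_priors(),
                        replay = NULL, start = NULL,
                        include_epistemic = TRUE) {
  if (is.null(replay)) replay <- replay_scanpaths(model, trials)
  if (replay$n_trials < 10L)
    warning("fewer than 10 trials; parameter estimates will be weak")
  mu0 <- priors$mu0
  if (is.null(start)) start <- mu0
  nlj <- function(th) {
    names(th) <- PARAM_NAMES
    -(action_loglik(model, th, replay = replay,
                    include_epistemic = include_epistemic) +
        dmvnorm_log(th, mu0, priors$Sigma0))
  }
  opt <- stats::optim(start, nlj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  flags <- character()
  if (opt$convergence != 0L) flags <- c(flags, "optim_not_converged")
  Hn <- fd_hessian(nlj, opt$par)
  spd <- make_spd(Hn)
  if (spd$jitter > 0) flags <- c(flags, "hessian_jittered")
  Sigma <- chol2inv(chol(spd$S))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- opt$par
  names(mu) <- PARAM_NAMES
  dimnames(Sigma) <- list(PARAM_NAMES, PARAM_NAMES)
  ll <- action_loglik(model, mu, replay = replay,
                      include_epistemic = include_epistemic)
  log_ev <- ll + dmvnorm_log(mu, mu0, priors$Sigma0) +
    (length(mu) / 2) * log(2 * pi) + 0.5 * logdet_spd(Sigma)
  structure(list(mu = mu, Sigma = Sigma, log_evidence = log_ev,
                 log_lik = ll, n_trials = replay$n_trials,
                 converged = opt$convergence == 0L, flags = flags),
            class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat("<gaussian_posterior> d =", length(x$mu),
      " log evidence =", round(x$log_evidence, 2), "\n")
  print(round(cbind(mean = x$mu, sd = sqrt(diag(x$Sigma))), 3))
  invisible(x)
}

#' Evidence for epistemic over extrinsic-only policy selection
#'
#' Fits the full model (epistemic plus pragmatic value) and the reduced
#' model with the epistemic term removed from expected free energy, both
#' independently on the same scan-paths, and returns the difference in
#' Laplace log evidence (positive favours the epistemic model).
#'
#' @inheritParams fit_subject
#' @return list with `delta_f` (nats), `fit_full`, `fit_extrinsic`.
#' @export
evidence_epistemic_vs_extrinsic <- function(model, trials = NULL,
                                            priors = fit_priors(),
                                            replay = NULL) {
  if (is.null(replay)) replay <- replay_scanpaths(model, trials)
  full <- fit_subject(model, priors = priors, replay = replay,
                      include_epistemic = TRUE)
  extr <- fit_subject(model, priors = priors, replay = replay,
                      include_epistemic = FALSE)
  list(delta_f = full$log_evidence - extr$log_evidence,
       fit_full = full, fit_extrinsic = extr)
}
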