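EFFECT_NAMES <- c("ln_beta_const", "E_h_const", "ln_C_cor_const",
                  "ln_C_q_const",
                  "ln_beta_decay", "E_h_decay", "ln_C_cor_decay",
                  "ln_C_q_decay")

#' Between-block design matrix
#'
#' A constant column and an exponential decay with a time constant of one
#' block: `X[b, ] = (1, exp(-(b - 1)))`.
#'
#' @param n_blocks number of blocks (default 5).
#' @return `n_blocks` x 2 matrix with columns `const`, `decay`.
#' @export
peb_design <- function(n_blocks = 5L) {
  b <- seq_len(n_blocks)
  X <- cbind(const = rep(1, n_blocks), decay = exp(-(b - 1)))
  X
}

#' Gaussian prior over the second-level effects
#'
#' @param mean length-8 prior mean (4 constants then 4 decays).
#' @param cov 8 x 8 prior covariance.
#' @return list with `mean`, `cov`.
#' @export
peb_prior <- function(mean = rep(0, 8), cov = diag(0.25, 8)) {
  names(mean) <- EFFECT_NAMES
  dimnames(cov) <- list(EFFECT_NAMES, EFFECT_NAMES)
  list(mean = mean, cov = cov)
}

#' Parametric empirical Bayes over blocks (one subject)
#'
#' Closed-form Gaussian linear model treating the five block-wise posterior
#' means of the four subject parameters as observations, with noise given
#' by each block's posterior covariance plus a fixed between-block
#' random-effects covariance. The second level models each parameter as a
#' constant plus an exponential decay over blocks, giving 4 x 2 = 8
#' between-block effects.
#'
#' @param block_posteriors list of `gaussian_posterior` (one per block, in
#'   block order, each of dimension 4).
#' @param X design matrix from [peb_design()].
#' @param eta_prior prior over the 8 effects, from [peb_prior()].
#' @param between_cov fixed 4 x 4 between-block covariance
#'   (default `diag(1/16, 4)`).
#' @return object of class `peb_model` with the effect posterior (mean,
#'   covariance, log evidence), the prior, and the design.
#' @export
peb_fit <- function(block_posteriors, X = peb_design(),
                    eta_prior = peb_prior(),
                    between_cov = diag(1 / 16, 4)) {
  n_blocks <- nrow(X)
  if (length(block_posteriors) != n_blocks)
    stop("need exactly ", n_blocks, " block posteriors (balanced design)")
  d <- 4L
  y <- unlist(lapply(block_posteriors, function(p) unname(p$mu)))
  K <- kronecker(X, diag(d))        # row blocks: [x_b1 I, x_b2 I]
  # block-diagonal observation noise
  W <- matrix(0, n_blocks * d, n_blocks * d)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * d + 1):(b * d)
    W[idx, idx] <- block_posteriors[[b]]$Sigma + between_cov
  }
  Winv <- chol2inv(chol(W))
  P0 <- chol2inv(chol(eta_prior$cov))
  P <- t(K) %*% Winv %*% K + P0
  Sigma <- chol2inv(chol(P))
  mu <- as.vector(Sigma %*% (t(K) %*% Winv %*% y + P0 %*% eta_prior$mean))
  names(mu) <- EFFECT_NAMES
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(EFFECT_NAMES, EFFECT_NAMES)
  # marginal likelihood of y under the hierarchical Gaussian model
  Vy <- K %*% eta_prior$cov %*% t(K) + W
  log_ev <- dmvnorm_log(y, as.vector(K %*% eta_prior$mean), Vy)
  eta_posterior <- structure(list(mu = mu, Sigma = Sigma,
                                  log_evidence = log_ev,
                                  n_trials = n_blocks),
                             class = "gaussian_posterior")
  structure(list(X = X, eta_prior = eta_prior,
                 eta_posterior = eta_posterior,
                 effect_names = EFFECT_NAMES),
            class = "peb_model")
}

#' Bayesian model reduction for Gaussian prior/posterior pairs
#'
#' Computes, analytically, the change in log evidence and the posterior
#' that would have been obtained under a reduced prior, from the full
#' model's prior and posterior alone. With precisions `P = Sigma^-1`, `P0`
#' (full prior) and `Pr0` (reduced prior):
#' `Pr = P + Pr0 - P0`, `mur = Pr^-1 (P mu + Pr0 mur0 - P0 mu0)`, and
#' `dF = 0.5 (log det P - log det Pr + log det Pr0 - log det P0)
#'     + 0.5 (mur' Pr mur - mu' P mu - mur0' Pr0 mur0 + mu0' P0 mu0)`.
#'
#' @param posterior,prior,reduced_prior lists with `mean` (or `mu`) and
#'   `cov` (or `Sigma`).
#' @return list with `delta_f` (nats; `-Inf` with `valid = FALSE` when the
#'   reduced posterior precision is not positive definite) and
#'   `reduced_posterior` (list with `mean`, `cov`).
#' @export
bmr <- function(posterior, prior, reduced_prior) {
  g <- function(x) list(mean = as.vector(x$mean %||% x$mu),
                        cov = x$cov %||% x$Sigma)
  po <- g(posterior); pr <- g(prior); rd <- g(reduced_prior)
  if (identical(pr$mean, rd$mean) && identical(pr$cov, rd$cov))
    return(list(delta_f = 0, reduced_posterior = po, valid = TRUE))
  P <- chol2inv(chol(po$cov))
  P0 <- chol2inv(chol(pr$cov))
  Pr0 <- chol2inv(chol(rd$cov))
  Pr <- P + Pr0 - P0
  ok <- tryCatch({ chol(Pr); TRUE }, error = function(e) FALSE)
  if (!ok)
    return(list(delta_f = -Inf, reduced_posterior = NULL, valid = FALSE))
  h <- P %*% po$mean + Pr0 %*% rd$mean - P0 %*% pr$mean
  Sr <- chol2inv(chol(Pr))
  mur <- as.vector(Sr %*% h)
  quad <- function(m, Pm) as.numeric(t(m) %*% Pm %*% m)
  delta_f <- 0.5 * (logdet_spd(P) - logdet_spd(Pr) +
                      logdet_spd(Pr0) - logdet_spd(P0)) +
    0.5 * (quad(mur, Pr) - quad(po$mean, P) -
             quad(rd$mean, Pr0) + quad(pr$mean, P0))
  list(delta_f = delta_f,
       reduced_posterior = list(mean = mur, cov = (Sr + t(Sr)) / 2),
       valid = TRUE)
}

# reduced prior for an on/off pattern: switched-off effects get mean 0 and
# variance 1e-8 (numerical stand-in for a point mass at zero)
reduced_prior_for_pattern <- function(eta_prior, pattern, off_var = 1e-8) {
  mean <- eta_prior$mean
  cov <- eta_prior$cov
  off <- which(!pattern)
  if (length(off)) {
    mean[off] <- 0
    cov[off, ] <- 0
    cov[, off] <- 0
    diag(cov)[off] <- off_var
  }
  list(mean = mean, cov = cov)
}

#' Search the space of between-block effect combinations
#'
#' Applies Bayesian model reduction to every on/off pattern over the 8
#' second-level effects (2^8 = 256 models) for each subject's PEB model,
#' pools (sums) the change in log evidence over subjects, and applies a
#' softmax to obtain posterior model probabilities.
#'
#' @param peb_models list of `peb_model` (one per subject).
#' @param off_var prior variance representing a switched-off effect.
#' @return object of class `model_space`: `patterns` (256 x 8 logical),
#'   `pooled_logev`, `posterior_prob`, `winning` (index and pattern),
#'   `per_subject` (reduced means/covariances, for model averaging).
#' @export
search_model_space <- function(peb_models, off_var = 1e-8) {
  if (inherits(peb_models, "peb_model")) peb_models <- list(peb_models)
  n_eff <- 8L
  n_models <- 2L^n_eff
  patterns <- matrix(FALSE, n_models, n_eff,
                     dimnames = list(NULL, EFFECT_NAMES))
  for (j in seq_len(n_eff))
    patterns[, j] <- bitwAnd(0:(n_models - 1L), bitwShiftL(1L, j - 1L)) > 0L
  n_sub <- length(peb_models)
  logev <- matrix(0, n_models, n_sub)
  per_subject <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    peb <- peb_models[[s]]
    mus <- matrix(NA_real_, n_models, n_eff)
    covs <- array(NA_real_, c(n_eff, n_eff, n_models))
    for (m in seq_len(n_models)) {
      rp <- reduced_prior_for_pattern(peb$eta_prior, patterns[m, ], off_var)
      res <- bmr(peb$eta_posterior, peb$eta_prior, rp)
      logev[m, s] <- res$delta_f
      if (res$valid) {
        mus[m, ] <- res$reduced_posterior$mean
        covs[, , m] <- res$reduced_posterior$cov
      }
    }
    per_subject[[s]] <- list(means = mus, covs = covs)
  }
  pooled <- rowSums(logev)
  prob <- softmax(pooled)
  win <- which.max(pooled)
  structure(list(patterns = patterns, pooled_logev = pooled,
                 posterior_prob = prob,
                 winning = list(index = win, pattern = patterns[win, ]),
                 per_subject_logev = logev, per_subject = per_subject),
            class = "model_space")
}

#' Moment-matched Bayesian model average of Gaussian posteriors
#'
#' @param probs simplex of model probabilities (length m).
#' @param means m x d matrix of model-specific posterior means.
#' @param covs d x d x m array of model-specific posterior covariances.
#' @return list with `mean` (length d) and `cov` (d x d), the moments of
#'   the mixture.
#' @export
bma_moments <- function(probs, means, covs) {
  keep <- probs > 0 & !is.na(means[, 1])
  probs <- probs[keep] / sum(probs[keep])
  means <- means[keep, , drop = FALSE]
  covs <- covs[, , keep, drop = FALSE]
  d <- ncol(means)
  mu <- as.vector(t(means) %*% probs)
  S <- matrix(0, d, d)
  for (m in seq_along(probs))
    S <- S + probs[m] * (covs[, , m] + tcrossprod(means[m, ]))
  S <- S - tcrossprod(mu)
  list(mean = mu, cov = (S + t(S)) / 2)
}

#' Bayesian model averages per subject over the reduced model space
#'
#' @param model_space a [search_model_space()] result.
#' @return list with `mean` (subjects x 8 matrix of BMA means) and `cov`
#'   (list of 8 x 8 BMA covariances per subject).
#' @export
bma <- function(model_space) {
  p <- model_space$posterior_prob
  n_sub <- length(model_space$per_subject)
  means <- matrix(NA_real_, n_sub, 8L, dimnames = list(NULL, EFFECT_NAMES))
  covs <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    ps <- model_space$per_subject[[s]]
    mom <- bma_moments(p, ps$means, ps$covs)
    means[s, ] <- mom$mean
    covs[[s]] <- mom$cov
  }
  list(mean = means, cov = covs)
}
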