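#' Prior beliefs at the start of a trial
#'
#' @param model a [scene_model()].
#' @return object of class `beliefs`: marginal simplices over context, vflip
#'   and hflip, the (observed, hence degenerate) current location, and the
#'   within-trial observation history.
#' @export
beliefs_prior <- function(model) {
  structure(list(context = model$D$context,
                 vflip = model$D$vflip, hflip = model$D$hflip,
                 location = LOC_FIX,
                 history = data.frame(location = integer(), outcome = integer())),
            class = "beliefs")
}

# sum of floored log-likelihoods over the history, per joint latent state
history_loglik <- function(model, history) {
  L <- numeric(12L)
  if (nrow(history)) {
    for (i in seq_len(nrow(history)))
      L <- L + model$logA_joint[[history$location[i]]][history$outcome[i], ]
  }
  L
}

# joint 12-state simplex induced by factor marginals (context fastest)
joint_from_marginals <- function(qc, qv, qh) {
  as.vector(outer(as.vector(outer(qc, qv)), qh))
}

# joint simplex carried by a beliefs object: the exact joint when present,
# otherwise the product of the factor marginals
joint_of <- function(beliefs) {
  beliefs$joint %||%
    joint_from_marginals(beliefs$context, beliefs$vflip, beliefs$hflip)
}

#' Mean-field belief update over the scene factors
#'
#' Iterated coordinate updates of the factorised posterior over context,
#' vertical flip and horizontal flip given the full within-trial history of
#' (location, what-outcome) pairs; the location factor is observed and stays
#' degenerate. Likelihood entries are floored at `exp(-16)` before logs.
#' Updates sweep context, vflip, hflip in turn until the largest absolute
#' change in any marginal falls below `tol`, or 16 sweeps.
#'
#' @param model a [scene_model()].
#' @param history data frame with integer columns `location` and `outcome`
#'   (indices into [LOCATIONS] and [WHAT_OUTCOMES]), or a `beliefs` object
#'   whose history is reused.
#' @param tol convergence tolerance on the marginals.
#' @param max_sweeps maximum number of coordinate sweeps.
#' @param strict error (condition class `epiforage_inconsistent_scanpath`)
#'   when no joint state is fully consistent with the history.
#' @return a `beliefs` object.
#' @export
update_beliefs <- function(model, history, tol = 1e-6, max_sweeps = 16L,
                           strict = TRUE) {
  if (inherits(history, "beliefs")) history <- history$history
  stopifnot(is.data.frame(history))
  L <- history_loglik(model, history)
  if (strict && nrow(history) && max(L) < LOG_FLOOR / 2) {
    cond <- structure(
      class = c("epiforage_inconsistent_scanpath", "error", "condition"),
      list(message = "observation history is inconsistent with every joint state",
           call = sys.call(-1)))
    stop(cond)
  }
  # matricised views of the 12-state log likelihood for each factor update
  Lc <- matrix(L, 3L, 4L)                          # rows: context; cols: (v,h)
  Lv <- matrix(aperm(array(L, c(3L, 2L, 2L)), c(2L, 1L, 3L)), 2L, 6L)
  Lh <- matrix(L, 6L, 2L)                          # rows: (c,v); cols: h
  qc <- model$D$context
  qv <- model$D$vflip
  qh <- model$D$hflip
  log_pc <- log(model$D$context)
  log_pv <- log(model$D$vflip)
  log_ph <- log(model$D$hflip)
  for (sweep in seq_len(max_sweeps)) {
    old <- c(qc, qv, qh)
    qc <- softmax(log_pc + as.vector(Lc %*% as.vector(outer(qv, qh))))
    qv <- softmax(log_pv + as.vector(Lv %*% as.vector(outer(qc, qh))))
    qh <- softmax(log_ph + as.vector(t(Lh) %*% as.vector(outer(qc, qv))))
    if (max(abs(c(qc, qv, qh) - old)) < tol) break
  }
  loc <- if (nrow(history)) history$location[nrow(history)] else LOC_FIX
  structure(list(context = qc, vflip = qv, hflip = qh,
                 location = as.integer(loc), history = history),
            class = "beliefs")
}

#' Exact posterior over the scene factors by joint enumeration
#'
#' Enumerates the 12 joint latent states and normalises the (floored)
#' likelihood of the history times the prior. Serves as a reference against
#' the mean-field approximation of [update_beliefs()].
#'
#' @inheritParams update_beliefs
#' @return list with marginal vectors `context`, `vflip`, `hflip` and the
#'   joint simplex `joint`.
#' @export
exact_beliefs <- function(model, history) {
  if (inherits(history, "beliefs")) history <- history$history
  L <- history_loglik(model, history)
  prior <- joint_from_marginals(model$D$context, model$D$vflip, model$D$hflip)
  w <- exp(L - max(L)) * prior
  w <- w / sum(w)
  arr <- array(w, dim = c(3L, 2L, 2L))
  list(context = stats::setNames(apply(arr, 1L, sum), CONTEXTS),
       vflip = apply(arr, 2L, sum),
       hflip = apply(arr, 3L, sum), joint = w)
}

#' Epistemic value of a policy
#'
#' Expected Bayesian surprise of the saccade: the expected KL divergence
#' between the posterior and prior over the 12-state joint of scene factors,
#' averaged over the predictive distribution of what-outcomes at the
#' policy's target location. The where-outcome is deterministic and
#' contributes nothing.
#'
#' @param model a [scene_model()].
#' @param beliefs current `beliefs`.
#' @param action policy index 1..9 (9 resolves its target through the
#'   heuristic kernel).
#' @return non-negative scalar, in nats.
#' @export
epistemic_value <- function(model, beliefs, action) {
  target <- action_target(action, beliefs$location, model$H)
  epistemic_value_q(model, joint_of(beliefs), target)
}

# epistemic value at a target location for a given joint simplex
epistemic_value_q <- function(model, q, target) {
  A <- model$A_joint[[target]]
  po <- as.vector(A %*% q)
  val <- 0
  for (o in which(po > 1e-12)) {
    post <- A[o, ] * q / po[o]
    nz <- post > 0
    val <- val + po[o] * sum(post[nz] * (log(post[nz]) - log(q[nz])))
  }
  max(val, 0)
}

#' Pragmatic (extrinsic) value of a policy
#'
#' Expected utility of the next outcome: the predictive what-outcome
#' distribution at the target location weighted by the what-preferences at
#' time step `tau + 1`, plus the where-preference of the target location.
#'
#' @inheritParams epistemic_value
#' @param prefs a [build_preferences()] object.
#' @param tau current time step (the outcome lands at `tau + 1`).
#' @return scalar, in nats.
#' @export
pragmatic_value <- function(model, prefs, beliefs, action, tau) {
  if (tau + 1 > prefs$T) stop("tau + 1 exceeds the trial horizon T")
  target <- action_target(action, beliefs$location, model$H)
  q <- joint_from_marginals(beliefs$context, beliefs$vflip, beliefs$hflip)
  po <- as.vector(model$A_joint[[target]] %*% q)
  unname(sum(po * prefs$C_what[, tau + 1]) + prefs$C_where[target, tau + 1])
}

#' Posterior over policies
#'
#' The softmax of `E - F - G / beta` (computed with max-subtraction):
#' prior log policy weights minus the free energy of past observations minus
#' expected free energy scaled by the inverse precision `beta`. Smaller
#' `beta` makes policy selection more deterministic.
#'
#' @param E length-9 log prior policy weights.
#' @param F length-9 past free energy (common to all one-step policies here,
#'   so it cancels; retained for fidelity of the interface).
#' @param G length-9 expected free energy.
#' @param beta positive inverse-precision hyperparameter.
#' @return simplex over the 9 policies.
#' @export
policy_posterior <- function(E, F = rep(0, 9), G, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a positive scalar")
  softmax(E - F - G / beta)
}

#' Evaluate all nine policies at the current time step
#'
#' Computes epistemic and pragmatic value per policy, the expected free
#' energy `G = -epistemic - pragmatic`, and the policy posterior.
#'
#' @inheritParams pragmatic_value
#' @param pol_prior a [build_policy_prior()] object.
#' @param beta positive inverse precision.
#' @param include_epistemic set `FALSE` for the extrinsic-only (expected
#'   utility) reduction of the model.
#' @return object of class `policy_evaluation` with fields `E`, `F`, `G`,
#'   `epistemic`, `pragmatic`, `pi`, `beta`.
#' @export
evaluate_policies <- function(model, prefs, pol_prior, beliefs, tau, beta,
                              include_epistemic = TRUE) {
  if (tau + 1 > prefs$T) stop("tau + 1 exceeds the trial horizon T")
  q <- joint_of(beliefs)
  h9 <- model$H[beliefs$location]  # heuristic policy's target
  epi_loc <- vapply(1:8, function(l) epistemic_value_q(model, q, l), 0)
  prag_loc <- vapply(1:8, function(l) {
    po <- as.vector(model$A_joint[[l]] %*% q)
    sum(po * prefs$C_what[, tau + 1]) + prefs$C_where[l, tau + 1]
  }, 0)
  epi <- c(epi_loc, epi_loc[h9])
  if (!include_epistemic) epi <- rep(0, 9)
  prag <- c(prag_loc, prag_loc[h9])
  G <- -epi - prag
  F <- rep(0, 9)
  structure(list(E = pol_prior$E, F = F, G = G,
                 epistemic = epi, pragmatic = prag,
                 pi = policy_posterior(pol_prior$E, F, G, beta), beta = beta),
            class = "policy_evaluation")
}

#' Select an action from a policy posterior
#'
#' @param pi simplex over the 9 policies.
#' @param mode `"sample"` draws from `pi` using the current RNG state;
#'   `"argmax"` takes the mode, breaking ties toward the lowest index.
#' @return policy index 1..9.
#' @export
select_action <- function(pi, mode = c("sample", "argmax")) {
  mode <- match.arg(mode)
  if (mode == "sample") sample.int(9L, 1L, prob = pi) else which.max(pi)
}
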