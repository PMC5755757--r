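#' Subject parameter set
#'
#' The four free prior-belief parameters of a subject, all on a log or
#' linear scale as named: `ln_beta` (log inverse precision of policy
#' selection), `E_h` (log heuristic bias), `ln_C_cor` and `ln_C_q` (log
#' scaling coefficients on the what- and where-modality preferences).
#'
#' @param ln_beta,E_h,ln_C_cor,ln_C_q finite reals.
#' @return named numeric vector of class `subject_params`.
#' @export
subject_params <- function(ln_beta = 0, E_h = 0, ln_C_cor = 0, ln_C_q = 0) {
  p <- c(ln_beta = ln_beta, E_h = E_h, ln_C_cor = ln_C_cor, ln_C_q = ln_C_q)
  if (any(!is.finite(p))) stop("subject parameters must be finite")
  structure(p, class = c("subject_params", "numeric"))
}

PARAM_NAMES <- c("ln_beta", "E_h", "ln_C_cor", "ln_C_q")

#' Draw a random scene configuration
#'
#' Uniform over the 12 context-by-flip configurations, using the current
#' RNG state.
#'
#' @return list with `context` token, `vflip`, `hflip`.
#' @export
sample_scene <- function() {
  k <- sample.int(12L, 1L)
  ci <- (k - 1L) %% 3L + 1L
  v <- ((k - 1L) %/% 3L) %% 2L == 1L
  h <- (k - 1L) %/% 6L == 1L
  list(context = CONTEXTS[ci], vflip = v, hflip = h)
}

# outcome emitted by the environment at a location, given the true scene
emit_outcome <- function(scene, layout, loc) {
  if (loc == LOC_FIX) return(what_index("NULL"))
  if (loc %in% LOC_QUAD) return(what_index(layout[[LOCATIONS[loc]]]))
  correct <- CHOICE_CONTEXT[[LOCATIONS[loc]]] == scene$context
  what_index(if (correct) "RIGHT" else "WRONG")
}

#' Cumulative exploration cost of attending n distinct squares
#'
#' The penalty of attending the n-th square is `-0.25 * n` and the costs
#' stack, so two squares cost `-0.25 + (-0.5) = -0.75`.
#'
#' @param n_quadrants number of distinct quadrants attended.
#' @return total sampling cost in points (non-positive).
#' @export
exploration_cost <- function(n_quadrants) {
  -0.25 * n_quadrants * (n_quadrants + 1) / 2
}

#' Score a completed trial
#'
#' +2 points for a correct categorisation, -4 for an incorrect one, -4 for
#' reaching the horizon without choosing (time-out), plus the cumulative
#' exploration cost over distinct quadrants attended (revisits do not stack
#' the cost twice).
#'
#' @param record a `trial_record`.
#' @return trial score in points.
#' @export
score_trial <- function(record) {
  choice_pts <- if (is.na(record$feedback)) {
    -4
  } else if (record$feedback == "RIGHT") 2 else -4
  choice_pts + exploration_cost(record$n_quadrants)
}

#' Simulate one gaze-contingent trial
#'
#' Runs the agent-environment loop: belief update on the history, policy
#' evaluation by expected free energy, action selection, and emission of the
#' cue (or feedback) at the new location. Terminates when the agent saccades
#' to a choice location (the categorisation response) or at the horizon.
#'
#' @param model a [scene_model()].
#' @param params a [subject_params()] set.
#' @param scene scene configuration as from [sample_scene()].
#' @param mode `"sample"` or `"argmax"` action selection.
#' @param include_epistemic `FALSE` simulates the extrinsic-only agent.
#' @param beliefs `"meanfield"` (the model's variational scheme) or
#'   `"exact"` (12-state enumeration; useful for isolating artefacts of the
#'   factorised approximation, such as spurious epistemic value on
#'   revisits).
#' @param forced_path optional integer vector of location indices; the agent
#'   is forced along these saccades (used to replay worked examples).
#' @return object of class `trial_record`: `scene`, `path` (data frame with
#'   `step`, `location`, `outcome` tokens), `choice`, `feedback`,
#'   `n_quadrants`, `n_saccades`, `score_delta`, and the final `beliefs`.
#' @export
run_trial <- function(model, params, scene = sample_scene(),
                      mode = c("sample", "argmax"), include_epistemic = TRUE,
                      forced_path = NULL,
                      beliefs = c("meanfield", "exact")) {
  mode <- match.arg(mode)
  beliefs_mode <- match.arg(beliefs)
  belief_fn <- function(hist) {
    b <- update_beliefs(model, hist)
    if (beliefs_mode == "exact") {
      e <- exact_beliefs(model, hist)
      b$context <- e$context; b$vflip <- e$vflip; b$hflip <- e$hflip
      b$joint <- e$joint
    }
    b
  }
  layout <- build_scene_layout(scene$context, scene$vflip, scene$hflip)
  prefs <- build_preferences(params[["ln_C_cor"]], params[["ln_C_q"]], model$T)
  pol_prior <- build_policy_prior(params[["E_h"]], model$H)
  beta <- exp(params[["ln_beta"]])

  hist <- data.frame(location = LOC_FIX, outcome = what_index("NULL"))
  steps <- data.frame(step = 0L, location = LOC_FIX,
                      outcome = what_index("NULL"))
  current <- LOC_FIX
  choice <- NA_character_
  feedback <- NA_character_
  beliefs <- belief_fn(hist)

  for (tau in seq_len(model$T - 1L)) {
    if (!is.null(forced_path)) {
      if (tau > length(forced_path)) break
      newloc <- as.integer(forced_path[tau])
    } else {
      ev <- evaluate_policies(model, prefs, pol_prior, beliefs, tau, beta,
                              include_epistemic = include_epistemic)
      a <- select_action(ev$pi, mode)
      newloc <- action_target(a, current, model$H)
    }
    outcome <- emit_outcome(scene, layout, newloc)
    steps <- rbind(steps, data.frame(step = tau, location = newloc,
                                     outcome = outcome))
    hist <- rbind(hist, data.frame(location = newloc, outcome = outcome))
    beliefs <- belief_fn(hist)
    current <- newloc
    if (newloc %in% LOC_CHOICE) {
      choice <- CHOICE_CONTEXT[[LOCATIONS[newloc]]]
      feedback <- WHAT_OUTCOMES[outcome]
      break
    }
  }

  path <- data.frame(step = steps$step,
                     location = LOCATIONS[steps$location],
                     outcome = WHAT_OUTCOMES[steps$outcome],
                     stringsAsFactors = FALSE)
  quad <- steps$location[steps$location %in% LOC_QUAD]
  rec <- structure(list(scene = scene, path = path,
                        choice = choice, feedback = feedback,
                        n_quadrants = length(unique(quad)),
                        n_saccades = sum(steps$step > 0L &
                                           !steps$location %in% LOC_CHOICE),
                        score_delta = NA_real_, beliefs = beliefs),
                   class = "trial_record")
  rec$score_delta <- score_trial(rec)
  rec
}

#' Simulate a block of trials
#'
#' @param model a [scene_model()].
#' @param params a [subject_params()] set.
#' @param n_trials number of trials (default 100).
#' @param start_points points at the start of the block (default 100).
#' @param mode,include_epistemic,beliefs passed to [run_trial()].
#' @return list with `records` (list of `trial_record`) and `summary`
#'   (one-row data frame: mean score per trial, percentage of correct
#'   categorisations, mean saccades per trial, trial count, final points).
#' @export
run_block <- function(model, params, n_trials = 100L, start_points = 100,
                      mode = "sample", include_epistemic = TRUE,
                      beliefs = "meanfield") {
  if (n_trials < 1L) stop("n_trials must be at least 1")
  records <- vector("list", n_trials)
  for (i in seq_len(n_trials))
    records[[i]] <- run_trial(model, params, sample_scene(), mode = mode,
                              include_epistemic = include_epistemic,
                              beliefs = beliefs)
  scores <- vapply(records, function(r) r$score_delta, 0)
  correct <- vapply(records, function(r)
    !is.na(r$feedback) && r$feedback == "RIGHT", TRUE)
  sacc <- vapply(records, function(r) r$n_saccades, 0L)
  summary <- data.frame(mean_score_per_trial = mean(scores),
                        pct_correct = 100 * mean(correct),
                        mean_saccades_per_trial = mean(sacc),
                        n_trials = n_trials,
                        final_points = start_points + sum(scores))
  list(records = records, summary = summary)
}
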