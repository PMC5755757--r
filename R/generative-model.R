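#' Token vocabularies for the scene-construction task
#'
#' The task is a 2x2 gaze-contingent grid. An agent starts at a central
#' fixation, may saccade to any of four quadrants to disclose the object
#' there, and categorises the scene by saccading to one of three choice
#' locations. The scene category (FLEE / FEED / WAIT) is defined by the
#' relative position of a bird and a second object (cat or seed), subject to
#' vertical and horizontal flips.
#'
#' @format Character vectors of location, outcome and context tokens.
#' @name tokens
NULL

#' @rdname tokens
#' @export
LOCATIONS <- c("FIX", "TL", "TR", "BL", "BR", "CH_FLEE", "CH_FEED", "CH_WAIT")

#' @rdname tokens
#' @export
QUADRANTS <- c("TL", "TR", "BL", "BR")

#' @rdname tokens
#' @export
WHAT_OUTCOMES <- c("NULL", "BIRD", "SEED", "CAT", "RIGHT", "WRONG")

#' @rdname tokens
#' @export
CONTEXTS <- c("FLEE", "FEED", "WAIT")

# location index helpers (1-based in the order of LOCATIONS)
LOC_FIX <- 1L
LOC_QUAD <- 2:5
LOC_CHOICE <- 6:8

# choice location -> context it asserts
CHOICE_CONTEXT <- c(CH_FLEE = "FLEE", CH_FEED = "FEED", CH_WAIT = "WAIT")

loc_index <- function(token) match(token, LOCATIONS)
what_index <- function(token) match(token, WHAT_OUTCOMES)
context_index <- function(token) match(token, CONTEXTS)

#' Construct the object layout of one scene
#'
#' Base layouts place the bird at the top left. In FLEE scenes the cat is
#' row-adjacent (top right); in FEED scenes the seed is row-adjacent (top
#' right); in WAIT scenes the seed is on the same diagonal (bottom right).
#' A vertical flip swaps the rows, a horizontal flip swaps the columns.
#'
#' @param context one of `"FLEE"`, `"FEED"`, `"WAIT"`.
#' @param vflip,hflip logical flags for the two spatial transformations.
#' @return named character vector over `TL`, `TR`, `BL`, `BR` with the
#'   object token at each quadrant (`"NULL"` for empty quadrants).
#' @export
build_scene_layout <- function(context, vflip = FALSE, hflip = FALSE) {
  if (!is.character(context) || length(context) != 1L || !context %in% CONTEXTS)
    stop("unknown context token: ", deparse(context))
  lay <- c(TL = "NULL", TR = "NULL", BL = "NULL", BR = "NULL")
  lay["TL"] <- "BIRD"
  lay[switch(context, FLEE = "TR", FEED = "TR", WAIT = "BR")] <-
    switch(context, FLEE = "CAT", FEED = "SEED", WAIT = "SEED")
  relabel <- function(x) { names(x) <- c("TL", "TR", "BL", "BR"); x }
  if (isTRUE(vflip)) lay <- relabel(lay[c("BL", "BR", "TL", "TR")])
  if (isTRUE(hflip)) lay <- relabel(lay[c("TR", "TL", "BR", "BL")])
  lay
}

# all 12 (context x vflip x hflip) layouts, context varying fastest
all_layouts <- function() {
  out <- list()
  for (h in c(FALSE, TRUE)) for (v in c(FALSE, TRUE)) for (ct in CONTEXTS) {
    out[[length(out) + 1L]] <- list(context = ct, vflip = v, hflip = h,
                                    layout = build_scene_layout(ct, v, h))
  }
  out
}

#' Build the observation likelihood arrays
#'
#' The what-modality likelihood is deterministic: central fixation yields the
#' null outcome, a quadrant yields the object of the current layout, and a
#' choice location yields RIGHT if its category matches the scene context and
#' WRONG otherwise. The where-modality likelihood is the identity on the
#' eight locations.
#'
#' @return list with `A_what` (6 x 3 x 8 x 2 x 2 array: outcome x context x
#'   location x vflip x hflip) and `A_where` (8 x 8 identity matrix).
#' @export
build_likelihood <- function() {
  A_what <- array(0, dim = c(6L, 3L, 8L, 2L, 2L),
                  dimnames = list(WHAT_OUTCOMES, CONTEXTS, LOCATIONS,
                                  c("v0", "v1"), c("h0", "h1")))
  for (v in 1:2) for (h in 1:2) for (ci in 1:3) {
    lay <- build_scene_layout(CONTEXTS[ci], v == 2L, h == 2L)
    for (li in 1:8) {
      o <- if (li == LOC_FIX) {
        "NULL"
      } else if (li %in% LOC_QUAD) {
        lay[[LOCATIONS[li]]]
      } else {
        if (CHOICE_CONTEXT[[LOCATIONS[li]]] == CONTEXTS[ci]) "RIGHT" else "WRONG"
      }
      A_what[what_index(o), ci, li, v, h] <- 1
    }
  }
  A_where <- diag(8)
  dimnames(A_where) <- list(LOCATIONS, LOCATIONS)
  list(A_what = A_what, A_where = A_where)
}

#' Deterministic heuristic kernel from a quadrant exploration order
#'
#' A fixed-form (state-action) policy visits the four quadrants in a set
#' order, regardless of beliefs. The kernel maps fixation to the first
#' quadrant, each quadrant to the next, the last quadrant to itself, and
#' each choice location to itself; it never targets a choice location, so a
#' pure heuristic cannot emit a categorisation response.
#'
#' @param order character vector: a permutation of the four quadrant tokens.
#' @return integer vector of length 8, named by location: next location
#'   index for each current location.
#' @export
heuristic_map <- function(order = c("TL", "TR", "BL", "BR")) {
  if (length(order) != 4L || anyDuplicated(order) ||
      !all(order %in% QUADRANTS))
    stop("order must be a permutation of ", paste(QUADRANTS, collapse = ", "))
  H <- seq_len(8L)  # self-map default (covers choice locations)
  H[LOC_FIX] <- loc_index(order[1L])
  for (i in 1:3) H[loc_index(order[i])] <- loc_index(order[i + 1L])
  H[loc_index(order[4L])] <- loc_index(order[4L])
  names(H) <- LOCATIONS
  H
}

check_heuristic_kernel <- function(H) {
  if (length(H) != 8L || anyNA(H) || !all(H %in% 1:8))
    stop("heuristic kernel H must map each of the 8 locations to a location")
  # a heuristic cannot emit a categorisation response: no exploration
  # location may map to a choice location (choice locations themselves are
  # absorbing self-maps)
  if (any(H[c(LOC_FIX, LOC_QUAD)] %in% LOC_CHOICE))
    stop("heuristic kernel H must not target a choice location")
  if (!all(H[LOC_CHOICE] == LOC_CHOICE))
    stop("choice locations must be absorbing under H")
  invisible(H)
}

#' Build the action-dependent transition tables
#'
#' Actions 1--8 are saccades that move to the corresponding location with
#' probability one regardless of the current location; action 9 follows the
#' deterministic heuristic kernel `H`. Context and flip factors do not change
#' within a trial, so their transition tables are exact identities.
#'
#' @param H heuristic kernel as returned by [heuristic_map()].
#' @return list with `B_location` (8 x 8 x 9, next x current x action),
#'   `B_context`, `B_vflip`, `B_hflip`.
#' @export
build_transitions <- function(H = heuristic_map()) {
  check_heuristic_kernel(H)
  B <- array(0, dim = c(8L, 8L, 9L),
             dimnames = list(LOCATIONS, LOCATIONS, NULL))
  for (a in 1:8) B[a, , a] <- 1
  for (j in 1:8) B[H[j], j, 9L] <- 1
  list(B_location = B,
       B_context = diag(3), B_vflip = diag(2), B_hflip = diag(2))
}

#' Build the log prior preferences over outcomes
#'
#' Utilities are expressed in nats and mirror the task's scoring rules:
#' a correct categorisation is worth +2 points and an incorrect one -4, and
#' remaining undecided at a non-choice location at time step tau costs
#' -0.25 * (tau - 1). Two scaling coefficients tune the precision of the
#' preferences in the what and where modalities multiplicatively:
#' `k_cor = exp(ln_C_cor)` and `k_q = exp(ln_C_q)`. First-step utilities are
#' zero (the trial starts at fixation).
#'
#' @param ln_C_cor,ln_C_q log scaling coefficients.
#' @param T trial horizon in time steps (at least 2).
#' @return object of class `scene_preferences` with matrices `C_what`
#'   (6 x T) and `C_where` (8 x T) plus the scales `k_cor`, `k_q`.
#' @export
build_preferences <- function(ln_C_cor = 0, ln_C_q = 0, T = 6L) {
  if (!is.numeric(T) || T < 2) stop("T must be at least 2")
  T <- as.integer(T)
  k_cor <- exp(ln_C_cor)
  k_q <- exp(ln_C_q)
  C_what <- matrix(0, 6L, T, dimnames = list(WHAT_OUTCOMES, NULL))
  C_what[what_index("RIGHT"), 2:T] <- 2 * k_cor
  C_what[what_index("WRONG"), 2:T] <- -4 * k_cor
  C_where <- matrix(0, 8L, T, dimnames = list(LOCATIONS, NULL))
  for (tau in 2:T) C_where[1:5, tau] <- -0.25 * (tau - 1) * k_q
  structure(list(C_what = C_what, C_where = C_where,
                 k_cor = k_cor, k_q = k_q, T = T),
            class = "scene_preferences")
}

#' Build the prior over policies
#'
#' The first eight policies (one-step saccades to each location) have log
#' prior weight zero; the ninth, heuristic policy has weight `E_h`, the log
#' propensity to engage a fixed-form exploration strategy.
#'
#' @param E_h log prior weight of the heuristic policy.
#' @param H heuristic kernel.
#' @return object of class `policy_prior` with fields `E` (length 9) and `H`.
#' @export
build_policy_prior <- function(E_h = log(2), H = heuristic_map()) {
  check_heuristic_kernel(H)
  structure(list(E = c(rep(0, 8), E_h), H = H), class = "policy_prior")
}

#' Assemble the full generative model of the task
#'
#' Bundles likelihood, transition and prior arrays together with
#' precomputed per-location likelihood matrices over the 12 joint latent
#' states (3 contexts x 2 vertical x 2 horizontal flips; context varying
#' fastest), which belief updating and policy evaluation use directly.
#'
#' @param T trial horizon in time steps.
#' @param H heuristic kernel (defaults to the reading order).
#' @return object of class `scene_model`.
#' @export
scene_model <- function(T = 6L, H = heuristic_map()) {
  check_heuristic_kernel(H)
  if (!is.numeric(T) || T < 2) stop("T must be at least 2")
  lik <- build_likelihood()
  trans <- build_transitions(H)
  D <- list(context = rep(1 / 3, 3),
            location = c(1, rep(0, 7)),
            vflip = c(0.5, 0.5), hflip = c(0.5, 0.5))
  names(D$context) <- CONTEXTS
  names(D$location) <- LOCATIONS

  # 6 x 12 likelihood per location over joint latent states
  A_joint <- vector("list", 8L)
  for (li in 1:8) {
    M <- matrix(0, 6L, 12L)
    k <- 0L
    for (h in 1:2) for (v in 1:2) for (ci in 1:3) {
      k <- k + 1L
      M[, k] <- lik$A_what[, ci, li, v, h]
    }
    rownames(M) <- WHAT_OUTCOMES
    A_joint[[li]] <- M
  }
  logA_joint <- lapply(A_joint, function(M) log(pmax(M, exp(LOG_FLOOR))))

  joint_states <- expand.grid(context = CONTEXTS,
                              vflip = c(FALSE, TRUE), hflip = c(FALSE, TRUE),
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)

  structure(list(A_what = lik$A_what, A_where = lik$A_where,
                 B_location = trans$B_location, B_context = trans$B_context,
                 B_vflip = trans$B_vflip, B_hflip = trans$B_hflip,
                 D = D, T = as.integer(T), H = H,
                 A_joint = A_joint, logA_joint = logA_joint,
                 joint_states = joint_states,
                 labels = list(locations = LOCATIONS, what = WHAT_OUTCOMES,
                               contexts = CONTEXTS)),
            class = "scene_model")
}

#' @export
print.scene_model <- function(x, ...) {
  cat("<scene_model> 2x2 gaze-contingent scene-categorisation task\n")
  cat("  horizon T =", x$T, "time steps; 9 one-step policies",
      "(8 saccades + 1 heuristic)\n")
  cat("  heuristic kernel:",
      paste(LOCATIONS, "->", LOCATIONS[x$H], collapse = ", "), "\n")
  invisible(x)
}

#' Resolve the target location of a policy
#'
#' @param action policy index 1..9.
#' @param current current location index.
#' @param H heuristic kernel.
#' @return location index the policy saccades to.
#' @export
action_target <- function(action, current, H) {
  if (action < 1L || action > 9L) stop("action must be in 1..9")
  if (action <= 8L) as.integer(action) else as.integer(H[current])
}

#' Serialise a scene model to JSON
#'
#' Writes label lists, flattened probability tables with shape metadata, the
#' horizon and the heuristic kernel as an 8-token list.
#'
#' @param model a `scene_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene_model <- function(model, path) {
  flat <- function(a) list(shape = dim(a) %||% length(a), values = as.vector(a))
  obj <- list(labels = model$labels, T = model$T,
              H = LOCATIONS[model$H],
              A_what = flat(model$A_what), A_where = flat(model$A_where),
              B_location = flat(model$B_location),
              D = model$D)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
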