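#' Enumerate the 24 fixed-form exploration orders
#'
#' With four quadrants and no revisits there are 4! = 24 ways of exploring
#' the scene; each is a fixed-form (state-action) policy.
#'
#' @return list of 24 objects of class `heuristic_order`, each with `order`
#'   (quadrant tokens) and `map` (the induced location kernel, per
#'   [heuristic_map()]), sorted lexicographically by quadrant index.
#' @export
enumerate_fixed_orders <- function() {
  perms <- permutations(QUADRANTS)
  lapply(perms, function(ord)
    structure(list(order = ord, map = heuristic_map(ord)),
              class = "heuristic_order"))
}

# quadrant visit sequence of one trial path (choice steps stripped;
# consecutive repeats collapsed -- a self-transition under an absorbing
# heuristic kernel is a held gaze, not a new fixation)
quadrant_sequence <- function(path) {
  loc <- path$location
  loc <- loc[loc %in% QUADRANTS]
  if (length(loc)) rle(loc)$values else loc
}

#' Estimate a subject's heuristic kernel from scan-paths
#'
#' Counts location-to-location transitions over all saccade sequences
#' (choice steps stripped, since a fixed-form policy never targets a choice
#' location) and maps each location to its most frequent successor. Ties are
#' broken toward the lowest location index; locations never visited map to
#' themselves.
#'
#' @param scanpaths list of trial paths: data frames with a `location`
#'   column of location tokens (a `trial_record$path` works directly).
#' @return integer kernel as from [heuristic_map()].
#' @export
estimate_heuristic_map <- function(scanpaths) {
  counts <- matrix(0L, 8L, 8L, dimnames = list(LOCATIONS, LOCATIONS))
  for (p in scanpaths) {
    if (is.list(p) && !is.data.frame(p) && !is.null(p$path)) p <- p$path
    loc <- loc_index(p$location)
    loc <- loc[!loc %in% LOC_CHOICE]
    if (length(loc) >= 2L)
      for (i in seq_len(length(loc) - 1L))
        counts[loc[i], loc[i + 1L]] <- counts[loc[i], loc[i + 1L]] + 1L
  }
  if (sum(counts) == 0L) stop("no transitions observed in the scan-paths")
  H <- vapply(1:8, function(j) {
    row <- counts[j, ]
    if (sum(row) == 0L) j else which.max(row)  # which.max: lowest index on ties
  }, 0L)
  H <- as.integer(H)
  names(H) <- LOCATIONS
  H
}

#' Heuristic consistency of scan-paths (fixed-order profile)
#'
#' A trial is consistent with a fixed order if its quadrant visit sequence
#' is a prefix of that order. Because short scan-paths are prefixes of
#' several orders, the per-order frequencies can sum to more than one.
#' Trials with no quadrant fixations (immediate choices) are consistent with
#' every order and are excluded from the denominator; their count is
#' reported separately.
#'
#' @param scanpaths list of trial paths (as in [estimate_heuristic_map()]).
#' @param orders list of `heuristic_order` objects
#'   (default [enumerate_fixed_orders()]).
#' @return list with `table` (data frame: order label, consistency
#'   frequency, favourite flag), `favourite` (list with `order` and
#'   `frequency`), `n_trials_used`, `n_zero_quadrant`.
#' @export
heuristic_consistency <- function(scanpaths, orders = enumerate_fixed_orders()) {
  seqs <- lapply(scanpaths, function(p) {
    if (is.list(p) && !is.data.frame(p) && !is.null(p$path)) p <- p$path
    quadrant_sequence(p)
  })
  nq <- lengths(seqs)
  used <- seqs[nq > 0L]
  n_used <- length(used)
  freq <- vapply(orders, function(o) {
    if (n_used == 0L) return(NA_real_)
    hit <- vapply(used, function(s)
      length(s) <= 4L && identical(s, o$order[seq_along(s)]), TRUE)
    mean(hit)
  }, 0)
  labels <- vapply(orders, function(o) paste(o$order, collapse = ","), "")
  fav <- if (n_used) which.max(freq) else NA_integer_
  tab <- data.frame(order = labels, frequency = freq,
                    favourite = seq_along(orders) == fav,
                    stringsAsFactors = FALSE)
  list(table = tab,
       favourite = if (n_used) list(order = orders[[fav]]$order,
                                    frequency = freq[fav]) else NULL,
       n_trials_used = n_used,
       n_zero_quadrant = sum(nq == 0L))
}
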