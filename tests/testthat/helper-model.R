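# shared fixtures: one default model and token index helpers
MODEL <- scene_model()

loc_i <- function(tok) match(tok, LOCATIONS)
out_i <- function(tok) match(tok, WHAT_OUTCOMES)

make_history <- function(locs, outs) {
  data.frame(location = loc_i(locs), outcome = out_i(outs))
}

# independent exact-posterior oracle: enumerate the 12 joint states straight
# from the scene layouts (does not touch the model's likelihood arrays)
oracle_posterior <- function(history_tokens) {
  grid <- expand.grid(context = CONTEXTS, vflip = c(FALSE, TRUE),
                      hflip = c(FALSE, TRUE), stringsAsFactors = FALSE)
  w <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    lay <- build_scene_layout(grid$context[k], grid$vflip[k], grid$hflip[k])
    ll <- 0
    for (r in seq_len(nrow(history_tokens))) {
      loc <- history_tokens$location[r]
      obs <- history_tokens$outcome[r]
      pred <- if (loc == "FIX") "NULL" else if (loc %in% QUADRANTS) {
        lay[[loc]]
      } else {
        ok <- switch(loc, CH_FLEE = "FLEE", CH_FEED = "FEED",
                     CH_WAIT = "WAIT")
        if (ok == grid$context[k]) "RIGHT" else "WRONG"
      }
      ll <- ll + if (pred == obs) 0 else -16
    }
    w[k] <- ll
  }
  w <- exp(w - max(w))
  w <- w / sum(w)
  list(context = tapply(w, grid$context, sum)[CONTEXTS],
       vflip = tapply(w, grid$vflip, sum),
       hflip = tapply(w, grid$hflip, sum))
}

tv <- function(a, b) 0.5 * sum(abs(a - b))
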