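test_that("an empty history returns the prior marginals", {
  b <- update_beliefs(MODEL, make_history(character(), character()))
  expect_equal(b$context, MODEL$D$context)
  expect_equal(b$vflip, MODEL$D$vflip)
  expect_equal(b$hflip, MODEL$D$hflip)
})

test_that("two disambiguating cues identify the scene almost surely", {
  # seed top-left then bird top-right: a FEED scene under a horizontal flip
  h <- make_history(c("FIX", "TL", "TR"), c("NULL", "SEED", "BIRD"))
  b <- update_beliefs(MODEL, h)
  expect_gt(b$context[["FEED"]], 0.999)
  e <- exact_beliefs(MODEL, h)
  expect_gt(e$context[["FEED"]], 0.999)
})

test_that("mean-field equals the exact posterior on product-support histories", {
  # fully disambiguated scenes: posterior is a point mass for every
  # context/flip combination, where the factorised fixed point is exact
  for (v in c(FALSE, TRUE)) for (h in c(FALSE, TRUE)) for (ct in CONTEXTS) {
    lay <- build_scene_layout(ct, v, h)
    hist <- make_history(c("FIX", QUADRANTS), c("NULL", unname(lay)))
    b <- update_beliefs(MODEL, hist)
    hist_tok <- data.frame(location = c("FIX", QUADRANTS),
                           outcome = c("NULL", unname(lay)),
                           stringsAsFactors = FALSE)
    o <- oracle_posterior(hist_tok)
    expect_lt(tv(b$context, o$context), 1e-6)
    expect_lt(tv(b$vflip, o$vflip), 1e-6)
    expect_lt(tv(b$hflip, o$hflip), 1e-6)
  }
  # context-only evidence (feedback with no cues) also has product support
  hist <- make_history(c("FIX", "CH_FEED"), c("NULL", "RIGHT"))
  b <- update_beliefs(MODEL, hist)
  o <- oracle_posterior(data.frame(location = c("FIX", "CH_FEED"),
                                   outcome = c("NULL", "RIGHT"),
                                   stringsAsFactors = FALSE))
  expect_lt(tv(b$context, o$context), 1e-6)
  expect_lt(tv(b$vflip, o$vflip), 1e-6)
})

test_that("mean-field is overconfident on correlated (non-product) support", {
  # a single empty quadrant leaves a posterior whose support is not a
  # product set; the coordinate-ascent fixed point then sharpens the flip
  # marginals well beyond the exact posterior -- a known property of the
  # factorised approximation, asserted here so it is documented behaviour
  h <- make_history(c("FIX", "TL"), c("NULL", "NULL"))
  b <- update_beliefs(MODEL, h)
  o <- oracle_posterior(data.frame(location = c("FIX", "TL"),
                                   outcome = c("NULL", "NULL"),
                                   stringsAsFactors = FALSE))
  expect_equal(unname(o$vflip[2]), 5 / 6, tolerance = 1e-6)
  expect_gt(tv(b$vflip, o$vflip), 0.1)
})

test_that("belief updating is order-invariant over the history", {
  h <- make_history(c("FIX", "TL", "TR", "BL"),
                    c("NULL", "NULL", "SEED", "BIRD"))
  b1 <- update_beliefs(MODEL, h)
  for (rep in 1:5) {
    perm <- sample(nrow(h))
    b2 <- update_beliefs(MODEL, h[perm, ])
    expect_lt(max(abs(c(b1$context - b2$context, b1$vflip - b2$vflip,
                        b1$hflip - b2$hflip))), 1e-9)
  }
})

test_that("contradictory observations are flagged as inconsistent", {
  h <- make_history(c("FIX", "TL", "TL"), c("NULL", "BIRD", "SEED"))
  expect_error(update_beliefs(MODEL, h),
               class = "epiforage_inconsistent_scanpath")
  expect_silent(update_beliefs(MODEL, h, strict = FALSE))
})

test_that("epistemic value is Bayesian surprise and vanishes when resolved", {
  b0 <- beliefs_prior(MODEL)
  expect_equal(epistemic_value(MODEL, b0, 1), 0)  # NULL certain at fixation
  # brute-force oracle for the first saccade to TL under a uniform prior
  grid <- expand.grid(context = CONTEXTS, vflip = c(FALSE, TRUE),
                      hflip = c(FALSE, TRUE), stringsAsFactors = FALSE)
  obj <- vapply(seq_len(nrow(grid)), function(k)
    build_scene_layout(grid$context[k], grid$vflip[k], grid$hflip[k])[["TL"]],
    "")
  expected <- 0
  for (o in unique(obj)) {
    po <- mean(obj == o)
    post <- (obj == o) / sum(obj == o)
    expected <- expected + po * sum(post[post > 0] *
                                      log(post[post > 0] / (1 / 12)))
  }
  expect_equal(epistemic_value(MODEL, b0, loc_i("TL")), expected,
               tolerance = 1e-10)
  expect_gt(expected, 0)
  # re-sampling an already observed quadrant resolves nothing
  h <- make_history(c("FIX", "TL"), c("NULL", "BIRD"))
  b <- update_beliefs(MODEL, h)
  # zero up to the exp(-16) likelihood floor's leakage
  expect_lt(epistemic_value(MODEL, b, loc_i("TL")), 1e-4)
  # and every epistemic value is non-negative
  for (a in 1:9) expect_gte(epistemic_value(MODEL, b, a), 0)
})

test_that("pragmatic value is the expected utility of the next outcome", {
  prefs <- build_preferences(0, 0, 6)
  b <- beliefs_prior(MODEL)
  b$context <- c(0, 1, 0)  # certain FEED
  expect_equal(pragmatic_value(MODEL, prefs, b, loc_i("CH_FEED"), 2), 2)
  b$context <- c(1, 0, 0)  # certain FLEE: choosing FEED is certainly wrong
  expect_equal(pragmatic_value(MODEL, prefs, b, loc_i("CH_FEED"), 2), -4)
  # first-step utilities are zero
  for (a in 1:9)
    expect_equal(pragmatic_value(MODEL, prefs, beliefs_prior(MODEL), a, 0), 0)
  expect_error(pragmatic_value(MODEL, prefs, b, 2, 6), "horizon")
})

test_that("the policy posterior is a shift-invariant softmax of E - F - G/beta", {
  set.seed(1)
  for (rep in 1:10) {
    E <- c(rep(0, 8), rnorm(1))
    G <- rnorm(9)
    F <- rnorm(9)
    beta <- exp(rnorm(1))
    p <- policy_posterior(E, F, G, beta)
    expect_equal(sum(p), 1)
    expect_equal(policy_posterior(E, F + 3.7, G, beta), p)
    expect_equal(policy_posterior(E, F, G + 11 * beta, beta), p)
  }
  expect_equal(policy_posterior(rep(0, 9), rep(0, 9), rep(2, 9), 1),
               rep(1 / 9, 9))
  # large beta discounts G entirely, leaving the prior
  p <- policy_posterior(c(rep(0, 8), log(2)), rep(0, 9), rnorm(9), 1e6)
  expect_equal(p, c(rep(0.1, 8), 0.2), tolerance = 1e-4)
  expect_error(policy_posterior(rep(0, 9), rep(0, 9), rep(0, 9), 0), "beta")
})

test_that("action selection respects the posterior and the tie-break", {
  pi <- replace(rep(0, 9), 4, 1)
  expect_equal(select_action(pi, "argmax"), 4L)
  expect_equal(select_action(pi, "sample"), 4L)
  expect_equal(select_action(c(0, 0.5, 0.5, rep(0, 6)), "argmax"), 2L)
  set.seed(2)
  pi <- softmax(rnorm(9))
  draws <- tabulate(vapply(1:20000, function(i) select_action(pi), 0L), 9)
  se <- sqrt(pi * (1 - pi) / 20000)
  expect_true(all(abs(draws / 20000 - pi) < 3.5 * se + 1e-3))
})

test_that("without the epistemic term, policies rank by pragmatic value", {
  h <- make_history(c("FIX", "TL"), c("NULL", "SEED"))
  b <- update_beliefs(MODEL, h)
  b$location <- loc_i("TL")
  prefs <- build_preferences(0, 0, 6)
  pp <- build_policy_prior(0)
  ev <- evaluate_policies(MODEL, prefs, pp, b, 2, 1, include_epistemic = FALSE)
  expect_equal(ev$epistemic, rep(0, 9))
  expect_equal(order(ev$pi, decreasing = TRUE),
               order(ev$pragmatic, decreasing = TRUE))
  # and with it, G decomposes as -epistemic - pragmatic
  ev2 <- evaluate_policies(MODEL, prefs, pp, b, 2, 1)
  expect_equal(ev2$G, -ev2$epistemic - ev2$pragmatic)
  expect_true(all(ev2$epistemic >= 0))
})
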