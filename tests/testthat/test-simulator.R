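test_that("scene sampling is seeded and uniform over the 12 configurations", {
  set.seed(10)
  a <- replicate(20, sample_scene(), simplify = FALSE)
  set.seed(10)
  b <- replicate(20, sample_scene(), simplify = FALSE)
  expect_identical(a, b)
  set.seed(11)
  draws <- replicate(12000, {
    s <- sample_scene()
    paste(s$context, s$vflip, s$hflip)
  })
  tab <- table(draws)
  expect_equal(length(tab), 12L)
  se <- sqrt(12000 * (1 / 12) * (11 / 12))
  expect_true(all(abs(tab - 1000) < 3.5 * se))
  ctx <- table(sub(" .*", "", draws)) / 12000
  expect_true(all(abs(ctx - 1 / 3) < 0.02))
})

test_that("the worked trial replays: seed then bird reveals a FEED scene", {
  scene <- list(context = "FEED", vflip = FALSE, hflip = TRUE)
  rec <- run_trial(MODEL, subject_params(), scene,
                   forced_path = loc_i(c("TL", "TR")))
  expect_identical(rec$path$outcome, c("NULL", "SEED", "BIRD"))
  expect_gt(rec$beliefs$context[["FEED"]], 0.999)
})

test_that("trial scoring combines feedback points and stacking sampling costs", {
  expect_equal(exploration_cost(2), -0.75)  # -0.25 + (-0.5)
  expect_equal(exploration_cost(0), 0)
  rec <- list(feedback = "RIGHT", n_quadrants = 2L)
  expect_equal(score_trial(rec), 1.25)
  rec$n_quadrants <- 0L
  expect_equal(score_trial(rec), 2)
  rec$feedback <- "WRONG"; rec$n_quadrants <- 3L
  expect_equal(score_trial(rec), -4 - 1.5)
  rec$feedback <- NA_character_  # time-out costs four points
  expect_equal(score_trial(rec), -4 - 1.5)
})

test_that("trial records satisfy their schema invariants", {
  set.seed(3)
  for (i in 1:150) {
    rec <- run_trial(MODEL, subject_params(rnorm(1, 0, 0.5), rnorm(1),
                                           rnorm(1, 0, 0.5),
                                           rnorm(1, 0, 0.5)))
    expect_identical(rec$path$location[1], "FIX")
    expect_lte(sum(rec$path$location %in%
                     c("CH_FLEE", "CH_FEED", "CH_WAIT")), 1L)
    expect_lte(nrow(rec$path), MODEL$T)
    expect_equal(rec$score_delta, score_trial(rec))
    expect_equal(rec$n_quadrants,
                 length(unique(rec$path$location[rec$path$location %in%
                                                   QUADRANTS])))
    if (!is.na(rec$choice)) {
      expect_identical(rec$path$location[nrow(rec$path)],
                       paste0("CH_", rec$choice))
      expect_true(rec$feedback %in% c("RIGHT", "WRONG"))
    }
  }
})

test_that("stronger urgency (larger k_q) yields fewer saccades", {
  set.seed(21)
  lazy <- run_block(MODEL, subject_params(0, 0, 0, -1), n_trials = 500)
  set.seed(21)
  hasty <- run_block(MODEL, subject_params(0, 0, 0, 1), n_trials = 500)
  expect_gt(lazy$summary$mean_saccades_per_trial,
            hasty$summary$mean_saccades_per_trial)
})

test_that("a pure-heuristic agent follows its order and never categorises", {
  ord <- c("BL", "TL", "TR", "BR")
  m <- scene_model(H = heuristic_map(ord))
  set.seed(4)
  for (i in 1:25) {
    rec <- run_trial(m, subject_params(ln_beta = 3, E_h = 8), mode = "argmax")
    expect_true(is.na(rec$choice))
    quads <- rec$path$location[rec$path$location %in% QUADRANTS]
    expect_identical(unique(quads), ord[seq_along(unique(quads))])
  }
})

test_that("a precise epistemic agent almost never revisits quadrants", {
  # revisits carry zero epistemic value under exact beliefs; the factorised
  # (mean-field) posterior can leak mass onto history-inconsistent states
  # after correlated null cues, giving revisits spurious epistemic value,
  # so the clean property is asserted for the exact-belief agent and the
  # mean-field excess is pinned down as documented behaviour
  rate <- function(bel, seed) {
    set.seed(seed)
    revisits <- 0L; quad_steps <- 0L
    for (i in 1:300) {
      rec <- run_trial(MODEL, subject_params(ln_beta = -1.5, E_h = 0),
                       beliefs = bel)
      quads <- rec$path$location[rec$path$location %in% QUADRANTS]
      quads <- rle(quads)$values  # a held gaze is not a new fixation
      quad_steps <- quad_steps + length(quads)
      revisits <- revisits + (length(quads) - length(unique(quads)))
    }
    revisits / max(quad_steps, 1)
  }
  expect_lt(rate("exact", 5), 0.01)
  expect_gt(rate("meanfield", 5), rate("exact", 5))
})

test_that("block summaries aggregate trial records deterministically", {
  set.seed(6)
  one <- run_block(MODEL, subject_params(), n_trials = 1)
  expect_equal(one$summary$mean_score_per_trial, one$records[[1]]$score_delta)
  expect_equal(one$summary$pct_correct,
               100 * as.numeric(identical(one$records[[1]]$feedback, "RIGHT")))
  set.seed(7)
  b1 <- run_block(MODEL, subject_params(), n_trials = 30)
  set.seed(7)
  b2 <- run_block(MODEL, subject_params(), n_trials = 30)
  expect_identical(b1$summary, b2$summary)
  expect_equal(b1$summary$final_points,
               100 + sum(vapply(b1$records, function(r) r$score_delta, 0)))
})
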