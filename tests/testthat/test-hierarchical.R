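gp <- function(mu, Sigma) structure(list(mu = mu, Sigma = Sigma),
                                    class = "gaussian_posterior")

# simulate one subject's block posteriors from known second-level effects
sim_blocks <- function(eta, obs_var = 0.04, between = 1 / 16) {
  X <- peb_design(5)
  lapply(1:5, function(b) {
    m <- eta[1:4] + X[b, 2] * eta[5:8]
    gp(m + rnorm(4, 0, sqrt(obs_var + between)), diag(obs_var, 4))
  })
}

test_that("the design matrix is a constant plus a one-block decay", {
  X <- peb_design(5)
  expect_equal(unname(X[, 1]), rep(1, 5))
  expect_equal(unname(X[, 2]), exp(-(0:4)))
})

test_that("the PEB posterior equals joint-Gaussian conditioning", {
  set.seed(41)
  bp <- sim_blocks(c(0.3, -0.2, 0.4, 0.1, 0, 0, -0.6, -0.5))
  peb <- peb_fit(bp)
  # independent route: condition eta on y in the joint normal
  # [eta; y] with y = K eta + e, e ~ N(0, W)
  X <- peb_design(5); K <- kronecker(X, diag(4))
  S0 <- diag(0.25, 8)
  W <- matrix(0, 20, 20)
  for (b in 1:5) {
    idx <- ((b - 1) * 4 + 1):(b * 4)
    W[idx, idx] <- bp[[b]]$Sigma + diag(1 / 16, 4)
  }
  y <- unlist(lapply(bp, function(p) unname(p$mu)))
  Syy <- K %*% S0 %*% t(K) + W
  Sey <- S0 %*% t(K)
  mu_cond <- as.vector(Sey %*% solve(Syy, y))
  S_cond <- S0 - Sey %*% solve(Syy, t(Sey))
  expect_equal(unname(peb$eta_posterior$mu), mu_cond, tolerance = 1e-8)
  expect_equal(unname(peb$eta_posterior$Sigma), unname(S_cond),
               tolerance = 1e-8)
  expect_error(peb_fit(bp[1:4]), "balanced")
})

test_that("constant block means leave the decay effects near zero", {
  bp <- lapply(1:5, function(b) gp(c(0.5, -0.3, 0.2, 0), diag(0.01, 4)))
  peb <- peb_fit(bp)
  decays <- peb$eta_posterior$mu[5:8]
  sds <- sqrt(diag(peb$eta_posterior$Sigma))[5:8]
  expect_true(all(abs(decays) < 2 * sds))
})

test_that("known second-level effects are recovered with calibrated intervals", {
  set.seed(42)
  eta <- c(0.3, -0.2, 0.4, 0.1, 0, 0, -0.6, -0.5)
  hits <- matrix(NA, 20, 8)
  for (r in 1:20) {
    peb <- peb_fit(sim_blocks(eta))
    sd <- sqrt(diag(peb$eta_posterior$Sigma))
    hits[r, ] <- eta >= peb$eta_posterior$mu - 1.645 * sd &
      eta <= peb$eta_posterior$mu + 1.645 * sd
  }
  # tail components of eta sit 1-2 prior SDs out, so mild shrinkage pulls
  # their per-component coverage a little below nominal; overall coverage
  # stays calibrated
  expect_gte(mean(hits), 0.85)
  expect_true(all(colMeans(hits) >= 0.7))
})

test_that("BMR matches numerical quadrature and is exact on identities", {
  post <- list(mean = 0.8, cov = matrix(0.1))
  prior <- list(mean = 0, cov = matrix(1))
  # identity reduction changes nothing, exactly
  r <- bmr(post, prior, prior)
  expect_identical(r$delta_f, 0)
  expect_equal(r$reduced_posterior$mean, 0.8)
  # 1-d oracle: evidence ratio by quadrature over the implied likelihood
  # l(x) propto N(x; mu, s) / N(x; mu0, s0)
  for (rv in c(0.5, 1e-2, 1e-4)) {
    red <- list(mean = 0, cov = matrix(rv))
    lik <- function(x) dnorm(x, 0.8, sqrt(0.1)) / dnorm(x, 0, 1)
    z_full <- integrate(function(x) lik(x) * dnorm(x, 0, 1),
                        -20, 20, rel.tol = 1e-12)$value
    z_red <- integrate(function(x) lik(x) * dnorm(x, 0, sqrt(rv)),
                       -20, 20, rel.tol = 1e-12)$value
    expect_equal(bmr(post, prior, red)$delta_f, log(z_red / z_full),
                 tolerance = 1e-6)
  }
  # switching off a component with a clearly nonzero mean loses evidence
  expect_lt(bmr(post, prior, list(mean = 0, cov = matrix(1e-8)))$delta_f, 0)
  # 2-d oracle with correlated posterior, by iterated 1-d quadrature
  S <- matrix(c(0.2, 0.05, 0.05, 0.1), 2)
  post2 <- list(mean = c(0.5, -0.3), cov = S)
  prior2 <- list(mean = c(0, 0), cov = diag(2))
  red2 <- list(mean = c(0, 0), cov = diag(c(1, 1e-4)))
  dmv <- function(x, y, m, V) {
    Vi <- solve(V)
    z1 <- x - m[1]; z2 <- y - m[2]
    qf <- Vi[1, 1] * z1^2 + 2 * Vi[1, 2] * z1 * z2 + Vi[2, 2] * z2^2
    exp(-0.5 * qf) / (2 * pi * sqrt(det(V)))
  }
  lik2 <- function(x, y) dmv(x, y, post2$mean, S) / dmv(x, y, c(0, 0), diag(2))
  z2d <- function(Vr, ylim) {
    inner <- function(x) vapply(x, function(xx)
      integrate(function(y) lik2(xx, y) * dmv(xx, y, c(0, 0), Vr),
                -ylim, ylim, rel.tol = 1e-11)$value, 0)
    integrate(inner, -8, 8, rel.tol = 1e-10)$value
  }
  z_full <- z2d(diag(2), 8)
  z_red <- z2d(diag(c(1, 1e-4)), 1)
  expect_equal(bmr(post2, prior2, red2)$delta_f, log(z_red / z_full),
               tolerance = 1e-6)
})

test_that("BMR is additive along chains of reductions", {
  set.seed(43)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  post <- list(mean = rnorm(3), cov = 0.1 * A)
  prior <- list(mean = rep(0, 3), cov = diag(3))
  mid <- list(mean = rep(0, 3), cov = diag(c(1, 1, 1e-2)))
  end <- list(mean = rep(0, 3), cov = diag(c(1, 1e-2, 1e-2)))
  ab <- bmr(post, prior, mid)
  bc <- bmr(ab$reduced_posterior, mid, end)
  ac <- bmr(post, prior, end)
  expect_equal(ab$delta_f + bc$delta_f, ac$delta_f, tolerance = 1e-9)
})

test_that("the model space has 256 patterns over 8 effects", {
  set.seed(44)
  pebs <- lapply(1:3, function(s)
    peb_fit(sim_blocks(c(0.3, -0.2, 0.4, 0.1, 0, 0, -0.6, -0.5))))
  ms <- search_model_space(pebs)
  expect_equal(dim(ms$patterns), c(256L, 8L))
  expect_equal(sum(ms$posterior_prob), 1)
  # softmax pooling ignores constant shifts
  expect_equal(softmax(ms$pooled_logev + 123), ms$posterior_prob)
  # the full model reduces to itself with zero evidence change
  full <- which(rowSums(ms$patterns) == 8)
  expect_equal(ms$pooled_logev[full], 0, tolerance = 1e-8)
})

test_that("null cohorts rank the all-off pattern among the top models", {
  set.seed(45)
  pebs <- lapply(1:4, function(s) peb_fit(sim_blocks(rep(0, 8))))
  ms <- search_model_space(pebs)
  null_model <- which(rowSums(ms$patterns) == 0)
  rank_null <- rank(-ms$pooled_logev)[null_model]
  expect_lte(rank_null, 25)  # top 10% of 256
})

test_that("model averaging matches closed-form mixture moments", {
  means <- rbind(c(1, 0), c(-1, 0))
  covs <- array(0, c(2, 2, 2))
  covs[, , 1] <- diag(0.2, 2); covs[, , 2] <- diag(0.2, 2)
  mom <- bma_moments(c(0.5, 0.5), means, covs)
  expect_equal(mom$mean, c(0, 0))
  expect_equal(mom$cov[1, 1], 1 + 0.2)  # between-model spread inflates
  expect_equal(mom$cov[2, 2], 0.2)
  # a single certain model returns that model's posterior
  mom1 <- bma_moments(c(1, 0), means, covs)
  expect_equal(mom1$mean, c(1, 0))
  expect_equal(mom1$cov, diag(0.2, 2))
  # law of total variance: mixture variance dominates the within part
  expect_gte(mom$cov[1, 1], min(covs[1, 1, ]))
})
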