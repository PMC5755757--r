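#' Numerically stable softmax
#'
#' @param x numeric vector of log weights.
#' @return simplex vector summing to 1.
#' @export
softmax <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

# log floor applied to likelihood entries before taking logs (keeps the
# objective finite on observations that are impossible under a state)
LOG_FLOOR <- -16

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# log determinant of a symmetric positive definite matrix via Cholesky
logdet_spd <- function(S) {
  2 * sum(log(diag(chol(S))))
}

# add the smallest diagonal jitter (powers of 10) that makes S positive
# definite; returns list(S, jitter)
make_spd <- function(S, max_tries = 12L) {
  S <- (S + t(S)) / 2
  jit <- 0
  for (i in seq_len(max_tries)) {
    ok <- tryCatch({ chol(S + diag(jit, nrow(S))); TRUE },
                   error = function(e) FALSE)
    if (ok) return(list(S = S + diag(jit, nrow(S)), jitter = jit))
    jit <- if (jit == 0) 1e-10 else jit * 10
  }
  stop("could not regularise matrix to positive definite")
}

# log density of a multivariate normal
dmvnorm_log <- function(x, mean, cov) {
  d <- length(x)
  L <- chol(cov)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# all permutations of a vector, in lexicographic order of positions
permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
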