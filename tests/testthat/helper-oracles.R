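# Independent oracles, written from the model definitions only -- no calls
# into the package's own closed forms.

# expected increment before event k, by definition of the geometric rate law
oracle_expected_increment <- function(k, alpha, lambda) {
  1 / (lambda * alpha^(-k + 1))
}

# expected strain between events i and j by literal term-by-term summation
oracle_mu_segment <- function(i, j, alpha, lambda, tol = 1e-16) {
  if (is.infinite(j)) {
    # sum the geometric tail numerically until terms vanish
    k <- i + 1
    acc <- 0
    repeat {
      term <- oracle_expected_increment(k, alpha, lambda)
      acc <- acc + term
      if (term < tol * max(acc, 1e-300)) break
      k <- k + 1
    }
    acc
  } else {
    sum(oracle_expected_increment(seq(i + 1, j), alpha, lambda))
  }
}

# penalty by literal re-summation of its defining terms
oracle_penalty <- function(alpha, lambda, eps) {
  n <- length(eps)
  term1 <- (oracle_mu_segment(0, Inf, alpha, lambda) - eps[n])^2
  term2 <- 0
  if (n >= 2) {
    for (k in seq_len(n - 1)) {
      term2 <- term2 +
        (oracle_mu_segment(k, k + 1, alpha, lambda) -
           (eps[k + 1] - eps[k]))^2
    }
  }
  term1 + term2
}

# event sequence whose consecutive gaps sit exactly at their expectations
# and whose total strain equals mu_infinity (the first event strain is the
# free coordinate that absorbs the remainder of the total)
exact_expectation_sequence <- function(alpha, lambda, n) {
  gaps <- alpha^seq_len(n - 1) / lambda          # gaps k = 1 .. n-1
  mu_inf <- 1 / ((1 - alpha) * lambda)
  eps1 <- mu_inf - sum(gaps)
  cumsum(c(eps1, gaps))
}

random_params <- function() {
  list(alpha = runif(1, 0.05, 0.95), lambda = exp(runif(1, -1, 5)))
}
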