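# Independent oracles used across tests.

# Bisection on the flux residual in log-pool space, independent of the
# package's solver path.
bisect_steady_a <- function(phiR, p, iters = 200L) {
  f <- function(a) flux_residual(a, phiR, p)
  lo <- log(p$K_gamma * 1e-6)
  hi <- log(p$K_nu * 1e6)
  while (f(exp(lo)) <= 0) lo <- lo - log(10)
  while (f(exp(hi)) >= 0) hi <- hi + log(10)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(exp(mid)) > 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

# Ordinary least squares via the normal equations, independent of lm().
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  c(intercept = beta[1], slope = beta[2],
    r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Seeded family of monotone hill control functions guaranteed to cross the
# optimality plateau: chi below the balance curve at the plateau's lower
# edge and above it at the upper edge.
sample_crossing_controls <- function(n, p, plateau, seed) {
  set.seed(seed)
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    K <- exp(stats::runif(1, log(plateau$a_lo), log(plateau$a_hi)))
    h <- sample(1:4, 1)
    b <- stats::runif(1, 0, 0.05)
    amp <- stats::runif(1, plateau$phiR_hi + 0.05 - b, 1 - b)
    chi <- control_function("hill", baseline = b, amplitude = amp,
                            K_chi = K, h = h)
    crosses <- chi(plateau$a_lo) < phiR_balance(plateau$a_lo, p) &&
      chi(plateau$a_hi) > phiR_balance(plateau$a_hi, p)
    if (!crosses) next
    k <- k + 1L
    out[[k]] <- chi
  }
  out
}
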