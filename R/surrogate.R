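# Exactly solvable Gaussian-chain surrogate used as a control variate for
# the equilibrium autocorrelation estimator.
#
# The surrogate replaces the stiff fixed-length springs by rest-length-0
# harmonic springs of constant k_h = 3 (kBT/a^2), which reproduces the
# unit mean-square bond length of the real chain, and drops the wall.
# Its end-vector dynamics is an exactly linear Ornstein-Uhlenbeck system
# whose discrete-time autocorrelation is known in closed form, and it is
# integrated with the *same* noise stream as a paired real-chain run, so
# the sampling error of its empirical autocorrelation tracks the error of
# the real chain's closely.  Subtracting the surrogate's error from the
# real estimate (a control variate with unit coefficient) removes most of
# the slow-mode sampling noise that otherwise dominates the fitted
# relaxation time.

# coupling matrix of the tethered (fixed-free) chain of n free beads
gaussian_chain_matrix <- function(n, kh = 3) {
  m <- diag(2, n)
  m[cbind(1:(n - 1), 2:n)] <- -1
  m[cbind(2:n, 1:(n - 1))] <- -1
  m[n, n] <- 1
  kh * m
}

# exact discrete-time ACF of the planar end vector of the surrogate on
# the recorded lag grid (lags in tau0, stride in steps)
gaussian_chain_acf <- function(n, lags_tau, kh = 3, dt = 1e-4,
                               stride = round(1 / dt)) {
  eg <- eigen(gaussian_chain_matrix(n, kh), symmetric = TRUE)
  a <- 1 - eg$values * dt
  if (any(a <= -1)) stop("surrogate unstable at this dt")
  var_p <- 2 * dt / (1 - a^2)
  v_end2 <- eg$vectors[n, ]^2
  steps <- round(lags_tau / dt)
  C <- vapply(steps, function(L) 2 * sum(v_end2 * var_p * a^L), numeric(1))
  tibble::tibble(lag = lags_tau, C = C)
}

# exact stationary draw of the surrogate (positions relative to the
# tether at (0, 0, 1)); independent x, y, z mode amplitudes
sample_gaussian_chain_state <- function(n, kh = 3, dt = 1e-4, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  eg <- eigen(gaussian_chain_matrix(n, kh), symmetric = TRUE)
  a <- 1 - eg$values * dt
  sd_p <- sqrt(2 * dt / (1 - a^2))
  u <- vapply(1:3, function(v) {
    as.vector(eg$vectors %*% (stats::rnorm(n) * sd_p))
  }, numeric(n))
  pos <- rbind(c(0, 0, 1), sweep(u, 2, c(0, 0, 1), "+"))
  pos
}

# run the surrogate with the same seed (hence same noise stream) as a
# paired real-chain run; returns the end series
run_gaussian_chain <- function(n, duration, stride, seed, init_pos,
                               kh = 3, dt = 1e-4) {
  n_steps <- round(duration / dt)
  res <- bd_run_cpp(init_pos, kh, 0, 0, 1, 0, 1L, 0, dt, 0, n_steps,
                    as.integer(stride), as.double(seed), TRUE, FALSE,
                    -Inf, 1, TRUE)
  tibble::tibble(time = res$times, x = res$frames[, 1],
                 y = res$frames[, 2], z = res$frames[, 3])
}
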