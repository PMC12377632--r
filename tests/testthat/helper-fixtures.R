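# helpers shared across test files

# random small conformation with bead 0 tethered; z kept well above the
# wall floor but sometimes inside the repulsive range
random_conformation <- function(n_segments, seed) {
  set.seed(seed)
  pos <- matrix(0, n_segments + 1, 3)
  pos[1, ] <- c(0, 0, 1)
  for (i in 2:(n_segments + 1)) {
    step <- stats::rnorm(3)
    step <- step / sqrt(sum(step^2)) * stats::runif(1, 0.9, 1.1)
    pos[i, ] <- pos[i - 1, ] + step
    pos[i, 3] <- max(pos[i, 3], 0.4)
  }
  chain_state(pos)
}

# parameters with every interaction active, small chain
peg_params <- function(n_segments = 6) {
  model_params(n_segments = n_segments, alpha = 0.4, peg_pct = 3,
               decay_d = 1)
}

force_matrix <- function(f) cbind(f$fx, f$fy, f$fz)

numerical_gradient <- function(state, params, h = 1e-6) {
  pos <- cbind(state$x, state$y, state$z)
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (v in 1:3) {
      pp <- pos; pp[i, v] <- pp[i, v] + h
      pm <- pos; pm[i, v] <- pm[i, v] - h
      up <- tetherflow:::total_potential_cpp(
        pp, params$spring_k, params$wall_eps, params$alpha, params$decay_d,
        params$peg_pct, params$neighbor_cutoff)
      um <- tetherflow:::total_potential_cpp(
        pm, params$spring_k, params$wall_eps, params$alpha, params$decay_d,
        params$peg_pct, params$neighbor_cutoff)
      g[i, v] <- -(up - um) / (2 * h)
    }
  }
  g
}
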