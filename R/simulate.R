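#' Gaussian noise impulses for the Euler-Maruyama scheme
#'
#' Draws the stochastic impulses `f^B` added to every free bead each step:
#' independent Gaussians with mean 0 and variance `2 dt` per bead per axis
#' (reduced units), the discrete form of the fluctuation-dissipation
#' relation for a bead with unit drag.  The stream is a deterministic
#' function of `seed`, and is the same stream the integrator consumes.
#'
#' @param n_beads number of beads drawn for per step.
#' @param dt time step (tau0).
#' @param seed integer seed.
#' @param n_steps number of steps' worth of impulses to return.
#' @return tibble with columns `step`, `bead`, `fx`, `fy`, `fz`.
#' @export
draw_noise <- function(n_beads, dt, seed, n_steps = 1) {
  if (dt <= 0) stop("dt must be > 0")
  m <- draw_noise_cpp(n_beads, dt, as.double(seed), as.integer(n_steps))
  tibble::tibble(
    step = rep(seq_len(n_steps), each = n_beads),
    bead = rep(seq_len(n_beads), times = n_steps),
    fx = m[, 1], fy = m[, 2], fz = m[, 3]
  )
}

#' Advance the chain by one Euler-Maruyama step
#'
#' One explicit update of beads `1..N`:
#' `r(i+1) = r(i) + (F_el + F_s + F_peg + Pe * z * x_hat) dt + f^B`,
#' with bead 0 held fixed and the clock advanced by `dt`.  `impulses` may
#' be `NULL` (deterministic step, the testing hook) or an `N x 3` matrix.
#'
#' @param state a [chain_state()].
#' @param params a [model_params()].
#' @param impulses `NULL` or numeric `n_segments x 3` matrix of stochastic
#'   impulses for beads `1..N`.
#' @return the advanced `chain_state`.
#' @export
bd_step <- function(state, params, impulses = NULL) {
  f <- total_forces(state, params)
  n <- params$n_segments
  if (is.null(impulses)) impulses <- matrix(0, n, 3)
  impulses <- as.matrix(impulses)
  stopifnot(nrow(impulses) == n, ncol(impulses) == 3)
  pos <- state_matrix(state)
  free <- 2:(n + 1)
  pos[free, 1] <- pos[free, 1] +
    (f$fx[free] + params$peclet * pos[free, 3]) * params$dt + impulses[, 1]
  pos[free, 2] <- pos[free, 2] + f$fy[free] * params$dt + impulses[, 2]
  pos[free, 3] <- pos[free, 3] + f$fz[free] * params$dt + impulses[, 3]
  if (any(!is.finite(pos)) || any(pos[free, 3] < params$z_floor)) {
    bad <- which(!is.finite(rowSums(pos)) | pos[, 3] < params$z_floor)[1] - 1
    stop("integration failure: bead ", bad,
         " non-finite or below z_floor after step")
  }
  chain_state(pos, time = attr(state, "time") + params$dt)
}

#' Run a Brownian dynamics trajectory
#'
#' Integrates the overdamped Langevin equation for the tethered chain by
#' the explicit Euler-Maruyama scheme with constant shear drift
#' `Pe * z` along x, recording every `stride` steps.  The run is fully
#' reproducible: identical `(params, duration, stride, seed, init)` give
#' bit-identical trajectories.
#'
#' @param params a [model_params()].
#' @param duration total simulated time (tau0 units).
#' @param stride recording interval in steps (default: one frame per
#'   tau0).
#' @param seed integer RNG seed, recorded in the result.
#' @param init `"extended_x"`, `"extended_z"`, or a [chain_state()].
#' @param noise_on `FALSE` switches the Brownian impulses off (a testing
#'   hook for deterministic fixed points, not a physical regime).
#' @param record `"end"` keeps only the free-end coordinates per frame
#'   (enough for every observable in the package); `"full"` keeps all
#'   beads.
#' @param antithetic `TRUE` negates the whole impulse stream, giving the
#'   antithetic partner of the run with the same seed (a
#'   variance-reduction device for ensemble means; the negated stream is
#'   an equally valid Gaussian sample).
#' @return object of class `"bd_trajectory"`: list with `times` (tau0),
#'   `end` (frames x 3 matrix of free-end x,y,z), `frames` (frames x
#'   3(N+1) matrix, only for `record = "full"`), `final` (final
#'   `chain_state`), `params`, and the run metadata.
#' @examples
#' traj <- bd_run(model_params(n_segments = 5), duration = 1, seed = 1)
#' tail(end_series(traj))
#' @export
bd_run <- function(params, duration, stride = round(1 / params$dt),
                   seed = 1L, init = "extended_x", noise_on = TRUE,
                   record = c("end", "full"), antithetic = FALSE) {
  validate_model_params(params)
  record <- match.arg(record)
  if (duration <= 0) stop("duration must be > 0")
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  state <- if (inherits(init, "chain_state")) init
           else init_conformation(init, params)
  if (nrow(state) != params$n_segments + 1) {
    stop("initial state has ", nrow(state) - 1,
         " segments but params$n_segments = ", params$n_segments)
  }
  n_steps <- round(duration / params$dt)
  res <- bd_run_cpp(state_matrix(state), params$spring_k, params$wall_eps,
                    params$alpha, params$decay_d, params$peg_pct,
                    params$neighbor_cutoff, params$peclet, params$dt,
                    attr(state, "time"), n_steps, stride, as.double(seed),
                    isTRUE(noise_on), record == "full", params$z_floor,
                    if (isTRUE(antithetic)) -1 else 1, FALSE)
  out <- list(
    times = res$times,
    end = if (record == "full") {
      nb <- params$n_segments + 1
      res$frames[, c(3 * nb - 2, 3 * nb - 1, 3 * nb), drop = FALSE]
    } else res$frames,
    frames = if (record == "full") res$frames else NULL,
    final = chain_state(res$final, time = attr(state, "time") +
                          n_steps * params$dt),
    params = params,
    runspec = list(duration = duration, stride = stride, seed = seed,
                   init = if (inherits(init, "chain_state")) "supplied"
                          else init,
                   noise_on = isTRUE(noise_on), record = record,
                   antithetic = isTRUE(antithetic))
  )
  class(out) <- "bd_trajectory"
  out
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<bd_trajectory> N = %d, Pe = %g, alpha = %g; %d frames over %g tau0 (seed %s)\n",
    x$params$n_segments, x$params$peclet, x$params$alpha, length(x$times),
    x$runspec$duration, format(x$runspec$seed)))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' One row per frame and bead (for full-record runs) or per frame for the
#' free end only. Columns `time`, `bead`, `x`, `y`, `z`, reduced units.
#'
#' @param x a [bd_run()] trajectory.
#' @param ... unused.
#' @export
as_tibble.bd_trajectory <- function(x, ...) {
  traj <- x
  if (!is.null(traj$frames)) {
    nb <- traj$params$n_segments + 1
    nf <- length(traj$times)
    tibble::tibble(
      time = rep(traj$times, times = nb),
      bead = rep(0:(nb - 1), each = nf),
      x = as.vector(traj$frames[, 3 * (1:nb) - 2]),
      y = as.vector(traj$frames[, 3 * (1:nb) - 1]),
      z = as.vector(traj$frames[, 3 * (1:nb)])
    )
  } else {
    tibble::tibble(time = traj$times, bead = traj$params$n_segments,
                   x = traj$end[, 1], y = traj$end[, 2], z = traj$end[, 3])
  }
}

#' Export a trajectory
#'
#' `write_trajectory_csv()` writes the tidy long form (columns `time`,
#' `bead`, `x`, `y`, `z`; reduced units) with `# key: value` metadata
#' header lines carrying the seed and parameters.  `write_trajectory_xyz()`
#' writes an XYZ-style block per frame for visualization (full-record
#' trajectories only).
#'
#' @param traj a [bd_run()] trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- traj$params
  writeLines(c(
    sprintf("# tetherflow trajectory; reduced units (a, kBT, tau0)"),
    sprintf("# seed: %s; stride: %d; duration: %g", format(traj$runspec$seed),
            traj$runspec$stride, traj$runspec$duration),
    sprintf("# N: %d; spring_k: %g; wall_eps: %g; alpha: %g; decay_d: %g; peg_pct: %g; Pe: %g; dt: %g",
            p$n_segments, p$spring_k, p$wall_eps, p$alpha, p$decay_d,
            p$peg_pct, p$peclet, p$dt)
  ), con)
  utils::write.csv(as_tibble.bd_trajectory(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_trajectory_xyz <- function(traj, path) {
  if (is.null(traj$frames)) {
    stop("XYZ export needs a full-record trajectory (record = \"full\")")
  }
  nb <- traj$params$n_segments + 1
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$times)) {
    writeLines(c(format(nb), sprintf("t = %g tau0", traj$times[i])), con)
    xyz <- matrix(traj$frames[i, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("C %.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Free-bead diffusion (fluctuation-dissipation check)
#'
#' Integrates force-free beads with the same noise generator and update
#' rule as [bd_run()]: each coordinate must perform a random walk whose
#' displacement variance grows as `2 t` in reduced units.
#'
#' @param n_replicas number of independent beads.
#' @param duration total time (tau0).
#' @param dt time step.
#' @param n_record number of equally spaced recording times.
#' @param seed integer seed.
#' @return tibble with columns `replica`, `time`, `x`, `y`, `z`
#'   (displacements from the origin).
#' @export
simulate_free_bead <- function(n_replicas = 200, duration = 1, dt = 1e-4,
                               n_record = 10, seed = 1L) {
  m <- free_bead_cpp(as.integer(n_replicas), round(duration / dt),
                     dt, as.integer(n_record), as.double(seed))
  tibble::tibble(
    replica = rep(seq_len(n_replicas), each = n_record),
    time = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4]
  )
}
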