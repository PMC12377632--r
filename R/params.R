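#' Model parameters for the tethered bead-spring chain
#'
#' Collects every reduced-unit constant of the chain model: lengths are
#' measured in units of the bond length `a`, energies in units of `kBT`,
#' and times in units of `tau0 = zeta a^2 / kBT` (the time a free bead
#' needs to diffuse one bond length).  The drag coefficient, temperature
#' and Boltzmann constant never appear explicitly; they enter only through
#' these reduced units.
#'
#' Defaults are the conditions used throughout the package: a chain of
#' `N = 50` segments (51 beads, bead 0 tethered at `(0, 0, 1)`), stiff
#' harmonic springs `spring_k = 1000` so the chain is nearly inextensible,
#' a soft repulsive wall of strength `wall_eps = 1` at `z = 0`, and time
#' step `dt = 1e-4`.  The crowding (PEG) attraction between beads has
#' amplitude `alpha` (kBT), decay length `decay_d` (units of `a`) and is
#' proportional to the PEG concentration `peg_pct` given as a bare percent
#' number (3 for 3%); the pair sum is truncated at contour separation
#' `neighbor_cutoff`.
#'
#' @param n_segments integer number of springs N (beads are `0..N`).
#' @param spring_k reduced spring constant (kBT/a^2).
#' @param wall_eps reduced wall strength (kBT).
#' @param alpha crowding attraction amplitude (kBT); 0 disables it.
#' @param decay_d decay length of the crowding attraction (units of a).
#' @param peg_pct PEG concentration as a percent number (e.g. 3, 5).
#' @param neighbor_cutoff maximum contour separation |n - n'| included in
#'   the crowding pair sum.
#' @param peclet Peclet number `Pe` (dimensionless shear rate per bead).
#' @param dt integration time step (tau0 units).
#' @param z_floor abort threshold for bead height; reaching it means the
#'   explicit scheme became unstable.
#'
#' @return an object of class `"model_params"` (a named list).
#' @examples
#' p <- model_params()
#' p$spring_k
#' @export
model_params <- function(n_segments = 50, spring_k = 1000, wall_eps = 1,
                         alpha = 0, decay_d = 1, peg_pct = 0,
                         neighbor_cutoff = 5, peclet = 0, dt = 1e-4,
                         z_floor = 1e-3) {
  p <- list(
    n_segments = as.integer(n_segments), spring_k = spring_k,
    wall_eps = wall_eps, alpha = alpha, decay_d = decay_d,
    peg_pct = peg_pct, neighbor_cutoff = as.integer(neighbor_cutoff),
    peclet = peclet, dt = dt, z_floor = z_floor, bond_a = 1
  )
  class(p) <- "model_params"
  validate_model_params(p)
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$n_segments < 1) stop("n_segments must be >= 1")
  if (p$spring_k <= 0) stop("spring_k must be > 0")
  if (p$wall_eps < 0) stop("wall_eps must be >= 0")
  if (p$alpha < 0) stop("alpha must be >= 0")
  if (p$decay_d <= 0) stop("decay_d must be > 0")
  if (p$peg_pct < 0) stop("peg_pct must be >= 0")
  if (p$neighbor_cutoff < 1) stop("neighbor_cutoff must be >= 1")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$spring_k * p$dt > 0.5) {
    stop("unstable configuration: spring_k * dt = ",
         format(p$spring_k * p$dt),
         " exceeds 0.5; the explicit scheme would blow up")
  }
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> tethered bead-spring chain (reduced units)\n")
  cat(sprintf("  N = %d segments, spring_k = %g kBT/a^2, wall_eps = %g kBT\n",
              x$n_segments, x$spring_k, x$wall_eps))
  cat(sprintf("  crowding: alpha = %g kBT, D = %g a, [PEG] = %g%%, cutoff %d\n",
              x$alpha, x$decay_d, x$peg_pct, x$neighbor_cutoff))
  cat(sprintf("  flow: Pe = %g; dt = %g tau0\n", x$peclet, x$dt))
  invisible(x)
}

#' Read or write model parameters as a flat JSON config file
#'
#' Keys are the `model_params()` argument names; keys absent from the file
#' take the standard defaults.
#'
#' @param path file path.
#' @return `read_params_config()` returns a `model_params` object;
#'   `write_params_config()` returns `path` invisibly.
#' @export
read_params_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(model_params, cfg)
}

#' @rdname read_params_config
#' @param params a `model_params` object.
#' @export
write_params_config <- function(params, path) {
  validate_model_params(params)
  keep <- intersect(names(params), names(formals(model_params)))
  jsonlite::write_json(params[keep], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Initial chain conformations
#'
#' Builds a chain state with bead 0 tethered at `(0, 0, 1)`:
#' `"extended_x"` places bead n at `(n, 0, 1)` (fully stretched along the
#' flow direction), `"extended_z"` at `(0, 0, 1 + n)` (perpendicular to
#' the surface).  All bonds have length 1.
#'
#' @param kind `"extended_x"` or `"extended_z"`.
#' @param params a [model_params()] object.
#' @return a `chain_state`: tibble with columns `bead`, `x`, `y`, `z` and
#'   a `time` attribute (tau0 units).
#' @examples
#' init_conformation("extended_x", model_params(n_segments = 5))
#' @export
init_conformation <- function(kind = c("extended_x", "extended_z"), params) {
  kind <- match.arg(kind)
  n <- 0:params$n_segments
  pos <- switch(kind,
    extended_x = cbind(x = n, y = 0 * n, z = 1 + 0 * n),
    extended_z = cbind(x = 0 * n, y = 0 * n, z = 1 + n)
  )
  chain_state(pos, time = 0)
}

#' Construct a chain state
#'
#' @param positions numeric (N+1) x 3 matrix or data frame of bead
#'   coordinates in units of `a`; row 1 is the tethered bead and must sit
#'   at `(0, 0, 1)`.
#' @param time simulation clock (tau0 units).
#' @return a tibble of class `"chain_state"` with columns `bead`
#'   (`0..N`), `x`, `y`, `z`.
#' @export
chain_state <- function(positions, time = 0) {
  pos <- as.matrix(positions)
  storage.mode(pos) <- "double"
  stopifnot(ncol(pos) == 3, nrow(pos) >= 2)
  if (any(!is.finite(pos))) stop("chain_state: non-finite coordinates")
  if (max(abs(pos[1, ] - c(0, 0, 1))) > 1e-12) {
    stop("chain_state: bead 0 must be tethered at (0, 0, 1)")
  }
  if (any(pos[, 3] < -1)) {
    stop("chain_state: bead below z = -1 (deeper than one bond length)")
  }
  out <- tibble::tibble(bead = 0:(nrow(pos) - 1),
                        x = pos[, 1], y = pos[, 2], z = pos[, 3])
  attr(out, "time") <- time
  class(out) <- c("chain_state", class(out))
  out
}

state_matrix <- function(state) {
  cbind(state$x, state$y, state$z)
}

#' Sample a random coil conformation
#'
#' Draws a freely-jointed chain from the tether: unit bond vectors
#' uniform on the sphere, with bead heights reflected at the surface
#' (`z -> |z|`).  For the in-plane coordinates this is exactly the
#' ideal-chain equilibrium ensemble, so equilibrium protocols started
#' here need only a short burn-in to relax bond lengths and the
#' wall-proximal height distribution, instead of waiting out the slow
#' global relaxation from a stretched start.
#'
#' @param params a [model_params()].
#' @param seed integer seed (uses its own stream; R's RNG state is left
#'   untouched).
#' @return a [chain_state()].
#' @export
sample_coil_state <- function(params, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  n <- params$n_segments
  # uniform unit vectors: z ~ U(-1, 1), azimuth uniform
  cz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(1 - cz^2)
  steps <- cbind(sz * cos(phi), sz * sin(phi), cz)
  pos <- rbind(c(0, 0, 1), sweep(apply(steps, 2, cumsum), 2, c(0, 0, 1), "+"))
  if (n == 1) pos <- rbind(c(0, 0, 1), steps + c(0, 0, 1))
  pos[, 3] <- pmax(abs(pos[, 3]), 2 * params$z_floor)
  chain_state(pos)
}
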