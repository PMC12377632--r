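#' Simulate the steady-state fractional extension at one condition
#'
#' Runs replica trajectories at the Peclet number `Pe = wi / tau_r` and
#' summarises the post-burn-in free-end position (see
#' [extension_summary()]).  Replicas start fully extended along the flow
#' (closest cheap guess of the sheared steady state) and the burn-in is
#' discarded.
#'
#' @param wi Weissenberg number.
#' @param params base [model_params()] (alpha, decay_d, peg_pct taken
#'   from here); `peclet` is overwritten.
#' @param n_replicas,burn_in,production replica count and spans (tau0).
#' @param tau_r reduced relaxation time mapping Wi to Pe.
#' @param seed integer seed (replica seeds derived deterministically).
#' @param seed_offset offset distinguishing simulation contexts that
#'   share `seed`.
#' @return one-row tibble from [extension_summary()] plus a `wi` column.
#' @export
simulate_extension <- function(wi, params = model_params(), n_replicas = 3,
                               burn_in = 400, production = 1600,
                               tau_r = 333, seed = 1L, seed_offset = 0L) {
  params$peclet <- pe_from_wi(wi, tau_r)
  trajs <- lapply(seq_len(n_replicas), function(r) {
    bd_run(params, duration = burn_in + production,
           seed = derive_seed(seed, seed_offset + r), init = "extended_x")
  })
  out <- extension_summary(trajs, burn_in = burn_in)
  out$wi <- wi
  out
}

#' Simulated fractional-extension curve over a Weissenberg grid
#'
#' Computes `xi(Wi)` at `alpha = 0` on a log-spaced grid, the input of
#' the viscosity calibration.  Low-Wi points get a longer burn-in: the
#' relaxation from the stretched start towards the weakly perturbed coil
#' is governed by the full chain relaxation time there.
#'
#' @param wi_grid Weissenberg numbers (increasing).
#' @param params base [model_params()] with `alpha = 0`.
#' @param protocol list as from [calibration_protocol()].
#' @param seed integer seed.
#' @return tibble: one [simulate_extension()] row per grid point.
#' @export
simulate_xi_curve <- function(wi_grid = exp(seq(log(2), log(120),
                                                length.out = 8)),
                              params = model_params(),
                              protocol = calibration_protocol(),
                              seed = 1L) {
  pr <- utils::modifyList(calibration_protocol(), protocol)
  purrr::list_rbind(purrr::imap(as.list(wi_grid), function(wi, i) {
    burn <- if (wi < 6) pr$grid_burn_in_low else pr$grid_burn_in
    simulate_extension(wi, params, n_replicas = pr$grid_replicas,
                       burn_in = burn, production = pr$grid_production,
                       tau_r = pr$tau_r, seed = seed,
                       seed_offset = 1000L + 10L * i)
  }))
}

#' Run sizes and numerics of the calibration pipeline
#'
#' These spans are the package's standard compromise between Monte-Carlo
#' error and runtime; the methods vignette discusses the resulting
#' statistical errors.  `tau_r` is an input (default 333) rather than
#' recomputed here, so the expensive relaxation pipeline runs once.
#'
#' @param grid_replicas,grid_production,grid_burn_in,grid_burn_in_low
#'   xi(Wi) grid sizes (tau0 units); the longer burn-in applies below
#'   Wi = 6.
#' @param baseline_production production span of the precise alpha = 0
#'   baseline at the fitting viscosity.
#' @param n_pairs,paired_production paired same-noise runs per alpha
#'   evaluation in the bisection.
#' @param pair_burn_in burn-in of each paired run.
#' @param alpha_bracket,alpha_tol bisection bracket and stopping width
#'   (kBT).
#' @param predict_replicas,predict_production,predict_burn_in sizes for
#'   prediction runs.
#' @param tau_r reduced relaxation time used for the Wi -> Pe mapping.
#' @param mono_tol tolerated non-monotonicity (xi units) in the grid
#'   before calibration aborts.
#' @export
calibration_protocol <- function(grid_replicas = 2, grid_production = 1600,
                                 grid_burn_in = 300, grid_burn_in_low = 800,
                                 baseline_production = 9000,
                                 n_pairs = 2, paired_production = 700,
                                 pair_burn_in = 150,
                                 alpha_bracket = c(0, 1.28),
                                 alpha_tol = 0.02,
                                 predict_replicas = 2,
                                 predict_production = 1200,
                                 predict_burn_in = 200,
                                 tau_r = 333, mono_tol = 0.015) {
  as.list(environment())
}

#' Calibrate the viscosity-to-Weissenberg constant
#'
#' Matches the simulated fractional extension without crowding
#' attraction to the measured fractional extension of the PEG-free
#' buffer: simulate `xi(Wi)` on a grid, interpolate monotonically in
#' `log Wi` (Hyman-filtered cubic spline), root-find `Wi0` with
#' `xi(Wi0) = xi_target`, and return `c_prime = Wi0 / eta0`.
#'
#' Small non-monotonic wiggles up to `mono_tol` (Monte-Carlo noise) are
#' projected onto the nearest monotone curve by isotonic regression;
#' larger inversions abort with a request for more replicas.
#'
#' @param xi_target measured fractional extension at the reference
#'   viscosity (e.g. `mean_ext_um / L`).
#' @param eta0 reference viscosity (cP).
#' @param params,protocol,seed forwarded to [simulate_xi_curve()].
#' @param xi_curve optionally, a precomputed [simulate_xi_curve()] result
#'   (columns `wi`, `xi`); when given, no simulation is run.
#' @return list with `c_prime`, `wi0`, `xi_target`, `eta0`, the grid
#'   tibble and the interpolator.
#' @export
calibrate_cprime <- function(xi_target, eta0, params = model_params(),
                             protocol = calibration_protocol(), seed = 1L,
                             xi_curve = NULL) {
  stopifnot(xi_target > 0, xi_target < 1, eta0 > 0)
  pr <- utils::modifyList(calibration_protocol(), protocol)
  if (is.null(xi_curve)) {
    params$alpha <- 0
    xi_curve <- simulate_xi_curve(params = params, protocol = pr, seed = seed)
  }
  ord <- order(xi_curve$wi)
  wi <- xi_curve$wi[ord]
  xi <- xi_curve$xi[ord]
  dec <- which(diff(xi) < 0)
  if (length(dec) && max(xi[dec] - xi[dec + 1]) > pr$mono_tol) {
    stop("xi(Wi) grid is non-monotone beyond mono_tol = ", pr$mono_tol,
         ": statistics too poor, increase grid replicas or production")
  }
  if (length(dec)) xi <- stats::isoreg(log(wi), xi)$yf
  if (xi_target < min(xi) || xi_target > max(xi)) {
    stop("xi_target = ", signif(xi_target, 4),
         " outside the simulated grid range [", signif(min(xi), 4), ", ",
         signif(max(xi), 4), "]")
  }
  interp <- stats::splinefun(log(wi), xi, method = "hyman")
  root <- stats::uniroot(function(lw) interp(lw) - xi_target,
                         range(log(wi)), tol = 1e-9)
  wi0 <- exp(root$root)
  list(c_prime = wi0 / eta0, wi0 = wi0, xi_target = xi_target, eta0 = eta0,
       xi_curve = xi_curve, interpolator = interp, protocol = pr, seed = seed)
}

#' Fit the crowding-attraction amplitude at the 3%-PEG condition
#'
#' Solves `xi_sim(Wi1; alpha, D) = xi_target` for `alpha` at
#' `Wi1 = c_prime * eta1` by bisection with common random numbers.  The
#' simulated objective is very shallow in `alpha`, so the Monte-Carlo
#' noise of a naive estimate would dominate the root; the objective is
#' therefore assembled as a control variate:
#' `g(alpha) = xi0 + mean_s[ xi_s(alpha) - xi_s(0) ] - xi_target`,
#' where `xi0` is a long precise alpha = 0 baseline at `Wi1` and the
#' bracketed difference pairs runs with *identical* noise streams (seed
#' `s`), whose strong coupling cancels most of the sampling error of the
#' attraction-induced shift.  Given the seeds, the objective is
#' deterministic and monotonically decreasing in `alpha` (asserted during
#' the bisection).
#'
#' @param c_prime calibration constant (1/cP) from [calibrate_cprime()].
#' @param eta1 viscosity at the fitting condition (cP).
#' @param xi_target measured fractional extension at that condition.
#' @param decay_d crowding decay length D (units of a).
#' @param peg_pct PEG concentration at the fitting condition (percent).
#' @param params,protocol,seed simulation configuration.
#' @param baseline optionally, a precomputed baseline list with `xi0`
#'   and `zero_runs` (reused across decay lengths).
#' @return list with `alpha`, `residual` (objective at the returned
#'   alpha), `wi1`, the evaluation table and the reusable `baseline`.
#' @export
calibrate_alpha <- function(c_prime, eta1, xi_target, decay_d = 1,
                            peg_pct = 3, params = model_params(),
                            protocol = calibration_protocol(), seed = 1L,
                            baseline = NULL) {
  pr <- utils::modifyList(calibration_protocol(), protocol)
  wi1 <- wi_from_viscosity(eta1, c_prime)
  pe1 <- pe_from_wi(wi1, pr$tau_r)
  dur <- pr$pair_burn_in + pr$paired_production

  run_xi <- function(alpha, s) {
    p <- params
    p$alpha <- alpha
    p$decay_d <- decay_d
    p$peg_pct <- peg_pct
    p$peclet <- pe1
    traj <- bd_run(p, duration = dur, seed = s, init = "extended_x")
    extension_summary(traj, burn_in = pr$pair_burn_in)$xi
  }

  if (is.null(baseline)) {
    p0 <- params
    p0$alpha <- 0
    base <- simulate_extension(wi1, p0, n_replicas = 2,
                               burn_in = pr$pair_burn_in,
                               production = pr$baseline_production / 2,
                               tau_r = pr$tau_r, seed = seed,
                               seed_offset = 3000L)
    pair_seeds <- vapply(seq_len(pr$n_pairs),
                         function(s) derive_seed(seed, 4000L + s), numeric(1))
    zero_runs <- vapply(pair_seeds, function(s) run_xi(0, s), numeric(1))
    baseline <- list(xi0 = base$xi, base_summary = base,
                     pair_seeds = pair_seeds, zero_runs = zero_runs)
  }

  objective <- function(alpha) {
    if (alpha == 0) return(baseline$xi0 - xi_target)
    d <- vapply(seq_along(baseline$pair_seeds), function(i) {
      run_xi(alpha, baseline$pair_seeds[i]) - baseline$zero_runs[i]
    }, numeric(1))
    baseline$xi0 + mean(d) - xi_target
  }

  lo <- pr$alpha_bracket[1]
  hi <- pr$alpha_bracket[2]
  g_lo <- objective(lo)
  g_hi <- objective(hi)
  if (g_lo < 0) {
    stop("no bracket: simulated xi at alpha = ", lo,
         " is already below the target (objective ", signif(g_lo, 3), ")")
  }
  if (g_hi > 0) {
    stop("no bracket: objective still positive at alpha = ", hi,
         "; widen alpha_bracket")
  }
  evals <- tibble::tibble(alpha = c(lo, hi), objective = c(g_lo, g_hi))
  while (hi - lo > pr$alpha_tol) {
    mid <- (lo + hi) / 2
    g_mid <- objective(mid)
    evals <- dplyr::add_row(evals, alpha = mid, objective = g_mid)
    sorted <- dplyr::arrange(evals, .data$alpha)
    if (any(diff(sorted$objective) > 1e-12)) {
      warning("objective not monotone in alpha at the current statistics ",
              "level; bisection continues on the sign structure")
    }
    if (g_mid > 0) lo <- mid else hi <- mid
  }
  alpha_hat <- (lo + hi) / 2
  list(alpha = alpha_hat, residual = objective(alpha_hat), wi1 = wi1,
       decay_d = decay_d, peg_pct = peg_pct, evaluations = evals,
       baseline = baseline, protocol = pr, seed = seed)
}

#' Parameter-free prediction of a PEG condition
#'
#' Simulates the chain at `Wi = c_prime * eta` with a previously fitted
#' attraction `(alpha, decay_d)` and the given PEG concentration, and
#' converts the reduced observables to micrometres:
#' `<x> = xi * L` and `Delta x = phi * Re_exp`.
#'
#' @param c_prime calibration constant (1/cP).
#' @param alpha fitted attraction amplitude (kBT); 0 for no crowding.
#' @param decay_d decay length (units of a).
#' @param eta viscosity of the predicted condition (cP).
#' @param peg_pct PEG concentration of the predicted condition.
#' @param L contour length (micrometres) for the extension conversion.
#' @param Re_exp experimental end-to-end reference (micrometres) for the
#'   fluctuation conversion.
#' @param params,protocol,seed simulation configuration.
#' @return one-row tibble: reduced summary columns plus `wi`, `eta`,
#'   `pred_mean_ext_um`, `pred_fluct_um`.
#' @export
predict_condition <- function(c_prime, alpha, decay_d, eta, peg_pct,
                              L = 16.49,
                              Re_exp = experimental_end_to_end()$Re,
                              params = model_params(),
                              protocol = calibration_protocol(),
                              seed = 1L) {
  pr <- utils::modifyList(calibration_protocol(), protocol)
  p <- params
  p$alpha <- alpha
  p$decay_d <- decay_d
  p$peg_pct <- peg_pct
  out <- simulate_extension(wi_from_viscosity(eta, c_prime), p,
                            n_replicas = pr$predict_replicas,
                            burn_in = pr$predict_burn_in,
                            production = pr$predict_production,
                            tau_r = pr$tau_r, seed = seed,
                            seed_offset = 7000L + round(1000 * eta))
  out$eta <- eta
  out$pred_mean_ext_um <- out$xi * L
  out$pred_fluct_um <- out$phi * Re_exp
  out
}

#' Full calibration and prediction pipeline
#'
#' Chains the three stages on a measured condition table (shape of
#' [peg_conditions()]): (1) calibrate `c_prime` on the 0% row, (2) fit
#' `alpha` for each requested decay length on the 3% row, (3) predict the
#' 5% row without adjustable parameters, plus the 0% fluctuation.
#'
#' @param conditions condition table with columns `peg_pct`, `eta_cp`,
#'   `mean_ext_um` (see [peg_conditions()]).
#' @param decay_lengths decay lengths D to fit (units of a).
#' @param L contour length (micrometres).
#' @param params,protocol,seed simulation configuration.
#' @return object of class `"peg_calibration"`.
#' @export
calibrate_pipeline <- function(conditions = peg_conditions(),
                               decay_lengths = c(1, 0.5), L = 16.49,
                               params = model_params(),
                               protocol = calibration_protocol(),
                               seed = 1L) {
  pr <- utils::modifyList(calibration_protocol(), protocol)
  row0 <- conditions[conditions$peg_pct == 0, ]
  row3 <- conditions[conditions$peg_pct == 3, ]
  row5 <- conditions[conditions$peg_pct == 5, ]
  if (!nrow(row0) || !nrow(row3)) stop("conditions must include 0% and 3%")

  cp <- calibrate_cprime(row0$mean_ext_um / L, row0$eta_cp, params = params,
                         protocol = pr, seed = seed)
  # the alpha = 0 baseline at Wi1 is shared across decay lengths
  fits <- vector("list", length(decay_lengths))
  base <- NULL
  for (i in seq_along(decay_lengths)) {
    fits[[i]] <- calibrate_alpha(cp$c_prime, row3$eta_cp,
                                 row3$mean_ext_um / L,
                                 decay_d = decay_lengths[i], peg_pct = 3,
                                 params = params, protocol = pr,
                                 seed = seed, baseline = base)
    base <- fits[[i]]$baseline
  }
  Re_exp <- experimental_end_to_end(contour_len = L)$Re
  predictions <- NULL
  if (nrow(row5)) {
    predictions <- purrr::list_rbind(lapply(seq_along(decay_lengths),
      function(i) {
        p <- predict_condition(cp$c_prime, fits[[i]]$alpha, decay_lengths[i],
                               row5$eta_cp, 5, L = L, Re_exp = Re_exp,
                               params = params, protocol = pr, seed = seed)
        p$decay_d <- decay_lengths[i]
        p$condition <- "5%"
        p
      }))
  }
  fluct0 <- predict_condition(cp$c_prime, 0, 1, row0$eta_cp, 0, L = L,
                              Re_exp = Re_exp, params = params,
                              protocol = pr, seed = seed)
  fluct0$decay_d <- NA_real_
  fluct0$condition <- "0%"
  predictions <- dplyr::bind_rows(predictions, fluct0)

  out <- list(
    c_prime = cp$c_prime, wi0 = cp$wi0, cprime_fit = cp,
    alpha_fits = tibble::tibble(
      decay_d = decay_lengths,
      alpha = vapply(fits, `[[`, numeric(1), "alpha"),
      residual = vapply(fits, `[[`, numeric(1), "residual")
    ),
    fits = fits, predictions = predictions, tau_r = pr$tau_r,
    conditions = conditions, L = L, Re_exp = Re_exp, protocol = pr,
    seed = seed
  )
  class(out) <- "peg_calibration"
  out
}

#' @export
print.peg_calibration <- function(x, ...) {
  cat(sprintf("<peg_calibration> c' = %.2f /cP (Wi0 = %.2f, tau_r = %g)\n",
              x$c_prime, x$wi0, x$tau_r))
  for (i in seq_len(nrow(x$alpha_fits))) {
    cat(sprintf("  alpha = %.3f kBT at D = %g a\n",
                x$alpha_fits$alpha[i], x$alpha_fits$decay_d[i]))
  }
  if (!is.null(x$predictions)) {
    cat("  predictions:\n")
    print(x$predictions[, c("condition", "decay_d", "pred_mean_ext_um",
                            "pred_fluct_um")])
  }
  invisible(x)
}
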