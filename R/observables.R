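#' Free-end time series of a trajectory
#'
#' Extracts the coordinates of bead N per frame; `x` is measured from the
#' tether at `x = 0`, and `(x, y)` is the planar projection `rho` of the
#' end-to-end vector used by the relaxation analysis.
#'
#' @param traj a [bd_run()] trajectory.
#' @return tibble with columns `time`, `x`, `y`, `z` (reduced units).
#' @export
end_series <- function(traj) {
  if (!inherits(traj, "bd_trajectory")) stop("not a bd_trajectory")
  if (length(traj$times) == 0) stop("empty trajectory")
  tibble::tibble(time = traj$times, x = traj$end[, 1], y = traj$end[, 2],
                 z = traj$end[, 3])
}

#' Autocorrelation of the planar end vector
#'
#' Estimates `C(t') = < rho(t) . rho(t + t') >` for the planar projection
#' `rho = (x, y)` of the chain end by time-averaging the dot product over
#' all overlapping pairs, with no mean subtraction (`<rho> = 0` by
#' symmetry at equilibrium).  When several replicas are given their
#' estimates are averaged lag by lag.
#'
#' @param series a tibble with columns `time`, `x`, `y` (see
#'   [end_series()]), or a list of such tibbles (replicas).  Times must be
#'   equally spaced.
#' @param max_lag largest lag, in the units of the `time` column.
#' @return tibble with columns `lag`, `C`.
#' @export
rho_autocorrelation <- function(series, max_lag) {
  if (!is.data.frame(series)) {
    acfs <- lapply(series, rho_autocorrelation, max_lag = max_lag)
    out <- acfs[[1]]
    out$C <- rowMeans(do.call(cbind, lapply(acfs, `[[`, "C")))
    return(out)
  }
  n <- nrow(series)
  if (n < 2) stop("series too short for autocorrelation")
  dtau <- series$time[2] - series$time[1]
  k_max <- floor(max_lag / dtau + 1e-9)
  if (k_max >= n) stop("max_lag exceeds the series span")
  x <- series$x
  y <- series$y
  C <- vapply(0:k_max, function(k) {
    i <- seq_len(n - k)
    mean(x[i] * x[i + k] + y[i] * y[i + k])
  }, numeric(1))
  tibble::tibble(lag = (0:k_max) * dtau, C = C)
}

#' Least-squares single-exponential fit
#'
#' Fits `A * exp(-t / tau)` to a curve by unweighted least squares on the
#' linear scale, restricted to a lag window.  The amplitude is profiled
#' out in closed form for each candidate `tau`, leaving a one-dimensional
#' minimisation solved with [stats::optimize()]; this is exactly ordinary
#' nonlinear least squares for this model, with no iterative-start failure
#' mode.  (A log-linear regression would weight the noisy tail very
#' differently; the linear-scale fit is the one used throughout the
#' package.)
#'
#' @param curve tibble with columns `lag` (or `time`) and `C` (or
#'   `value`).
#' @param window numeric length-2: fit window in lag units.
#' @return list with `amplitude`, `tau`, `rss` (residual sum of squares)
#'   and `n` (points fitted).
#' @export
fit_single_exponential <- function(curve, window = c(200, 2000)) {
  lag <- curve[[intersect(c("lag", "time"), names(curve))[1]]]
  val <- curve[[intersect(c("C", "value"), names(curve))[1]]]
  keep <- lag >= window[1] & lag <= window[2] & is.finite(val)
  if (sum(keep) < 3) stop("fit window contains fewer than 3 points")
  t <- lag[keep]
  c_ <- val[keep]
  rss_of <- function(log_tau) {
    e <- exp(-t / exp(log_tau))
    a <- sum(c_ * e) / sum(e * e)
    sum((c_ - a * e)^2)
  }
  # a priori identifiable range: a decay time far below the window start
  # or beyond the window end cannot be resolved by data on this window
  opt <- stats::optimize(rss_of,
                         interval = log(c(max(window[1] / 10, 1e-3),
                                          1.2 * window[2])),
                         tol = 1e-10)
  tau <- exp(opt$minimum)
  e <- exp(-t / tau)
  a <- sum(c_ * e) / sum(e * e)
  if (!is.finite(a) || !is.finite(tau) || tau <= 0) {
    stop("single-exponential fit failed: tau = ", tau, ", amplitude = ", a)
  }
  list(amplitude = a, tau = tau, rss = opt$objective, n = length(t))
}

#' Longest relaxation time of the tethered chain
#'
#' Estimates the reduced longest relaxation time of the chain at `Pe = 0`
#' by the two standard protocols and averages them:
#'
#' * **corr**: the decay of the equilibrium autocorrelation
#'   `C(t') = <rho(t) . rho(t + t')>` of the planar end vector;
#' * **relax**: the decay of the ensemble mean end position `<rho(t)>`
#'   back to zero, starting from a chain fully extended along x (the mean
#'   is zero in y by symmetry, so the signed x component is fitted).
#'
#' Both curves are fitted to single exponentials on the `window` lag
#' range.  The two estimators agree by Onsager's regression hypothesis;
#' their spread is reported so disagreement is visible.  Relaxation
#' simulations are run without flow and (by default) without the crowding
#' attraction.
#'
#' Two variance-reduction devices (both on by default; plain Monte-Carlo
#' estimators when switched off) keep the fitted time constants usable at
#' single-workstation run lengths:
#'
#' * equilibrium replicas are initialised from random coil conformations
#'   ([sample_coil_state()]) and their autocorrelation sampling error is
#'   removed by a control variate: a rest-length-0 Gaussian chain with
#'   the same mean-square bond length, integrated with the *same* noise
#'   stream, whose exact autocorrelation is known in closed form;
#' * relaxation replicas come in antithetic pairs (mirrored impulse
#'   streams), which cancels the leading, noise-linear fluctuation of
#'   the ensemble-mean decay almost completely.
#'
#' @param params a [model_params()]; `peclet` is forced to 0.
#' @param protocol list of run sizes and options, see
#'   [relaxation_protocol()].
#' @param seed integer seed.
#' @return object of class `"relaxation_estimate"`: list with `tau_corr`,
#'   `tau_relax`, `tau_avg = (tau_corr + tau_relax)/2`, the fitted
#'   amplitudes, the fit window, and the two fitted curves.
#' @export
estimate_relaxation_time <- function(params = model_params(),
                                     protocol = relaxation_protocol(),
                                     seed = 1L) {
  params$peclet <- 0
  validate_model_params(params)
  pr <- utils::modifyList(relaxation_protocol(), protocol)
  stride <- round(pr$stride_tau / params$dt)
  n <- params$n_segments

  eq_series <- list()
  sur_series <- list()
  for (r in seq_len(pr$n_corr)) {
    rs <- derive_seed(seed, 100 + r)
    init <- sample_coil_state(params, seed = derive_seed(seed, 900 + r))
    traj <- bd_run(params, duration = pr$corr_burn_in + pr$corr_production,
                   stride = stride, seed = rs, init = init)
    s <- end_series(traj)
    eq_series[[r]] <- s[s$time >= pr$corr_burn_in, ]
    if (pr$control_variate) {
      ig <- sample_gaussian_chain_state(n, dt = params$dt,
                                        seed = derive_seed(seed, 950 + r))
      sg <- run_gaussian_chain(n, pr$corr_burn_in + pr$corr_production,
                               stride, rs, ig, dt = params$dt)
      sur_series[[r]] <- sg[sg$time >= pr$corr_burn_in, ]
    }
  }
  acf_curve <- rho_autocorrelation(eq_series, max_lag = pr$window[2])
  if (pr$control_variate) {
    acf_sur <- rho_autocorrelation(sur_series, max_lag = pr$window[2])
    acf_exact <- gaussian_chain_acf(n, acf_sur$lag, dt = params$dt)
    acf_curve$C <- acf_curve$C - (acf_sur$C - acf_exact$C)
  }
  fit_c <- fit_single_exponential(acf_curve, pr$window)

  relax_xy <- list()
  for (r in seq_len(pr$n_relax_pairs)) {
    rs <- derive_seed(seed, 500 + r)
    relax_xy[[2 * r - 1]] <- end_series(
      bd_run(params, duration = pr$relax_duration, stride = stride,
             seed = rs, init = "extended_x"))
    relax_xy[[2 * r]] <- end_series(
      bd_run(params, duration = pr$relax_duration, stride = stride,
             seed = if (pr$antithetic) rs else derive_seed(seed, 700 + r),
             init = "extended_x", antithetic = pr$antithetic))
  }
  mean_x <- rowMeans(do.call(cbind, lapply(relax_xy, `[[`, "x")))
  relax_curve <- tibble::tibble(lag = relax_xy[[1]]$time, C = mean_x)
  fit_r <- fit_single_exponential(relax_curve, pr$window)

  out <- list(
    tau_corr = fit_c$tau, tau_relax = fit_r$tau,
    tau_avg = (fit_c$tau + fit_r$tau) / 2,
    amp_corr = fit_c$amplitude, amp_relax = fit_r$amplitude,
    fit_window = pr$window,
    curves = list(corr = acf_curve, relax = relax_curve),
    eq_series = eq_series,
    protocol = pr, seed = seed, params = params
  )
  class(out) <- "relaxation_estimate"
  out
}

#' Default run sizes for [estimate_relaxation_time()]
#'
#' @param n_corr,corr_burn_in,corr_production equilibrium (autocorrelation)
#'   replicas and lengths, tau0 units.
#' @param n_relax_pairs,relax_duration relaxation-to-equilibrium replica
#'   pairs (each pair shares a seed; the partner has the mirrored noise
#'   stream when `antithetic` is on).
#' @param stride_tau recording interval (tau0).
#' @param window exponential fit window (tau0).
#' @param control_variate subtract the paired Gaussian-chain surrogate's
#'   autocorrelation sampling error (see [estimate_relaxation_time()]).
#' @param antithetic pair relaxation replicas with mirrored noise.
#' @export
relaxation_protocol <- function(n_corr = 6, corr_burn_in = 150,
                                corr_production = 4000, n_relax_pairs = 4,
                                relax_duration = 2050, stride_tau = 1,
                                window = c(200, 2000),
                                control_variate = TRUE, antithetic = TRUE) {
  list(n_corr = n_corr, corr_burn_in = corr_burn_in,
       corr_production = corr_production, n_relax_pairs = n_relax_pairs,
       relax_duration = relax_duration, stride_tau = stride_tau,
       window = window, control_variate = control_variate,
       antithetic = antithetic)
}

#' @export
print.relaxation_estimate <- function(x, ...) {
  cat(sprintf("<relaxation_estimate> tau_corr = %.1f, tau_relax = %.1f, tau_avg = %.1f tau0\n",
              x$tau_corr, x$tau_relax, x$tau_avg))
  cat(sprintf("  fit window [%g, %g] tau0; amplitudes %.2f / %.2f\n",
              x$fit_window[1], x$fit_window[2], x$amp_corr, x$amp_relax))
  invisible(x)
}

#' Steady-state extension summary of the free end
#'
#' Pools the post-burn-in free-end x position across replicas: the mean
#' gives the extension `<x>`, the standard deviation the fluctuation
#' `Delta x` (both in units of a), the fractional extension
#' `xi = <x> / L` and the normalised fluctuation `phi = Delta x / Re`
#' with the supplied references.  The between-replica scatter of the mean
#' is reported as a standard error.
#'
#' @param trajs a [bd_run()] trajectory or list of replicas.
#' @param burn_in discarded initial span (tau0).
#' @param L contour length reference for `xi` (units of a for reduced
#'   output; pass `n_segments` for the model chain).
#' @param Re end-to-end reference for `phi` (units of a; see
#'   [model_end_to_end()]).
#' @return one-row tibble: `mean_x`, `sd_x`, `xi`, `phi`, `se_mean_x`,
#'   `n_replicas`, `burn_in`, `production`.
#' @export
extension_summary <- function(trajs, burn_in,
                              L = NULL, Re = NULL) {
  if (inherits(trajs, "bd_trajectory")) trajs <- list(trajs)
  if (!length(trajs)) stop("no trajectories supplied")
  n <- trajs[[1]]$params$n_segments
  if (is.null(L)) L <- n
  if (is.null(Re)) Re <- model_end_to_end(trajs[[1]]$params)
  xs <- lapply(trajs, function(tr) {
    s <- end_series(tr)
    keep <- s$time >= burn_in
    if (!any(keep)) stop("burn_in >= trajectory duration")
    s$x[keep]
  })
  pooled <- unlist(xs)
  rep_means <- vapply(xs, mean, numeric(1))
  tibble::tibble(
    mean_x = mean(pooled),
    sd_x = stats::sd(pooled),
    xi = mean(pooled) / L,
    phi = stats::sd(pooled) / Re,
    se_mean_x = if (length(xs) > 1) {
      stats::sd(rep_means) / sqrt(length(xs))
    } else NA_real_,
    n_replicas = length(xs),
    burn_in = burn_in,
    production = sum(vapply(xs, length, numeric(1))) *
      (trajs[[1]]$times[2] - trajs[[1]]$times[1])
  )
}

#' Ideal-chain end-to-end reference of the model chain
#'
#' Root-mean-square end-to-end distance of the free chain at equilibrium:
#' `sqrt(N)` in units of a for N independent unit bonds (the stiff-spring
#' chain is freely jointed to an excellent approximation).  Used to
#' normalise the simulated fluctuation `phi = Delta x / Re`.
#'
#' @param params a [model_params()].
#' @return scalar, units of a.
#' @export
model_end_to_end <- function(params) {
  sqrt(params$n_segments)
}

#' End-to-end reference of the experimental DNA from Kuhn statistics
#'
#' Worm-like-chain statistics: Kuhn length `bK = 2 lP`, number of Kuhn
#' segments `NK = L / bK` (unrounded), and
#' `Re = sqrt(NK) * bK = sqrt(L * bK)`.
#'
#' @param persistence_len persistence length (micrometres).
#' @param contour_len contour length (micrometres).
#' @return list with `bK`, `NK`, `Re` (micrometres).
#' @examples
#' experimental_end_to_end(0.05, 16.49)$Re # 1.284 um
#' @export
experimental_end_to_end <- function(persistence_len = 0.05,
                                    contour_len = 16.49) {
  stopifnot(persistence_len > 0, contour_len > 0)
  bK <- 2 * persistence_len
  NK <- contour_len / bK
  list(bK = bK, NK = NK, Re = sqrt(contour_len * bK))
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, i) {
  (1103515245 * (as.double(seed) %% 65536) + 12345 + 790151 * i) %% 2147483647
}
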