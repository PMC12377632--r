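#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' For end-only recordings: free-end extension `x` versus time.  For
#' full recordings: chain snapshots in the x-z plane at a handful of
#' times, the classic flow-stretching cartoon.
#'
#' @param object a [bd_run()] trajectory.
#' @param n_snapshots snapshots drawn for full recordings.
#' @param ... unused.
#' @export
autoplot.bd_trajectory <- function(object, n_snapshots = 6, ...) {
  if (is.null(object$frames)) {
    df <- end_series(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$x)) +
      ggplot2::geom_line(colour = "#2c7fb8") +
      ggplot2::labs(x = "time (tau0)", y = "free-end x (a)",
                    title = sprintf("Pe = %g, alpha = %g",
                                    object$params$peclet,
                                    object$params$alpha))
  } else {
    long <- as_tibble.bd_trajectory(object)
    keep <- unique(long$time[round(seq(1, length(object$times),
                                       length.out = n_snapshots))])
    ggplot2::ggplot(dplyr::filter(long, .data$time %in% keep),
                    ggplot2::aes(x = .data$x, y = .data$z,
                                 group = .data$time,
                                 colour = .data$time)) +
      ggplot2::geom_path() +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
      ggplot2::labs(x = "x (a)", y = "z (a)", colour = "time (tau0)")
  }
}

#' Plot the two relaxation-time fits
#'
#' Autocorrelation and relaxation-to-equilibrium curves with their
#' single-exponential fits over the fit window.
#'
#' @param object a [estimate_relaxation_time()] result.
#' @param ... unused.
#' @export
autoplot.relaxation_estimate <- function(object, ...) {
  cv <- dplyr::bind_rows(
    dplyr::mutate(object$curves$corr, which = "autocorrelation C(t')"),
    dplyr::mutate(object$curves$relax, which = "relaxation <x(t)>")
  )
  fit <- dplyr::bind_rows(
    tibble::tibble(which = "autocorrelation C(t')", lag = cv$lag,
                   C = object$amp_corr * exp(-cv$lag / object$tau_corr)),
    tibble::tibble(which = "relaxation <x(t)>", lag = cv$lag,
                   C = object$amp_relax * exp(-cv$lag / object$tau_relax))
  )
  win <- object$fit_window
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$lag, y = .data$C)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_line(data = dplyr::filter(fit, .data$lag >= win[1],
                                            .data$lag <= win[2]),
                       colour = "#d95f02") +
    ggplot2::geom_vline(xintercept = win, linetype = 3) +
    ggplot2::facet_wrap(~which, scales = "free_y") +
    ggplot2::labs(x = "lag / time (tau0)", y = NULL)
}

#' Plot a calibration: xi(Wi) curve, target and fitted conditions
#'
#' @param object a [calibrate_pipeline()] result.
#' @param ... unused.
#' @export
autoplot.peg_calibration <- function(object, ...) {
  grid <- object$cprime_fit$xi_curve
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$wi, y = .data$xi)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$cprime_fit$xi_target,
                        linetype = 2, colour = "#1b9e77") +
    ggplot2::geom_vline(xintercept = object$wi0, linetype = 2,
                        colour = "#1b9e77") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Wi", y = "fractional extension xi",
                  title = sprintf("c' = %.2f /cP (Wi0 = %.1f)",
                                  object$c_prime, object$wi0))
}
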