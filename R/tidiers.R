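#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a relaxation-time estimate
#'
#' One row per estimator (`corr`, `relax`) plus the averaged value, with
#' fitted amplitudes where they exist.
#'
#' @param x a [estimate_relaxation_time()] result.
#' @param ... unused.
#' @export
tidy.relaxation_estimate <- function(x, ...) {
  tibble::tibble(
    estimator = c("corr", "relax", "average"),
    tau = c(x$tau_corr, x$tau_relax, x$tau_avg),
    amplitude = c(x$amp_corr, x$amp_relax, NA_real_)
  )
}

#' @rdname tidy.relaxation_estimate
#' @export
glance.relaxation_estimate <- function(x, ...) {
  tibble::tibble(
    tau_avg = x$tau_avg,
    rel_spread = abs(x$tau_corr - x$tau_relax) / x$tau_avg,
    window_lo = x$fit_window[1], window_hi = x$fit_window[2],
    n_corr = x$protocol$n_corr, n_relax_pairs = x$protocol$n_relax_pairs,
    seed = x$seed
  )
}

#' Tidy a calibration result
#'
#' `tidy()` returns one row per calibrated parameter (`c_prime` and each
#' fitted `alpha`); `glance()` a one-row pipeline overview.
#'
#' @param x a [calibrate_pipeline()] result.
#' @param ... unused.
#' @export
tidy.peg_calibration <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "c_prime", decay_d = NA_real_,
                   estimate = x$c_prime, units = "1/cP"),
    tibble::tibble(term = "alpha", decay_d = x$alpha_fits$decay_d,
                   estimate = x$alpha_fits$alpha, units = "kBT")
  )
}

#' @rdname tidy.peg_calibration
#' @export
glance.peg_calibration <- function(x, ...) {
  tibble::tibble(
    c_prime = x$c_prime, wi0 = x$wi0, tau_r = x$tau_r,
    n_alpha_fits = nrow(x$alpha_fits),
    max_abs_residual = max(abs(x$alpha_fits$residual)),
    seed = x$seed
  )
}
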