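#' Reference measurement summary for PEG-supplemented buffers
#'
#' The bundled summary of the flow-stretching measurement campaign on
#' lambda-DNA: per PEG concentration, the rheometer-averaged buffer
#' viscosity, the ensemble mean extension of the free DNA end and its
#' fluctuation (SD of the end position), each with SD and SEM over the
#' molecule ensemble.  The 10% condition has no extension data
#' (nonspecific sticking of the DNA to the surface).  These numbers are
#' the experimental inputs of the calibration pipeline.
#'
#' @return tibble with columns `peg_pct`, `eta_cp`, `sd_eta_cp`,
#'   `mean_ext_um`, `sd_ext_um`, `sem_ext_um`, `fluct_um`, `sd_fluct_um`,
#'   `sem_fluct_um`, `n_molecules`.
#' @examples
#' peg_conditions()
#' @export
peg_conditions <- function() {
  tibble::tibble(
    peg_pct = c(0, 3, 5, 10),
    eta_cp = c(0.914, 1.675, 2.396, 5.680),
    sd_eta_cp = c(0.02, 0.05, 0.03, 0.04),
    mean_ext_um = c(11.897, 12.446, 12.554, NA),
    sd_ext_um = c(1.249, 1.545, 0.819, NA),
    sem_ext_um = c(0.126, 0.221, 0.117, NA),
    fluct_um = c(0.3966, 0.3538, 0.2652, NA),
    sd_fluct_um = c(0.1095, 0.1118, 0.0601, NA),
    sem_fluct_um = c(0.0111, 0.0160, 0.0086, NA),
    n_molecules = c(98L, 49L, 49L, NA)
  )
}

#' Reduce a rheometer sweep table to per-condition viscosities
#'
#' A rheometer sweep records replicate viscosity readings over a range of
#' shear rates.  Within a window of shear rates where the buffer is
#' Newtonian the readings are flat; this reduction averages the replicate
#' columns row-wise, keeps only rows whose shear rate falls inside
#' `window`, and reports mean and SD per condition.
#'
#' @param table data frame with a `shear_rate` column (1/s), one or more
#'   numeric replicate columns (viscosities, cP), and optionally a
#'   `peg_pct` column separating conditions.
#' @param window shear-rate window (1/s) over which to average.
#' @return tibble with `peg_pct` (if present), `mean_eta`, `sd_eta`,
#'   `n_rates`, `window_lo`, `window_hi`.
#' @export
reduce_viscosity_table <- function(table, window = c(60, 500)) {
  stopifnot(is.data.frame(table))
  if (!"shear_rate" %in% names(table)) {
    stop("table needs a 'shear_rate' column")
  }
  has_cond <- "peg_pct" %in% names(table)
  rep_cols <- setdiff(names(table), c("shear_rate", "peg_pct"))
  if (!length(rep_cols)) stop("table needs at least one replicate column")
  if (!all(vapply(table[rep_cols], is.numeric, logical(1)))) {
    stop("replicate columns must be numeric")
  }
  reduced <- table |>
    dplyr::filter(.data$shear_rate >= window[1],
                  .data$shear_rate <= window[2]) |>
    dplyr::mutate(.row_eta = rowMeans(dplyr::pick(dplyr::all_of(rep_cols))))
  if (!nrow(reduced)) stop("no shear rates inside the averaging window")
  grouped <- if (has_cond) dplyr::group_by(reduced, .data$peg_pct)
             else reduced
  dplyr::summarise(
    grouped,
    mean_eta = mean(.data$.row_eta),
    sd_eta = stats::sd(.data$.row_eta),
    n_rates = dplyr::n(),
    window_lo = window[1],
    window_hi = window[2],
    .groups = "drop"
  )
}

#' Pearson correlation between PEG concentration and viscosity
#'
#' @param conditions tibble with columns `peg_pct` and `mean_eta` (or
#'   `eta_cp`), at least 3 rows.
#' @return Pearson's r.
#' @examples
#' concentration_viscosity_correlation(peg_conditions()) # 0.976
#' @export
concentration_viscosity_correlation <- function(conditions) {
  eta_col <- intersect(c("mean_eta", "eta_cp"), names(conditions))[1]
  if (is.na(eta_col)) stop("conditions need a 'mean_eta' or 'eta_cp' column")
  x <- conditions$peg_pct
  y <- conditions[[eta_col]]
  if (length(x) < 3) stop("need at least 3 conditions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}
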