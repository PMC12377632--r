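#' Ensemble statistics over single DNA molecules
#'
#' Averages per-molecule flow-stretching statistics over an ensemble:
#' `X_bar` is the mean of the per-molecule mean extensions `<x_i>` and
#' `DX_bar` the mean of the per-molecule fluctuations `Delta x_i`, each
#' with SD and SEM (`sd / sqrt(N)`) over molecules.
#'
#' @param stats tibble of per-molecule statistics with columns
#'   `molecule_id`, `condition`, `mean_x_um`, `sd_x_um` (see
#'   [read_molecule_table()]).  All rows must share one condition.
#' @return one-row tibble: `condition`, `n_molecules`, `xbar_um`,
#'   `sd_xbar_um`, `sem_xbar_um`, `dxbar_um`, `sd_dxbar_um`,
#'   `sem_dxbar_um`.
#' @examples
#' ensemble_summary(tibble::tibble(
#'   molecule_id = 1:3, condition = "0%",
#'   mean_x_um = c(10, 12, 14), sd_x_um = c(0.3, 0.5, 0.4)
#' ))
#' @export
ensemble_summary <- function(stats) {
  if (!nrow(stats)) stop("empty molecule table")
  req <- c("condition", "mean_x_um", "sd_x_um")
  missing_cols <- setdiff(req, names(stats))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(stats$condition)) != 1) {
    stop("mixed conditions: summarise one condition at a time (got ",
         paste(unique(stats$condition), collapse = ", "), ")")
  }
  n <- nrow(stats)
  tibble::tibble(
    condition = stats$condition[1],
    n_molecules = n,
    xbar_um = mean(stats$mean_x_um),
    sd_xbar_um = stats::sd(stats$mean_x_um),
    sem_xbar_um = stats::sd(stats$mean_x_um) / sqrt(n),
    dxbar_um = mean(stats$sd_x_um),
    sd_dxbar_um = stats::sd(stats$sd_x_um),
    sem_dxbar_um = stats::sd(stats$sd_x_um) / sqrt(n)
  )
}

#' Read or write a per-molecule statistics table
#'
#' CSV with one row per DNA molecule: `molecule_id`, `condition` (a label
#' such as "0%", "3%", "5%"), `mean_x_um` and `sd_x_um` (micrometres).
#' Round trips are lossless at full double precision.
#'
#' @param path CSV file path.
#' @return a tibble of per-molecule statistics.
#' @export
read_molecule_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("molecule_id", "condition", "mean_x_um", "sd_x_um")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("molecule table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("mean_x_um", "sd_x_um")) {
    bad <- which(!is.finite(tab[[col]]))
    if (length(bad)) {
      stop("non-numeric or missing ", col, " in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (any(tab$sd_x_um < 0)) stop("sd_x_um must be >= 0")
  tab
}

#' @rdname read_molecule_table
#' @param stats tibble of per-molecule statistics.
#' @export
write_molecule_table <- function(stats, path) {
  readr::write_csv(stats, path)
  invisible(path)
}

#' Extension statistics of a single quantum-dot trace
#'
#' A flow-stretching trace starts with a flow-off segment (the average
#' probe position there marks the tether point) followed by a flow-on
#' segment.  The extension is the flow-on mean minus the flow-off mean
#' (so a constant offset of the whole trace cancels), and the
#' fluctuation is the SD of the flow-on segment.
#'
#' @param trace tibble with columns `time` (s) and `x_um`.
#' @param flow_on_window numeric length-2, time window (s) of the
#'   flow-on segment; everything strictly before it is the flow-off
#'   segment.
#' @return list with `mean_x_um` and `sd_x_um`.
#' @export
trace_stats <- function(trace, flow_on_window) {
  on <- trace$time >= flow_on_window[1] & trace$time <= flow_on_window[2]
  off <- trace$time < flow_on_window[1]
  if (!any(on) || !any(off)) {
    stop("flow-on window leaves an empty flow-on or flow-off segment")
  }
  list(mean_x_um = mean(trace$x_um[on]) - mean(trace$x_um[off]),
       sd_x_um = stats::sd(trace$x_um[on]))
}

#' Configuration of the synthetic trace generator
#'
#' @param mean_ext_um ensemble mean extension (micrometres).
#' @param sd_ext_um stationary SD of a single trace (micrometres).
#' @param molecule_sd_um SD of the molecule-level offset of the mean
#'   extension (molecule heterogeneity, micrometres).
#' @param tau_s relaxation time of the mean-reverting process (s).
#' @param frame_s frame interval (s); default the 100 ms camera exposure.
#' @param flow_off_s,flow_on_s segment durations (s).
#' @param noise_um localization noise SD added per frame (micrometres).
#' @export
synthetic_trace_config <- function(mean_ext_um = 11.897, sd_ext_um = 0.3966,
                                   molecule_sd_um = 1.249, tau_s = 0.5,
                                   frame_s = 0.1, flow_off_s = 20,
                                   flow_on_s = 60, noise_um = 0.01) {
  stopifnot(tau_s > 0, frame_s > 0, flow_off_s > 0, flow_on_s > 0,
            sd_ext_um >= 0, molecule_sd_um >= 0, noise_um >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_trace_config"
  cfg
}

#' Generate synthetic quantum-dot traces with known truth
#'
#' Emulates the statistical shape of per-molecule flow-stretching data:
#' each molecule draws a mean extension offset (heterogeneity between
#' molecules), then follows a stationary Gaussian mean-reverting
#' (Ornstein-Uhlenbeck) process around it during flow-on, sampled exactly
#' at the frame interval; the flow-off segment fluctuates around the
#' tether at 0.  Localization noise is added independently per frame.
#' The generator returns both the traces and the per-molecule truth
#' table, so estimator recovery can be tested.
#'
#' @param config a [synthetic_trace_config()].
#' @param n_molecules number of molecules.
#' @param condition condition label stored in the truth table.
#' @param seed integer seed (deterministic output).
#' @return list with `traces` (tibble: `molecule_id`, `time`, `x_um`),
#'   `truth` (per-molecule means), and `flow_on_window`.
#' @export
generate_synthetic_traces <- function(config = synthetic_trace_config(),
                                      n_molecules = 49, condition = "0%",
                                      seed = 1L) {
  cfg <- config
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  phi <- exp(-cfg$frame_s / cfg$tau_s)
  n_off <- round(cfg$flow_off_s / cfg$frame_s)
  n_on <- round(cfg$flow_on_s / cfg$frame_s)
  t_all <- (seq_len(n_off + n_on) - 1) * cfg$frame_s
  ou <- function(n, mu, sd_stat) {
    x <- numeric(n)
    x[1] <- mu + stats::rnorm(1, 0, sd_stat)
    innov <- stats::rnorm(n - 1, 0, sd_stat * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- mu + phi * (x[i - 1] - mu) + innov[i - 1]
    x
  }
  mols <- purrr::map(seq_len(n_molecules), function(m) {
    mu_m <- cfg$mean_ext_um + stats::rnorm(1, 0, cfg$molecule_sd_um)
    x_off <- ou(n_off, 0, cfg$sd_ext_um)
    x_on <- ou(n_on, mu_m, cfg$sd_ext_um)
    x <- c(x_off, x_on) + stats::rnorm(n_off + n_on, 0, cfg$noise_um)
    list(trace = tibble::tibble(molecule_id = m, time = t_all, x_um = x),
         mu = mu_m)
  })
  list(
    traces = purrr::list_rbind(purrr::map(mols, "trace")),
    truth = tibble::tibble(
      molecule_id = seq_len(n_molecules),
      condition = condition,
      true_mean_um = purrr::map_dbl(mols, "mu"),
      true_sd_um = cfg$sd_ext_um
    ),
    flow_on_window = c(cfg$flow_off_s, cfg$flow_off_s + cfg$flow_on_s),
    config = cfg, seed = seed
  )
}

#' Per-molecule statistics of a set of synthetic traces
#'
#' Applies [trace_stats()] to each molecule of a
#' [generate_synthetic_traces()] result, yielding a molecule table in the
#' [read_molecule_table()] shape.
#'
#' @param synth a [generate_synthetic_traces()] result.
#' @param condition condition label for the table.
#' @return tibble: `molecule_id`, `condition`, `mean_x_um`, `sd_x_um`.
#' @export
molecule_stats_from_traces <- function(synth, condition = "0%") {
  synth$traces |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_modify(function(df, key) {
      st <- trace_stats(df, synth$flow_on_window)
      tibble::tibble(condition = condition, mean_x_um = st$mean_x_um,
                     sd_x_um = st$sd_x_um)
    }) |>
    dplyr::ungroup()
}

#' Rank-sum comparison of two conditions (delegated)
#'
#' Thin descriptive pass-through to [stats::wilcox.test()] comparing a
#' per-molecule statistic between two condition tables; reported, never
#' re-derived.
#'
#' @param stats_a,stats_b molecule tables ([read_molecule_table()] shape).
#' @param column statistic column to compare.
#' @return tibble with the two condition labels, W and the p-value.
#' @export
compare_conditions <- function(stats_a, stats_b, column = "mean_x_um") {
  ht <- stats::wilcox.test(stats_a[[column]], stats_b[[column]])
  tibble::tibble(
    condition_a = stats_a$condition[1], condition_b = stats_b$condition[1],
    column = column, statistic = unname(ht$statistic),
    p_value = ht$p.value
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
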