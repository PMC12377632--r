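# File formats

All files are plain text. Units are stated per column; reduced units use
the bond length `a`, thermal energy `kBT` and bead diffusion time `tau0`.

## Molecule statistics table (CSV)

One row per DNA molecule (`read_molecule_table()` /
`write_molecule_table()`, `ensemble-stats` subcommand):

| column        | type    | meaning                                   |
|---------------|---------|-------------------------------------------|
| `molecule_id` | integer | identifier within the condition            |
| `condition`   | string  | condition label, e.g. `0%`, `3%`, `5%`     |
| `mean_x_um`   | double  | mean extension of the free end (um)        |
| `sd_x_um`     | double  | SD of the free-end position (um), >= 0     |

## Rheometer sweep table (CSV)

`reduce_viscosity_table()` / `reduce-viscosity` subcommand:
`shear_rate` (1/s), one or more numeric replicate columns (viscosity,
cP), optional `peg_pct` grouping column.

## Condition table (CSV)

Input of `calibrate_pipeline()` (`calibrate --table`); shape of
`peg_conditions()`: `peg_pct`, `eta_cp`, `sd_eta_cp`, `mean_ext_um`,
`sd_ext_um`, `sem_ext_um`, `fluct_um`, `sd_fluct_um`, `sem_fluct_um`,
`n_molecules`.

## Trajectory CSV

`write_trajectory_csv()`: `#`-prefixed metadata header lines (seed,
stride, duration, model parameters), then `time` (tau0), `bead`
(0 = tether), `x`, `y`, `z` (units of `a`), one row per frame and bead
(or free end only for end-recorded runs).

## Trajectory XYZ

`write_trajectory_xyz()`: standard XYZ blocks, one per frame — bead
count line, `t = <time> tau0` comment line, then one `C x y z` line per
bead (units of `a`).

## Model parameter config (JSON)

Flat key-value JSON consumed by `read_params_config()`; keys are the
`model_params()` arguments (`n_segments`, `spring_k`, `wall_eps`,
`alpha`, `decay_d`, `peg_pct`, `neighbor_cutoff`, `peclet`, `dt`,
`z_floor`). Missing keys take the defaults.

## Summary / calibration JSON

`relax --out` writes `tau_corr`, `tau_relax`, `tau_avg`, `amp_corr`,
`amp_relax`, `window`, `seed`. `calibrate --out` writes `c_prime`,
`wi0`, `tau_r`, `alpha_fits` (rows of `decay_d`, `alpha`, `residual`),
`predictions` and `seed`.
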