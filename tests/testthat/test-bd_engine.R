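test_that("noise impulses have mean zero and variance 2 dt", {
  dt <- 1e-4
  imp <- draw_noise(n_beads = 100, dt = dt, seed = 4, n_steps = 3334)
  draws <- c(imp$fx, imp$fy, imp$fz) # ~1e6 draws
  n <- length(draws)
  se_mean <- sqrt(2 * dt / n)
  expect_lt(abs(mean(draws)), 4 * se_mean)
  expect_equal(var(draws), 2 * dt, tolerance = 0.01)
  # fourth moment consistent with a Gaussian (kurtosis 3)
  expect_equal(mean(draws^4) / (2 * dt)^2, 3, tolerance = 0.05)
  expect_error(draw_noise(1, dt = 0, seed = 1), "dt")
})

test_that("the noise stream is a deterministic function of the seed", {
  a <- draw_noise(10, 1e-4, seed = 123, n_steps = 50)
  b <- draw_noise(10, 1e-4, seed = 123, n_steps = 50)
  c <- draw_noise(10, 1e-4, seed = 124, n_steps = 50)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$fx, c$fx)))
})

test_that("trajectories are bit-reproducible given the seed", {
  p <- model_params(n_segments = 10, peclet = 0.05)
  t1 <- bd_run(p, duration = 2, seed = 77)
  t2 <- bd_run(p, duration = 2, seed = 77)
  t3 <- bd_run(p, duration = 2, seed = 78)
  expect_identical(t1$end, t2$end)
  expect_identical(t1$final, t2$final)
  expect_false(identical(t1$end, t3$end))
})

test_that("a relaxed straight chain is a fixed point without noise", {
  p <- model_params(n_segments = 8)
  tr <- bd_run(p, duration = 0.05, stride = 100, seed = 1, noise_on = FALSE)
  expect_equal(tail(tr$end[, 1], 1), 8)
  expect_equal(tail(tr$end[, 3], 1), 1)
  expect_equal(attr(tr$final, "time"), 0.05)
})

test_that("a single tethered bead balances spring against shear drag", {
  # closed form: x* = 1 + Pe/ks at z = a
  p <- model_params(n_segments = 1, peclet = 0.02, spring_k = 1000)
  tr <- bd_run(p, duration = 5, stride = 1000, seed = 1, noise_on = FALSE)
  expect_equal(unname(tr$final$x[2]), 1 + 0.02 / 1000, tolerance = 1e-10)
  expect_equal(unname(tr$final$y[2]), 0)
  expect_equal(unname(tr$final$z[2]), 1)
})

test_that("one deterministic step displaces by (F + Pe z) dt exactly", {
  p <- model_params(n_segments = 2, peclet = 0.3)
  s <- chain_state(rbind(c(0, 0, 1), c(1, 0, 1), c(1.6, 0, 1.8)))
  f <- total_forces(s, p)
  s1 <- bd_step(s, p)
  expect_equal(s1$x[-1], s$x[-1] + (f$fx[-1] + 0.3 * s$z[-1]) * p$dt)
  expect_equal(s1$z[-1], s$z[-1] + f$fz[-1] * p$dt)
  expect_equal(unlist(s1[1, c("x", "y", "z")]),
               c(x = 0, y = 0, z = 1)) # tether untouched
  expect_equal(attr(s1, "time"), p$dt)
  # supplied impulses are added verbatim
  imp <- matrix(c(0.01, 0, 0, 0, 0.02, 0), 2, 3)
  s2 <- bd_step(s, p, impulses = imp)
  expect_equal(s2$x[-1] - s1$x[-1], imp[, 1])
})

test_that("frame bookkeeping: duration 1 at stride 1 gives 1/dt + 1 frames", {
  p <- model_params(n_segments = 3)
  tr <- bd_run(p, duration = 1, stride = 1, seed = 1)
  expect_length(tr$times, round(1 / p$dt) + 1)
  expect_equal(tr$times[1], 0)
  expect_equal(diff(tr$times), rep(p$dt, round(1 / p$dt)), tolerance = 1e-9)
  # stride thinning
  tr2 <- bd_run(p, duration = 1, stride = 500, seed = 1)
  expect_length(tr2$times, 21)
})

test_that("free-bead displacement variance grows as 2t", {
  # fluctuation-dissipation: per-coordinate MSD slope = 2 in reduced
  # units, estimated from independent increments over 200 replicas
  fb <- simulate_free_bead(n_replicas = 200, duration = 1, dt = 1e-4,
                           n_record = 10, seed = 5)
  inc <- fb |>
    dplyr::group_by(replica) |>
    dplyr::reframe(dx = diff(c(0, x)), dy = diff(c(0, y)),
                   dz = diff(c(0, z)), dt_rec = diff(c(0, time)))
  slope <- mean(c(inc$dx^2, inc$dy^2, inc$dz^2) / inc$dt_rec)
  expect_equal(slope, 2, tolerance = 0.05)
})

test_that("equilibrium bond lengths confirm near-inextensibility", {
  p <- model_params(n_segments = 10)
  tr <- bd_run(p, duration = 220, seed = 31, record = "full")
  long <- as_tibble(tr)
  bonds <- long |>
    dplyr::filter(time >= 20) |>
    dplyr::arrange(time, bead) |>
    dplyr::group_by(time) |>
    dplyr::reframe(len = sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
  expect_equal(mean(bonds$len), 1, tolerance = 0.01)
  expect_lt(var(bonds$len), 5 / p$spring_k) # O(1/spring_k)
})

test_that("without flow the free end has no preferred x or y", {
  # small chain so the run covers many relaxation times
  p <- model_params(n_segments = 10)
  trajs <- lapply(1:2, function(r) bd_run(p, duration = 1100, seed = 40 + r))
  xs <- unlist(lapply(trajs, function(tr) end_series(tr)$x))
  ys <- unlist(lapply(trajs, function(tr) end_series(tr)$y))
  keep <- rep(end_series(trajs[[1]])$time >= 100, 2)
  # tau_R ~ 15 tau0 at N=10: ~130 independent samples; sd(x) ~ sqrt(10/3)
  se <- sqrt(10 / 3) / sqrt(2 * 1000 / 30)
  expect_lt(abs(mean(xs[keep])), 4 * se)
  expect_lt(abs(mean(ys[keep])), 4 * se)
})

test_that("shear qualitatively stretches a z-aligned chain downstream", {
  p <- model_params(peclet = 0.02) # Wi = 6.66 conditions
  tr <- bd_run(p, duration = 300, seed = 8, init = "extended_z")
  s <- end_series(tr)
  expect_lt(s$x[1], 1e-9)         # starts at the wall-normal axis
  expect_gt(mean(tail(s$x, 100)), 15) # ends strongly stretched along flow
})

test_that("trajectory exports round-trip and carry metadata", {
  p <- model_params(n_segments = 4, peclet = 0.1)
  tr <- bd_run(p, duration = 1, stride = 2500, seed = 3, record = "full")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  hdr <- readLines(csv, n = 3)
  expect_match(hdr[2], "seed: 3")
  back <- utils::read.csv(csv, comment.char = "#")
  expect_equal(nrow(back), 5 * 5) # 5 frames x 5 beads
  expect_equal(back$x[back$time == 0 & back$bead == 4], 4)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, xyz)
  lines <- readLines(xyz)
  expect_length(lines, 5 * (5 + 2))
  # end-only trajectories refuse XYZ export
  tr_end <- bd_run(p, duration = 1, stride = 2500, seed = 3)
  expect_error(write_trajectory_xyz(tr_end, xyz), "full")
})
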