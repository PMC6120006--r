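# Observables tested on constructed inputs with known answers.

# minimal hand-built trajectory object
fake_traj <- function(positions, box, dt = 0.01, velocities = NULL) {
  F <- dim(positions)[3]
  structure(list(positions = positions,
                 times_pos = dt * (seq_len(F) - 1),
                 velocities = velocities,
                 times_vel = if (!is.null(velocities))
                   dt * (seq_len(dim(velocities)[3]) - 1),
                 box = box), class = "cg_trajectory")
}

test_that("ideal-gas configurations give g(r) = 1 within counting noise", {
  set.seed(5)
  N <- 200; box <- 40; F <- 40
  pos <- array(runif(N * 3 * F, 0, box), c(N, 3, F))
  r <- rdf(fake_traj(pos, box), bin_width = 0.5)
  sel <- r$r > 3        # skip the lowest-count bins
  counts <- r$g[sel] * r$n_frames * N * (N - 1) / 2 *
    4 / 3 * pi * ((r$r[sel] + 0.25)^3 - (r$r[sel] - 0.25)^3) / box^3
  z <- (r$g[sel] - 1) * sqrt(pmax(counts, 1))
  expect_lt(max(abs(z)), 4.5)                  # per-bin ~4.5 sigma bound
  expect_lt(abs(mean(r$g[sel]) - 1), 0.01)
  # normalization integral: density-weighted integral of g recovers N - 1
  full <- rdf(fake_traj(pos, box), bin_width = 0.25)
  integral <- sum(full$g * 4 * pi * full$r^2 * full$bin_width) * N / box^3
  frac <- 4 / 3 * pi * (max(full$r) + 0.125)^3 / box^3  # sphere within box
  expect_equal(integral, (N - 1) * frac, tolerance = 0.02 * (N - 1))
})

test_that("a static FCC crystal shows discrete shell peaks", {
  c60 <- c60_cached()
  init <- fcc_configuration(32, 1.219, 720.66, c60, 1529, seed = 1)
  pos <- array(rep(t(init$positions), 12), c(3, 32, 12))
  pos <- aperm(pos, c(2, 1, 3))
  r <- rdf(fake_traj(pos, init$box), bin_width = 0.1)
  a_nn <- init$box / 2 / sqrt(2)      # nearest-neighbor distance
  peak_bin <- which.max(r$g)
  expect_lt(abs(r$r[peak_bin] - a_nn), 0.1)
  # gaps between shells are empty
  expect_equal(max(r$g[r$r > a_nn * 1.1 & r$r < a_nn * 1.3]), 0)
  expect_error(rdf(fake_traj(pos, init$box), r_max = init$box), "half the box")
})

test_that("first_peak interpolates a synthetic bump and rejects flat input", {
  r <- seq(0.05, 20, by = 0.1)
  g <- 1 + 4.2 * exp(-(r - 9.63)^2 / (2 * 0.5^2))
  res <- first_peak(structure(list(r = r, g = g, bin_width = 0.1),
                              class = "rdf_result"))
  expect_lt(abs(res$position - 9.63), 0.1)
  expect_equal(res$height, 5.2, tolerance = 0.01)
  flat <- structure(list(r = r, g = rep(1, length(r)), bin_width = 0.1),
                    class = "rdf_result")
  expect_error(first_peak(flat), "no RDF peak")
})

test_that("VAF is 1 at lag zero and constant for free particles", {
  set.seed(8)
  N <- 30; F <- 100
  v0 <- matrix(rnorm(N * 3), N, 3)
  vel <- array(rep(v0, F), c(N, 3, F))    # ballistic: velocities constant
  tr <- fake_traj(array(0, c(N, 3, F)), box = -1, velocities = vel)
  res <- vaf(tr, max_lag_ps = 0.5)
  expect_equal(res$C[1], 1)
  expect_equal(res$C, rep(1, length(res$C)), tolerance = 1e-12)
  expect_equal(res$v2_mean, mean(rowSums(v0^2)), tolerance = 1e-12)
  expect_error(vaf(fake_traj(array(0, c(2, 3, 5)), -1)), "no velocity")
  # constant-velocity input: Green-Kubo precondition fails
  expect_error(green_kubo_D(res), "not decayed")
})

test_that("Green-Kubo recovers the closed-form Ornstein-Uhlenbeck diffusivity", {
  # v(t+dt) = v exp(-dt/tau) + noise  ->  C_v(t) = exp(-t/tau),
  # D = <v^2> tau / 3
  set.seed(123)
  N <- 60; F <- 4000; dt <- 0.01; tau <- 0.08; v2_1d <- 2.0
  decay <- exp(-dt / tau)
  vel <- array(0, c(N, 3, F))
  vel[, , 1] <- rnorm(N * 3, sd = sqrt(v2_1d))
  for (f in 2:F)
    vel[, , f] <- vel[, , f - 1] * decay +
      matrix(rnorm(N * 3, sd = sqrt(v2_1d * (1 - decay^2))), N, 3)
  tr <- fake_traj(array(0, c(N, 3, F)), box = -1, velocities = vel)
  res <- vaf(tr, max_lag_ps = 0.6)
  gk <- green_kubo_D(res)
  D_expected <- 10 * (3 * v2_1d) * tau / 3     # in 1e-9 m^2/s units
  expect_equal(gk$D, D_expected, tolerance = 0.05)
  expect_lt(abs(gk$D_80 - gk$D) / gk$D, 0.05)
})

test_that("Green-Kubo and MSD diffusion agree on a liquid trajectory", {
  c60 <- c60_cached()
  pot <- morse_potential(0.00177, 1.3, 9.65)
  init <- fcc_configuration(108, 1.0, 720.66, c60, 1800, seed = 6)
  sc <- simulation_config("cg0", pot, timestep_fs = 5, n_steps_equil = 2000,
                          n_steps_prod = 10000, temperature = 1800,
                          thermostat_interval = 50, pos_stride = 10,
                          vel_stride = 5, log_stride = 200)
  tr <- run_md(sc, init)
  gk <- green_kubo_D(vaf(tr, max_lag_ps = 5), override = TRUE)
  ms <- msd_diffusion(tr, max_lag_ps = 10)
  expect_lt(abs(gk$D - ms$D) / ms$D, 0.15)
  expect_gt(gk$D, 0)
})
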