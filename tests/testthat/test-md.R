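# Integrator and engine-level checks on small systems; the paper-scale
# liquid runs live in test-acceptance.R.

test_that("force-free bodies move uniformly and spin about a fixed axis", {
  pt <- blob_template(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                            c(0, 0, 1), c(0, 0, -1)))  # spherical top
  pot <- morse_potential(1e-12, 0.5, 5)   # negligible interaction
  cfg <- make_configuration(pt, rbind(c(0, 0, 0), c(0, 0, 500)),
                            velocities = rbind(c(0.1, 0, 0), c(0, 0.2, 0)),
                            omega = rbind(c(0.3, 0.1, 0), c(0, 0, 0.4)))
  out <- md_step(cfg, pot, engine = "cg4", dt_fs = 2, n_steps = 500,
                 cutoff = 10)
  # uniform translation: x = x0 + v t, t = 1 ps
  expect_equal(out$positions[1, ], c(0.1, 0, 0), tolerance = 1e-9)
  expect_equal(out$positions[2, ], c(0, 0.2, 500), tolerance = 1e-9)
  expect_equal(out$velocities, cfg$velocities, tolerance = 1e-12)
  # spherical top: |omega| and spin axis conserved
  expect_equal(out$omega, cfg$omega, tolerance = 1e-10)
})

test_that("thermostat rescaling hits the target temperature exactly", {
  c60 <- c60_cached()
  init <- fcc_configuration(32, 1.0, 720.66, c60, 1200, seed = 2)
  resc <- thermostat_rescale(init, 1529)
  expect_equal(kinetic_temperature(resc), 1529, tolerance = 1e-12)
  # momentum stays zero
  expect_lt(max(abs(colSums(resc$velocities))), 1e-9)
  down <- thermostat_rescale(resc, 300)
  expect_equal(kinetic_temperature(down), 300, tolerance = 1e-12)
})

test_that("trajectories are bit-identical for identical seeds and configs", {
  c60 <- c60_cached()
  pot <- morse_potential(0.00177, 1.3, 9.65)
  mk <- function(seed) {
    init <- fcc_configuration(32, 1.219, 720.66, c60, 1529, seed = seed)
    sc <- simulation_config("cg0", pot, timestep_fs = 5, n_steps_equil = 50,
                            n_steps_prod = 200, temperature = 1529,
                            thermostat_interval = 20, pos_stride = 20,
                            vel_stride = 20, log_stride = 50)
    run_md(sc, init)
  }
  t1 <- mk(7); t2 <- mk(7); t3 <- mk(8)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$velocities, t2$velocities)
  expect_identical(t1$log, t2$log)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("32-molecule smoke run completes and conserves momentum", {
  c60 <- c60_cached()
  pot <- morse_potential(0.00177, 1.3, 9.65)
  init <- fcc_configuration(32, 1.219, 720.66, c60, 1529, seed = 4)
  sc <- simulation_config("cg3", pot, timestep_fs = 5, n_steps_equil = 100,
                          n_steps_prod = 400, temperature = 1529,
                          thermostat_interval = 20, pos_stride = 40,
                          vel_stride = 40, log_stride = 100)
  tr <- run_md(sc, init)
  expect_equal(dim(tr$positions)[1], 32)
  p <- colSums(tr$final$velocities) * tr$mass
  vscale <- mean(abs(tr$final$velocities)) * tr$mass * 32
  expect_lt(max(abs(p)) / vscale, 1e-8)
  expect_true(all(is.finite(tr$log)))
  # NVT held: time-averaged kinetic temperature within 1% of target
  expect_lt(abs(mean(tr$log[-1, "T_kin"]) - 1529) / 1529, 0.01)
})

test_that("all-atom engine pair energy equals the direct double sum", {
  c60 <- c60_cached()
  pot <- atomic_carbon_morse()
  cfg <- make_configuration(c60, rbind(c(0, 0, 0), c(0, 0, 10.3)),
                            quaternions = rbind(quat_normalize(c(1, .1, 0, .2)),
                                                quat_normalize(c(.8, 0, .3, 0))))
  sc <- simulation_config("allatom", pot, timestep_fs = 2, n_steps_equil = 0,
                          n_steps_prod = 1, temperature = NULL, cutoff = 1e5,
                          pos_stride = 1, vel_stride = 1, log_stride = 1)
  tr <- run_md(sc, cfg)
  sA <- blob_state(cfg$template, cfg$positions[1, ], cfg$quaternions[1, ])
  sB <- blob_state(cfg$template, cfg$positions[2, ], cfg$quaternions[2, ])
  expect_equal(tr$log[1, "pe_kcal"], allatom_energy(sA, sB, pot),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("CG engine on point blobs reproduces a bare pair-potential liquid", {
  # cross-engine equivalence: a point-blob CG run equals an all-atom run of
  # the same single-site potential, step for step
  pt <- blob_template(matrix(0, 1, 3), masses = 720.66)
  pot <- morse_potential(6.4, 1.3, 9.65)
  init <- fcc_configuration(32, 1.219, 720.66, pt, 1529, seed = 9)
  run_engine <- function(engine) {
    sc <- simulation_config(engine, pot, timestep_fs = 5, n_steps_equil = 0,
                            n_steps_prod = 100, temperature = NULL,
                            thermostat_interval = 0, pos_stride = 100,
                            vel_stride = 100, log_stride = 100,
                            shift = FALSE)
    run_md(sc, init)
  }
  cg <- run_engine("cg0")
  aa <- run_engine("allatom")
  expect_equal(cg$final$positions, aa$final$positions, tolerance = 1e-12)
  expect_equal(cg$log[, "pe_kcal"], aa$log[, "pe_kcal"], tolerance = 1e-10)
})

test_that("NVE runs conserve energy for a bound C60 pair (both engines)", {
  c60 <- c60_cached()
  drift <- function(engine, pot, R, dt_fs, steps) {
    cfg <- make_configuration(c60, rbind(c(0, 0, 0), c(0, 0, R)),
                              velocities = rbind(c(0, 0, 0.05),
                                                 c(0, 0, -0.05)),
                              omega = rbind(c(0.1, 0.2, 0.05),
                                            c(-0.1, 0, 0.15)))
    sc <- simulation_config(engine, pot, timestep_fs = dt_fs,
                            n_steps_equil = 0, n_steps_prod = steps,
                            temperature = NULL, cutoff = 1e5,
                            pos_stride = steps, vel_stride = steps,
                            log_stride = 50)
    tr <- run_md(sc, cfg)
    E <- tr$log[, "pe_kcal"] + tr$log[, "ke_trans_kcal"] +
      tr$log[, "ke_rot_kcal"]
    max(E) - min(E)
  }
  # drift under 1e-3 of the well depth over 10^4 steps at dt = 2 fs
  d_aa <- drift("allatom", atomic_carbon_morse(), 10.0, 2, 10000)
  expect_lt(d_aa, 1e-3 * 7.4)
  d_cg <- drift("cg3", morse_potential(0.00177, 1.3, 9.65), 10.5, 2, 10000)
  expect_lt(d_cg, 1e-3 * 6.4)
  # drift scales roughly as dt^2: quadruple step, expect much larger drift
  d_cg8 <- drift("cg3", morse_potential(0.00177, 1.3, 9.65), 10.5, 8, 2500)
  expect_gt(d_cg8, 4 * d_cg)
})

test_that("non-finite coordinates abort with an integration error", {
  pt <- blob_template(matrix(0, 1, 3), masses = 1)
  pot <- morse_potential(1, 100, 10)   # exp overflow at tiny separations
  cfg <- make_configuration(pt, rbind(c(0, 0, 0), c(0, 0, 0.1)))
  expect_error(md_step(cfg, pot, engine = "cg0", dt_fs = 1000, n_steps = 50,
                       cutoff = 20),
               "integration failure")
})
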