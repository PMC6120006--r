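# Rigid-body molecular dynamics driver (compiled core in src/cg_core.cpp).
#
# Translation: leapfrog/velocity-Verlet. Rotation: body-frame Euler
# equations (including the gyroscopic omega x I omega term) advanced with a
# quaternion exponential map, renormalized every step. NVT via velocity
# rescaling at fixed intervals; minimum-image periodic boundaries.

.engine_code <- function(engine) if (engine == "allatom") 1L else 0L

.engine_max_m <- function(engine)
  switch(engine, allatom = -1L, cg0 = 0L, cg1 = 1L, cg2 = 2L, cg3 = 3L,
         cg4 = 4L, stop("unknown engine: ", engine))

.sigma_star <- function(potential)
  if (potential$kind == "morse") potential$R0 else potential$sigma

.resolve_cutoff <- function(config, box) {
  rc <- config$cutoff
  if (is.null(rc)) rc <- 3 * .sigma_star(config$potential)
  if (box > 0) rc <- min(rc, 0.499 * box)
  rc
}

#' Run a rigid-body MD simulation
#'
#' Equilibrates with frequent velocity rescaling, then runs production with
#' rescaling every `thermostat_interval` steps (or NVE when no temperature
#' is set). Fully deterministic given the initial configuration: all
#' randomness lives in [fcc_configuration()].
#'
#' @param config A `simulation_config`.
#' @param initial An `md_configuration`.
#' @return Object of class `cg_trajectory`: `positions` (N x 3 x frames,
#'   Angstrom, wrapped), `times_pos` (ps), `velocities` (N x 3 x frames,
#'   A/ps), `times_vel`, `log` (time, potential/kinetic energies in
#'   kcal/mol, kinetic temperature), `box`, `final` (an `md_configuration`
#'   for restarts), plus run metadata.
#' @export
run_md <- function(config, initial) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(initial, "md_configuration"))
  dt <- config$timestep_fs / 1000        # ps
  box <- initial$box
  cutoff <- .resolve_cutoff(config, box)
  engine <- .engine_code(config$engine)
  max_m <- .engine_max_m(config$engine)
  pack <- .tensor_pack(compute_moment_tensors(initial$template, 4))
  pot <- .potential_spec(config$potential)

  state <- initial
  if (config$n_steps_equil > 0) {
    eq <- md_run_cpp(engine, pack, initial$template$xyz, initial$mass,
                     initial$inertia,
                     state$positions, state$velocities, state$quaternions,
                     state$omega,
                     box, pot, max_m, cutoff, config$shift,
                     dt, config$n_steps_equil,
                     config$temperature,
                     max(1L, config$thermostat_interval %/% 5L),
                     config$n_steps_equil + 1L, config$n_steps_equil + 1L,
                     config$log_stride)
    state$positions <- eq$final_pos
    state$velocities <- eq$final_vel
    state$quaternions <- eq$final_quat
    state$omega <- eq$final_omega
  }
  pr <- md_run_cpp(engine, pack, initial$template$xyz, initial$mass,
                   initial$inertia,
                   state$positions, state$velocities, state$quaternions,
                   state$omega,
                   box, pot, max_m, cutoff, config$shift,
                   dt, config$n_steps_prod,
                   config$temperature, config$thermostat_interval,
                   config$pos_stride, config$vel_stride, config$log_stride)
  final <- state
  final$positions <- pr$final_pos
  final$velocities <- pr$final_vel
  final$quaternions <- pr$final_quat
  final$omega <- pr$final_omega
  structure(list(
    positions = pr$positions, times_pos = pr$times_pos,
    velocities = pr$velocities, times_vel = pr$times_vel,
    log = pr$log,
    box = box, cutoff = cutoff, timestep_fs = config$timestep_fs,
    engine = config$engine, temperature = config$temperature,
    density = initial$density, mass = initial$mass, seed = initial$seed,
    n_molecules = nrow(initial$positions),
    final = final), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "cg_trajectory: %s engine, %d molecules, %.1f ps production (%d position frames), box %.2f A\n",
    x$engine, x$n_molecules, max(x$times_pos), dim(x$positions)[3], x$box))
  if (x$temperature > 0)
    cat(sprintf("  NVT at %g K; mean kinetic T over run: %.1f K\n",
                x$temperature, mean(x$log[, "T_kin"])))
  invisible(x)
}

#' Advance a configuration by single MD steps
#'
#' One (or a few) velocity-Verlet rigid-body steps without thermostatting;
#' useful for inspecting the integrator. For full runs use [run_md()].
#'
#' @param initial An `md_configuration`.
#' @param potential A `pair_potential`.
#' @param engine Engine name as in [simulation_config()].
#' @param dt_fs Timestep, fs.
#' @param n_steps Number of steps (default 1).
#' @param cutoff Cutoff, Angstrom (`NULL`: 3 sigma*, clamped to the box).
#' @return The advanced `md_configuration`.
#' @export
md_step <- function(initial, potential, engine = "cg4", dt_fs = 2,
                    n_steps = 1, cutoff = NULL) {
  cfg <- simulation_config(engine = engine, potential = potential,
                           timestep_fs = dt_fs, n_steps_equil = 0,
                           n_steps_prod = n_steps, temperature = NULL,
                           cutoff = cutoff, pos_stride = n_steps,
                           vel_stride = n_steps, log_stride = n_steps)
  run_md(cfg, initial)$final
}
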