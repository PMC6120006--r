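# Simulation configurations: FCC initial states and run parameters.

#' Rotate a blob template into its principal inertia frame
#'
#' @param template A `blob_template`.
#' @return List with `template` (coordinates rotated so the inertia tensor
#'   is diagonal), `inertia` (principal moments, amu A^2, ascending) and
#'   `mass` (total, amu).
#' @export
principal_frame <- function(template) {
  xyz <- template$xyz
  m <- template$masses
  r2 <- rowSums(xyz^2)
  I <- diag(sum(m * r2), 3) - crossprod(xyz * sqrt(m), xyz * sqrt(m))
  eig <- eigen(I, symmetric = TRUE)
  V <- eig$vectors[, 3:1]          # ascending principal moments
  if (det(V) < 0) V[, 3] <- -V[, 3]
  rot <- blob_template(xyz %*% V, masses = m, label = template$label)
  for (at in c("pentagon_axes", "hexagon_axes"))
    if (!is.null(attr(template, at)))
      attr(rot, at) <- attr(template, at) %*% V
  list(template = rot, inertia = rev(eig$values), mass = sum(m))
}

#' FCC-lattice initial configuration
#'
#' Places molecular centers on a face-centered cubic lattice in a cubic box
#' whose edge follows from the target mass density, randomizes orientations
#' uniformly over rotations, and draws center-of-mass and angular velocities
#' from the Maxwell-Boltzmann distribution at the target temperature (net
#' linear momentum then zeroed).
#'
#' @param n_molecules Number of molecules; must equal 4 k^3 for integer k.
#' @param density Mass density, g/cm^3.
#' @param molar_mass Molar mass of one molecule, g/mol.
#' @param template A `blob_template` for the rigid molecule.
#' @param temperature Target temperature, K.
#' @param seed Integer seed for orientations and velocities.
#' @return Object of class `md_configuration`: `box` (edge, Angstrom),
#'   `positions`, `velocities`, `quaternions`, `omega` (body frame),
#'   `template` (principal frame), `mass`, `inertia`, `density`,
#'   `temperature`, `seed`.
#' @export
fcc_configuration <- function(n_molecules, density, molar_mass, template,
                              temperature, seed = 1) {
  k <- round((n_molecules / 4)^(1 / 3))
  if (4 * k^3 != n_molecules)
    stop("n_molecules must be 4 k^3 for integer k (FCC filling); got ",
         n_molecules)
  stopifnot(density > 0, molar_mass > 0, temperature > 0)
  vol <- n_molecules * molar_mass / (density * .AVOGADRO) * 1e24  # A^3
  box <- vol^(1 / 3)
  a <- box / k
  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  cells <- as.matrix(expand.grid(x = 0:(k - 1), y = 0:(k - 1), z = 0:(k - 1)))
  pos <- NULL
  for (b in seq_len(4))
    pos <- rbind(pos, sweep(cells, 2, basis[b, ], "+") * a)
  pos <- pos + a / 4                # keep sites away from the box faces

  pf <- principal_frame(template)
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(seed)
  quats <- random_quaternion(n_molecules)
  kT <- .KB_KCALMOL * .KCAL_TO_INTERNAL * temperature  # amu A^2/ps^2
  vel <- matrix(rnorm(3 * n_molecules, sd = sqrt(kT / pf$mass)), ncol = 3)
  vel <- sweep(vel, 2, colMeans(vel))  # zero net momentum (equal masses)
  # point-like blobs carry no rotational degrees of freedom
  om_sd <- ifelse(pf$inertia > 1e-9, sqrt(kT / pmax(pf$inertia, 1e-9)), 0)
  om <- cbind(rnorm(n_molecules, sd = om_sd[1]),
              rnorm(n_molecules, sd = om_sd[2]),
              rnorm(n_molecules, sd = om_sd[3]))
  structure(list(box = box, positions = unname(pos),
                 velocities = unname(vel),
                 quaternions = unname(quats), omega = unname(om),
                 template = pf$template, mass = pf$mass,
                 inertia = pf$inertia, density = density,
                 temperature = temperature, seed = seed),
            class = "md_configuration")
}

#' Assemble a configuration by hand
#'
#' Low-level constructor for small systems (dimers, toy liquids) where the
#' FCC builder is not wanted. The template is rotated into its principal
#' inertia frame.
#'
#' @param template A `blob_template`.
#' @param positions N x 3 matrix of molecular centers (Angstrom).
#' @param velocities N x 3 (A/ps); default zero.
#' @param quaternions N x 4 unit quaternions; default identity.
#' @param omega N x 3 body-frame angular velocities (rad/ps); default zero.
#' @param box Cubic box edge (Angstrom); <= 0 for an open (non-periodic)
#'   system.
#' @param temperature Nominal temperature tag, K (metadata only).
#' @return An `md_configuration`.
#' @export
make_configuration <- function(template, positions, velocities = NULL,
                               quaternions = NULL, omega = NULL, box = -1,
                               temperature = 0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(omega)) omega <- matrix(0, n, 3)
  if (is.null(quaternions))
    quaternions <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  pf <- principal_frame(template)
  structure(list(box = box, positions = unname(positions),
                 velocities = unname(as.matrix(velocities)),
                 quaternions = unname(as.matrix(quaternions)),
                 omega = unname(as.matrix(omega)),
                 template = pf$template, mass = pf$mass,
                 inertia = pf$inertia, density = NA_real_,
                 temperature = temperature, seed = NA_integer_),
            class = "md_configuration")
}

#' @export
print.md_configuration <- function(x, ...) {
  cat(sprintf(
    "md_configuration: %d x '%s' in %.2f A box (%.4f g/cm^3), T = %g K, seed %d\n",
    nrow(x$positions), x$template$label, x$box, x$density, x$temperature,
    x$seed))
  invisible(x)
}

#' Instantaneous kinetic temperature of a configuration
#'
#' Equipartition over 6 degrees of freedom per rigid body:
#' T = (KE_trans + KE_rot) / (3 N kB).
#'
#' @param config An `md_configuration`.
#' @return Temperature, K.
#' @export
kinetic_temperature <- function(config) {
  ket <- 0.5 * config$mass * sum(config$velocities^2)
  ker <- 0.5 * sum(sweep(config$omega^2, 2, config$inertia, "*"))
  (ket + ker) / (3 * nrow(config$positions) * .KB_KCALMOL * .KCAL_TO_INTERNAL)
}

#' Rescale velocities to a target kinetic temperature
#'
#' Scales linear and angular velocities by sqrt(T_target / T_kinetic); the
#' post-call kinetic temperature equals the target to round-off. This is the
#' velocity-rescaling thermostat applied between MD intervals.
#'
#' @param config An `md_configuration`.
#' @param target Target temperature, K.
#' @return The rescaled configuration.
#' @export
thermostat_rescale <- function(config, target) {
  tk <- kinetic_temperature(config)
  if (tk <= 0) stop("kinetic temperature must be positive")
  s <- sqrt(target / tk)
  config$velocities <- config$velocities * s
  config$omega <- config$omega * s
  config
}

#' Simulation run parameters
#'
#' @param engine "allatom", "cg0", "cg3" or "cg4" (coarse-grained series
#'   truncated at order 0, 3 or 4).
#' @param potential A `pair_potential` (the united-atom pair potential; for
#'   the CG engines this is the fitted single-site potential of the blob).
#' @param timestep_fs Integration timestep, fs (default 5 for CG, use ~2 for
#'   all-atom rigid bodies).
#' @param n_steps_equil,n_steps_prod Equilibration / production step counts.
#' @param temperature Target temperature, K (NVT); `NULL` or <= 0 runs NVE.
#' @param thermostat_interval Steps between velocity rescalings in
#'   production (equilibration uses `max(1, interval %/% 5)`).
#' @param cutoff Interaction cutoff on center separation, Angstrom. Default
#'   `NULL` means 3 sigma*, where sigma* is the potential's equilibrium
#'   distance (Morse R0, or LJ sigma), clamped below half the box edge.
#' @param shift Energy-shift the leading series term to zero at the cutoff
#'   (CG engines; default TRUE).
#' @param pos_stride,vel_stride,log_stride Sampling strides (steps) for
#'   positions, velocities, and the energy/temperature log.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(engine = c("cg3", "cg0", "cg4", "allatom"),
                              potential,
                              timestep_fs = 5,
                              n_steps_equil = 20000, n_steps_prod = 50000,
                              temperature = NULL,
                              thermostat_interval = 50,
                              cutoff = NULL, shift = TRUE,
                              pos_stride = 20, vel_stride = 2,
                              log_stride = 100) {
  engine <- match.arg(engine)
  stopifnot(inherits(potential, "pair_potential"), timestep_fs > 0)
  structure(list(engine = engine, potential = potential,
                 timestep_fs = timestep_fs,
                 n_steps_equil = n_steps_equil, n_steps_prod = n_steps_prod,
                 temperature = if (is.null(temperature)) -1 else temperature,
                 thermostat_interval = thermostat_interval,
                 cutoff = cutoff, shift = isTRUE(shift),
                 pos_stride = pos_stride, vel_stride = vel_stride,
                 log_stride = log_stride),
            class = "simulation_config")
}
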