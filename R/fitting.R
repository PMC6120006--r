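# Effective-potential curves and Morse fitting: the coarse-grained
# parameterization workflow. A pair of C60 molecules is scanned face-to-face
# (hexagon-hexagon, hexagon-pentagon, pentagon-pentagon), the exact all-atom
# double sum provides the reference curve, and a single-site Morse (energy
# model: scale * U_Morse, scale = N_A * N_B for one site per molecule) is
# least-squares fitted so the truncated coarse-grained series reproduces it.

#' Effective potential curve container
#'
#' @param separations Strictly increasing center separations, Angstrom.
#' @param energies Energies, kcal/mol.
#' @param label Configuration label, e.g. "hex-hex" or
#'   "orientation-averaged".
#' @return Object of class `potential_curve` (a data frame with attributes).
#' @export
potential_curve <- function(separations, energies, label = "curve") {
  separations <- as.numeric(separations); energies <- as.numeric(energies)
  if (length(separations) != length(energies))
    stop("separations and energies must have equal length")
  if (any(diff(separations) <= 0))
    stop("separations must be strictly increasing")
  structure(data.frame(R = separations, energy = energies),
            label = label, class = c("potential_curve", "data.frame"))
}

#' Write / read two-column curve files
#' @param curve A `potential_curve`.
#' @param path File path (two columns: R in Angstrom, energy in kcal/mol).
#' @export
write_curve <- function(curve, path) {
  writeLines(c(sprintf("# %s", attr(curve, "label")),
               "# R_Angstrom energy_kcal_mol",
               sprintf("%.8g %.10g", curve$R, curve$energy)), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  label <- sub("^#\\s*", "", lines[1])
  dat <- read.table(text = lines[!grepl("^#", lines)])
  potential_curve(dat[[1]], dat[[2]], label = label)
}

# states for a face-to-face scan: B at origin with its face axis along +z
# (towards A), A at (0, 0, R) with its face axis along -z (towards B)
.face_orientations <- function(templateA, templateB, orientation) {
  pick_axis <- function(tmpl, face) {
    axes <- attr(tmpl, switch(face, hex = "hexagon_axes",
                              pent = "pentagon_axes"))
    if (is.null(axes))
      stop("template lacks face-axis attributes (build it with build_c60)")
    axes[1, ]
  }
  faces <- switch(orientation,
                  "hex-hex" = c("hex", "hex"),
                  "hex-pent" = c("hex", "pent"),
                  "pent-hex" = c("pent", "hex"),
                  "pent-pent" = c("pent", "pent"),
                  "identity" = NULL,
                  stop("unknown orientation label: ", orientation))
  if (is.null(faces)) return(list(qA = c(1, 0, 0, 0), qB = c(1, 0, 0, 0)))
  axA <- pick_axis(templateA, faces[1])
  axB <- pick_axis(templateB, faces[2])
  list(qA = matrix_to_quat(rotation_aligning(axA, c(0, 0, -1))),
       qB = matrix_to_quat(rotation_aligning(axB, c(0, 0, 1))))
}

#' Scan an effective pair-potential curve
#'
#' Energy of two blobs at a series of center separations in a fixed
#' relative orientation, by the exact all-atom double sum or by the
#' truncated coarse-grained series.
#'
#' @param templateA,templateB `blob_template` objects (face orientations
#'   need the axis attributes produced by [build_c60()]).
#' @param potential A `pair_potential`.
#' @param orientation "hex-hex", "hex-pent", "pent-pent" (face-to-face) or
#'   "identity" (as-built orientations).
#' @param R_values Center separations, Angstrom (increasing).
#' @param engine "allatom" or a `truncation_scheme` for the CG series.
#' @return A `potential_curve`.
#' @export
scan_curve <- function(templateA, templateB, potential,
                       orientation = "hex-hex",
                       R_values = seq(8.5, 16, by = 0.05),
                       engine = "allatom") {
  ori <- .face_orientations(templateA, templateB, orientation)
  stateB <- blob_state(templateB, c(0, 0, 0), ori$qB)
  energies <- vapply(R_values, function(R) {
    stateA <- blob_state(templateA, c(0, 0, R), ori$qA)
    if (identical(engine, "allatom"))
      allatom_energy(stateA, stateB, potential)
    else
      interblob_energy(stateA, stateB, potential, scheme = engine)
  }, numeric(1))
  potential_curve(R_values, energies, label = orientation)
}

#' Fit a (scaled) Morse potential to an energy curve
#'
#' Least-squares fit of `scale * U_Morse(R; De, alpha, R0)` over a window
#' bracketing the minimum (default 0.9 to 1.6 times the location of the
#' curve minimum, which keeps the steep repulsive wall from dominating an
#' unweighted fit).
#'
#' @param curve A `potential_curve` with at least 10 points spanning an
#'   interior minimum.
#' @param fix_alpha If non-NULL, hold the width parameter fixed at this
#'   value (1/Angstrom).
#' @param scale Energy-model scale factor (e.g. 3600 = 60 x 60 for a
#'   single-site fit to a C60-C60 curve). Default 1.
#' @param window Fit window in Angstrom, `c(lo, hi)`; default
#'   `c(0.9, 1.6) * R_min`.
#' @return Object of class `morse_fit`: `potential` (the fitted
#'   `pair_potential`), `R0`, `De`, `alpha`, `residual` (RMS over the
#'   window, kcal/mol), `window`, `n_points`.
#' @export
fit_morse <- function(curve, fix_alpha = NULL, scale = 1, window = NULL) {
  if (nrow(curve) < 10) stop("need at least 10 curve points")
  imin <- which.min(curve$energy)
  if (imin == 1 || imin == nrow(curve))
    stop("fit failure: curve has no interior minimum")
  Rmin <- curve$R[imin]
  if (is.null(window)) window <- c(0.9, 1.6) * Rmin
  sel <- curve$R >= window[1] & curve$R <= window[2]
  if (sum(sel) < 5) stop("fit window contains too few points")
  dat <- data.frame(R = curve$R[sel], E = curve$energy[sel])
  De0 <- max(-min(dat$E) / scale, 1e-12)
  a0 <- if (is.null(fix_alpha)) 1.3 else fix_alpha
  morse_E <- function(R, De, a, R0)
    scale * De * (exp(-2 * a * (R - R0)) - 2 * exp(-a * (R - R0)))
  fit <- if (is.null(fix_alpha)) {
    minpack.lm::nlsLM(E ~ morse_E(R, De, a, R0), data = dat,
                      start = list(De = De0, a = a0, R0 = Rmin),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    a_fixed <- fix_alpha
    minpack.lm::nlsLM(E ~ morse_E(R, De, a_fixed, R0), data = dat,
                      start = list(De = De0, R0 = Rmin),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- coef(fit)
  alpha <- if (is.null(fix_alpha)) cf[["a"]] else fix_alpha
  structure(list(
    potential = morse_potential(cf[["De"]], alpha, cf[["R0"]]),
    R0 = cf[["R0"]], De = cf[["De"]], alpha = alpha,
    residual = sqrt(mean(residuals(fit)^2)), window = window,
    scale = scale, n_points = nrow(dat)), class = "morse_fit")
}

#' @export
print.morse_fit <- function(x, ...) {
  cat(sprintf(
    "morse_fit: R0 = %.4f A, De = %.6g kcal/mol, alpha = %.3f 1/A (scale %g)\n  RMS residual %.3g kcal/mol over [%.2f, %.2f] A (%d points)\n",
    x$R0, x$De, x$alpha, x$scale, x$residual, x$window[1], x$window[2],
    x$n_points))
  invisible(x)
}

#' Coarse-grained Morse parameterization of a rigid blob
#'
#' The full coarse-graining workflow for a pair of identical blobs
#' (typically C60): generate the exact all-atom reference curves for the
#' three face-to-face configurations with the atomic pair potential, average
#' them with equal weights, and fit the effective single-site Morse (energy
#' scale N_A * N_B, width alpha held fixed) so the CG series truncated at
#' the requested order reproduces the reference. At order 0 the series is
#' N_A N_B U(R) and the fit is a plain scaled-Morse fit; at higher orders
#' the moment-tensor terms of the trial Morse are included self-consistently
#' in the fitted model.
#'
#' @param template A `blob_template` with face axes (see [build_c60()]).
#' @param atomic_potential The atomic pair potential (`pair_potential`).
#' @param order Truncation order of the CG series being parameterized
#'   (0 or 3 in practice).
#' @param R_values Scan separations, Angstrom.
#' @param fix_alpha Width parameter held fixed (default 1.3 1/Angstrom).
#' @param orientations Face configurations averaged into the reference.
#' @return A `morse_fit` (scale = N_A * N_B), with the reference curve in
#'   attribute `reference`.
#' @export
cg_parameterize <- function(template, atomic_potential, order = 0,
                            R_values = seq(8.5, 16, by = 0.05),
                            fix_alpha = 1.3,
                            orientations = c("hex-hex", "hex-pent",
                                             "pent-pent")) {
  n_atoms <- nrow(template$xyz)
  scale <- n_atoms^2
  curves <- lapply(orientations, function(o)
    scan_curve(template, template, atomic_potential, o, R_values, "allatom"))
  ref_E <- rowMeans(do.call(cbind, lapply(curves, function(c) c$energy)))
  ref <- potential_curve(R_values, ref_E, label = "orientation-averaged")

  if (order == 0) {
    fit <- fit_morse(ref, fix_alpha = fix_alpha, scale = scale)
    attr(fit, "reference") <- ref
    return(fit)
  }

  # higher order: model(R) = sum over (m,n), m <= order, of
  # V(mn)[Morse] * Theta(mn); Theta constants per orientation (fixed Rhat)
  pairs <- series_index_pairs(order)
  theta <- matrix(0, length(orientations), nrow(pairs))
  for (oi in seq_along(orientations)) {
    ori <- .face_orientations(template, template, orientations[oi])
    TA <- lab_tensors(blob_state(template, c(0, 0, 1), ori$qA))
    TB <- lab_tensors(blob_state(template, c(0, 0, 0), ori$qB))
    for (r in seq_len(nrow(pairs)))
      theta[oi, r] <- angular_part_tensor(TA, TB, c(0, 0, 1),
                                          pairs[r, 1], pairs[r, 2])
  }
  theta_bar <- colMeans(theta)
  imin <- which.min(ref$energy)
  if (imin == 1 || imin == nrow(ref))
    stop("fit failure: reference curve has no interior minimum")
  Rmin <- ref$R[imin]
  window <- c(0.9, 1.6) * Rmin
  sel <- ref$R >= window[1] & ref$R <= window[2]
  dat <- data.frame(R = ref$R[sel], E = ref$energy[sel])
  model_E <- function(R, De, R0) {
    pot <- morse_potential(De, fix_alpha, R0)
    out <- numeric(length(R))
    for (r in seq_len(nrow(pairs)))
      out <- out + radial_coefficient(pot, R, pairs[r, 1], pairs[r, 2]) *
        theta_bar[r]
    out
  }
  De0 <- max(-min(dat$E) / scale, 1e-12)
  fit <- minpack.lm::nlsLM(E ~ model_E(R, De, R0), data = dat,
                           start = list(De = De0, R0 = Rmin),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  out <- structure(list(
    potential = morse_potential(cf[["De"]], fix_alpha, cf[["R0"]]),
    R0 = cf[["R0"]], De = cf[["De"]], alpha = fix_alpha,
    residual = sqrt(mean(residuals(fit)^2)), window = window,
    scale = scale, n_points = nrow(dat)), class = "morse_fit")
  attr(out, "reference") <- ref
  out
}
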