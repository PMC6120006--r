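# The multipolar inter-blob series:
#
#   V(R, Omega) = sum over (m, n) of V(mn)(R) * Theta(mn)(orientations)
#
# with angular parts
#
#   Theta(mn) = sum_{alpha, beta} (Rhat . rho_ab)^n |rho_ab|^(m-n),
#   rho_ab = rho_alpha - rho_beta (lab frame),
#
# where the sum runs over atoms alpha of blob A and beta of blob B, and the
# center separation follows the sign convention R = R_A - R_B (so Rhat
# points from B towards A). `angular_part_direct` evaluates the definition
# by the O(N_A N_B) double loop (the oracle); `angular_part_tensor`
# evaluates the same quantity from the interaction moment tensors alone.

#' Positional state of one blob
#'
#' @param template A `blob_template`.
#' @param position Center-of-mass position (Angstrom).
#' @param quaternion Orientation as a unit quaternion (w, x, y, z); body ->
#'   lab rotation. Default identity.
#' @return Object of class `blob_state` (caches the body-frame moment
#'   tensors of the template).
#' @export
blob_state <- function(template, position = c(0, 0, 0),
                       quaternion = c(1, 0, 0, 0)) {
  stopifnot(inherits(template, "blob_template"), length(position) == 3)
  if (abs(sqrt(sum(quaternion^2)) - 1) > 1e-10)
    quaternion <- quat_normalize(quaternion)
  structure(list(template = template,
                 tensors_body = compute_moment_tensors(template, 4),
                 position = as.numeric(position),
                 quaternion = as.numeric(quaternion)),
            class = "blob_state")
}

#' Lab-frame atom positions of a blob state
#' @param state A `blob_state`.
#' @return N x 3 matrix (Angstrom).
#' @export
lab_atoms <- function(state) {
  Q <- quat_to_matrix(state$quaternion)
  sweep(state$template$xyz %*% t(Q), 2, state$position, "+")
}

#' Lab-frame moment tensors of a blob state
#' @param state A `blob_state`.
#' @return A `moment_tensors` with `frame = "lab"`.
#' @export
lab_tensors <- function(state) {
  rotate_tensors(state$tensors_body, quat_to_matrix(state$quaternion))
}

.pair_geometry <- function(stateA, stateB) {
  Rvec <- stateA$position - stateB$position
  R <- sqrt(sum(Rvec^2))
  if (R < 1e-12) stop("coincident blob centers")
  list(Rvec = Rvec, R = R, Rhat = Rvec / R)
}

#' Angular part Theta(mn) by direct double summation (oracle)
#'
#' @param stateA,stateB `blob_state` objects.
#' @param m,n Series indices.
#' @return Theta(mn) in Angstrom^m.
#' @export
angular_part_direct <- function(stateA, stateB, m, n) {
  .check_mn(m, n)
  geo <- .pair_geometry(stateA, stateB)
  QA <- quat_to_matrix(stateA$quaternion)
  QB <- quat_to_matrix(stateB$quaternion)
  rhoA <- stateA$template$xyz %*% t(QA)
  rhoB <- stateB$template$xyz %*% t(QB)
  tot <- 0
  for (a in seq_len(nrow(rhoA))) {
    d <- sweep(-rhoB, 2, rhoA[a, ], "+")      # rho_alpha - rho_beta
    proj <- as.numeric(d %*% geo$Rhat)
    r2 <- rowSums(d^2)
    tot <- tot + sum(proj^n * r2^((m - n) / 2))
  }
  tot
}

# scalar invariants shared by the tensor-contraction angular parts and
# (in C++) the force/torque kernel
.pair_invariants <- function(TA, TB, Rhat) {
  v3 <- function(g3, u) {
    # g3 contracted twice with u: vector
    m <- matrix(g3, nrow = 3)                 # [i, (j,k)]
    as.numeric(m %*% as.numeric(outer(u, u)))
  }
  w4 <- function(g4, u) {
    m <- matrix(g4, nrow = 3)                 # [i, (j,k,l)]
    as.numeric(m %*% as.numeric(outer(outer(u, u), u)))
  }
  list(
    NA_ = TA$gamma0, NB_ = TB$gamma0,
    q1A = sum(TA$gamma1 * Rhat), q1B = sum(TB$gamma1 * Rhat),
    P11 = sum(TA$gamma1 * TB$gamma1),
    Q2A = as.numeric(Rhat %*% TA$gamma2 %*% Rhat),
    Q2B = as.numeric(Rhat %*% TB$gamma2 %*% Rhat),
    t2A = TA$tr2_gamma2, t2B = TB$tr2_gamma2,
    X2AB = as.numeric(Rhat %*% TA$gamma2 %*% TB$gamma1),
    X2BA = as.numeric(Rhat %*% TB$gamma2 %*% TA$gamma1),
    h3A_R = sum(TA$tr2_gamma3 * Rhat), h3B_R = sum(TB$tr2_gamma3 * Rhat),
    h3A_g1B = sum(TA$tr2_gamma3 * TB$gamma1),
    h3B_g1A = sum(TB$tr2_gamma3 * TA$gamma1),
    T3A = sum(v3(TA$gamma3, Rhat) * Rhat),
    T3B = sum(v3(TB$gamma3, Rhat) * Rhat),
    Z3A = sum(v3(TA$gamma3, Rhat) * TB$gamma1),
    Z3B = sum(v3(TB$gamma3, Rhat) * TA$gamma1),
    C22 = sum(TA$gamma2 * TB$gamma2),
    Y = as.numeric(Rhat %*% TA$gamma2 %*% TB$gamma2 %*% Rhat),
    tr4A = TA$tr4_gamma4, tr4B = TB$tr4_gamma4,
    H4A_RR = as.numeric(Rhat %*% TA$tr2_gamma4 %*% Rhat),
    H4B_RR = as.numeric(Rhat %*% TB$tr2_gamma4 %*% Rhat),
    T4A = sum(w4(TA$gamma4, Rhat) * Rhat),
    T4B = sum(w4(TB$gamma4, Rhat) * Rhat)
  )
}

#' Angular part Theta(mn) from moment tensors
#'
#' Evaluates the same quantity as [angular_part_direct()] without any atom
#' loops, from the lab-frame moment tensors of the two blobs contracted with
#' the unit center-separation vector.
#'
#' @param tensorsA,tensorsB Lab-frame `moment_tensors`.
#' @param Rhat Unit vector along R_A - R_B.
#' @param m,n Series indices.
#' @return Theta(mn) in Angstrom^m.
#' @export
angular_part_tensor <- function(tensorsA, tensorsB, Rhat, m, n) {
  .check_mn(m, n)
  if (tensorsA$frame != "lab" || tensorsB$frame != "lab")
    stop("angular_part_tensor requires lab-frame tensors (use rotate_tensors)")
  if (abs(sum(Rhat^2) - 1) > 1e-8) stop("Rhat must be a unit vector")
  iv <- .pair_invariants(tensorsA, tensorsB, Rhat)
  key <- paste(m, n)
  with(iv, switch(
    key,
    "0 0" = NA_ * NB_,
    "1 1" = NB_ * q1A - NA_ * q1B,
    "2 0" = NB_ * t2A + NA_ * t2B - 2 * P11,
    "2 2" = NB_ * Q2A + NA_ * Q2B - 2 * q1A * q1B,
    "3 1" = NB_ * h3A_R - NA_ * h3B_R + q1A * t2B - q1B * t2A -
            2 * X2AB + 2 * X2BA,
    "3 3" = NB_ * T3A - NA_ * T3B - 3 * Q2A * q1B + 3 * q1A * Q2B,
    "4 0" = NB_ * tr4A + NA_ * tr4B + 4 * C22 + 2 * t2A * t2B -
            4 * h3A_g1B - 4 * h3B_g1A,
    "4 2" = NB_ * H4A_RR + NA_ * H4B_RR + Q2A * t2B + t2A * Q2B + 4 * Y -
            2 * Z3A - 2 * Z3B - 2 * h3A_R * q1B - 2 * q1A * h3B_R,
    "4 4" = NB_ * T4A + NA_ * T4B + 6 * Q2A * Q2B -
            4 * T3A * q1B - 4 * q1A * T3B,
    stop("unhandled (m, n)")
  ))
}

#' Truncated coarse-grained inter-blob energy
#'
#' V(R, Omega) = sum over retained (m, n) of V(mn)(R) * Theta(mn). With a
#' `max_m = 0` scheme this reduces to N_A N_B U(R).
#'
#' @param stateA,stateB `blob_state` objects.
#' @param potential A `pair_potential` (the united-atom pair potential).
#' @param scheme A `truncation_scheme` (default keeps all m <= 4).
#' @return Energy, kcal/mol.
#' @export
interblob_energy <- function(stateA, stateB, potential,
                             scheme = truncation_scheme(4)) {
  geo <- .pair_geometry(stateA, stateB)
  TA <- lab_tensors(stateA)
  TB <- lab_tensors(stateB)
  tot <- 0
  for (r in seq_len(nrow(scheme$pairs))) {
    m <- scheme$pairs[[r, 1]]; n <- scheme$pairs[[r, 2]]
    tot <- tot + radial_coefficient(potential, geo$R, m, n) *
      angular_part_tensor(TA, TB, geo$Rhat, m, n)
  }
  unname(tot)
}

#' Exact all-atom inter-blob energy (oracle)
#'
#' E = sum over atom pairs of U(|r_alpha - r_beta|), the quantity the
#' truncated series approximates.
#'
#' @inheritParams interblob_energy
#' @return Energy, kcal/mol.
#' @export
allatom_energy <- function(stateA, stateB, potential) {
  ra <- lab_atoms(stateA)
  rb <- lab_atoms(stateB)
  tot <- 0
  for (a in seq_len(nrow(ra))) {
    d <- sweep(rb, 2, ra[a, ])
    tot <- tot + sum(potential_deriv(potential, sqrt(rowSums(d^2)), 0))
  }
  tot
}

#' Inter-blob force and torques from the truncated series
#'
#' Force on blob A (Newton's third law gives minus that on B) and the
#' torques on each blob about its own center of mass, from the gradient of
#' the truncated series energy. The analytic path differentiates the nine
#' angular-part invariants in closed form (compiled kernel); the
#' finite-difference path displaces/rotates the blobs symmetrically and is
#' retained as the oracle.
#'
#' @inheritParams interblob_energy
#' @param method "analytic" (default) or "fd".
#' @param h_t Translation step for the fd path (Angstrom).
#' @param h_r Rotation step for the fd path (radians).
#' @return List with `force` (on A, kcal/mol/A), `torque_A`, `torque_B`
#'   (kcal/mol, about each center of mass) and `energy` (kcal/mol).
#' @export
interblob_force_torque <- function(stateA, stateB, potential,
                                   scheme = truncation_scheme(4),
                                   method = c("analytic", "fd"),
                                   h_t = 1e-4, h_r = 1e-5) {
  method <- match.arg(method)
  if (method == "analytic") {
    out <- cg_pair_kernel_r(stateA, stateB, potential, scheme)
    return(out)
  }
  en <- function(sA, sB) interblob_energy(sA, sB, potential, scheme)
  force <- numeric(3)
  for (k in 1:3) {
    dp <- numeric(3); dp[k] <- h_t
    Ap <- stateA; Ap$position <- stateA$position + dp
    Am <- stateA; Am$position <- stateA$position - dp
    force[k] <- -(en(Ap, stateB) - en(Am, stateB)) / (2 * h_t)
  }
  rot_state <- function(state, axis, angle) {
    Q <- axis_angle_matrix(axis, angle)
    s <- state
    s$quaternion <- quat_normalize(quat_multiply(matrix_to_quat(Q),
                                                 state$quaternion))
    s
  }
  tq <- function(which_blob) {
    tau <- numeric(3)
    for (k in 1:3) {
      ax <- numeric(3); ax[k] <- 1
      if (which_blob == "A") {
        ep <- en(rot_state(stateA, ax, h_r), stateB)
        em <- en(rot_state(stateA, ax, -h_r), stateB)
      } else {
        ep <- en(stateA, rot_state(stateB, ax, h_r))
        em <- en(stateA, rot_state(stateB, ax, -h_r))
      }
      tau[k] <- -(ep - em) / (2 * h_r)
    }
    tau
  }
  list(force = force, torque_A = tq("A"), torque_B = tq("B"),
       energy = en(stateA, stateB))
}

# thin R wrapper assembling inputs for the compiled pair kernel
cg_pair_kernel_r <- function(stateA, stateB, potential, scheme) {
  TA <- lab_tensors(stateA)
  TB <- lab_tensors(stateB)
  pot <- .potential_spec(potential)
  res <- cg_pair_kernel_cpp(
    .tensor_pack(TA), .tensor_pack(TB),
    stateA$position - stateB$position,
    pot, scheme$max_m)
  list(force = res$force, torque_A = res$torque_A, torque_B = res$torque_B,
       energy = res$energy)
}

# potential spec understood by the C++ kernel
.potential_spec <- function(potential) {
  if (potential$kind == "morse")
    c(0, potential$De, potential$alpha, potential$R0, 0)
  else
    c(1, potential$epsilon, potential$sigma, potential$alpha, potential$beta)
}

# pack lab-frame tensors into the flat numeric layout used by C++:
# N, g1(3), G2(9), t2, h3(3), G3(27), tr4, H4(9), G4(81) -> length 134
.tensor_pack <- function(tensors) {
  c(tensors$gamma0, tensors$gamma1, as.numeric(tensors$gamma2),
    tensors$tr2_gamma2, tensors$tr2_gamma3, as.numeric(tensors$gamma3),
    tensors$tr4_gamma4, as.numeric(tensors$tr2_gamma4),
    as.numeric(tensors$gamma4))
}
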