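test_that("tensor-contraction angular parts equal the direct double sum", {
  pairs <- series_index_pairs(4)
  for (rep in 1:30) {
    st <- random_pair_state(rep)
    TA <- lab_tensors(st$A); TB <- lab_tensors(st$B)
    Rv <- st$A$position - st$B$position
    Rhat <- Rv / sqrt(sum(Rv^2))
    for (r in seq_len(nrow(pairs))) {
      m <- pairs[r, 1]; n <- pairs[r, 2]
      direct <- angular_part_direct(st$A, st$B, m, n)
      tens <- angular_part_tensor(TA, TB, Rhat, m, n)
      expect_lt(abs(direct - tens) / max(abs(direct), 1e-12), 1e-9)
    }
  }
})

test_that("angular parts match closed-form special cases", {
  st <- random_pair_state(7)
  TA <- lab_tensors(st$A); TB <- lab_tensors(st$B)
  Rv <- st$A$position - st$B$position
  Rhat <- Rv / sqrt(sum(Rv^2))
  NA_ <- TA$gamma0; NB_ <- TB$gamma0
  # (0,0): product of atom counts
  expect_equal(angular_part_tensor(TA, TB, Rhat, 0, 0), NA_ * NB_)
  # (1,1): Rhat . (N_B Gamma_A(1) - N_A Gamma_B(1))
  expect_equal(angular_part_tensor(TA, TB, Rhat, 1, 1),
               sum(Rhat * (NB_ * TA$gamma1 - NA_ * TB$gamma1)))
  # (2,0): N_B Tr2 Gamma_A(2) + N_A Tr2 Gamma_B(2) - 2 Gamma_A(1).Gamma_B(1)
  expect_equal(angular_part_tensor(TA, TB, Rhat, 2, 0),
               NB_ * TA$tr2_gamma2 + NA_ * TB$tr2_gamma2 -
                 2 * sum(TA$gamma1 * TB$gamma1))
  # (2,2): quadratic form expansion
  expect_equal(angular_part_tensor(TA, TB, Rhat, 2, 2),
               NB_ * as.numeric(Rhat %*% TA$gamma2 %*% Rhat) +
                 NA_ * as.numeric(Rhat %*% TB$gamma2 %*% Rhat) -
                 2 * sum(Rhat * TA$gamma1) * sum(Rhat * TB$gamma1))
  # body-frame tensors are rejected
  expect_error(angular_part_tensor(st$A$tensors_body, TB, Rhat, 0, 0),
               "lab-frame")
  # point blobs: all m >= 1 angular parts vanish
  pt <- blob_state(blob_template(matrix(0, 1, 3)), c(0, 0, 4))
  pt2 <- blob_state(blob_template(matrix(0, 1, 3)), c(0, 0, 0))
  expect_equal(angular_part_direct(pt, pt2, 2, 2), 0)
  expect_equal(angular_part_direct(pt, pt2, 4, 0), 0)
  expect_error(angular_part_direct(pt2, pt2, 2, 2), "coincident")
})

test_that("series energy reduces to N_A N_B U(R) for point blobs", {
  pot <- morse_potential(0.5, 1.2, 3.3)
  pt <- blob_template(matrix(0, 1, 3))
  for (R in c(2.5, 4, 8)) {
    sA <- blob_state(pt, c(0, 0, R))
    sB <- blob_state(pt, c(0, 0, 0))
    for (mm in c(0, 2, 4)) {
      expect_equal(interblob_energy(sA, sB, pot, truncation_scheme(mm)),
                   potential_deriv(pot, R, 0), tolerance = 1e-12)
    }
    expect_equal(allatom_energy(sA, sB, pot), potential_deriv(pot, R, 0))
  }
})

test_that("series energy is invariant under a global rigid rotation", {
  pot <- morse_potential(0.3, 1.1, 4)
  st <- random_pair_state(12, R = 9)
  e0 <- interblob_energy(st$A, st$B, pot)
  for (rep in 1:5) {
    Q <- random_rotation()
    qQ <- matrix_to_quat(Q)
    rot <- function(s) {
      s$position <- as.numeric(Q %*% s$position)
      s$quaternion <- quat_normalize(quat_multiply(qQ, s$quaternion))
      s
    }
    e1 <- interblob_energy(rot(st$A), rot(st$B), pot)
    expect_lt(abs(e1 - e0) / abs(e0), 1e-9)
  }
})

test_that("series converges to the all-atom sum with order and distance", {
  pot <- morse_potential(0.2, 1.1, 4)
  set.seed(31)
  rho_max <- 1.6
  errs <- array(NA_real_, c(3, 3, 12))   # ratio x order x draw
  ratios <- c(3, 5, 10)
  for (d in 1:12) {
    ba <- weighted_blob(5, 400 + d, scale = 0.8)
    bb <- weighted_blob(6, 500 + d, scale = 0.8)
    rmax <- max(blob_radius(ba), blob_radius(bb))
    for (ri in 1:3) {
      R <- ratios[ri] * rmax
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      sA <- blob_state(ba, R * dir, quat_normalize(rnorm(4)))
      sB <- blob_state(bb, c(0, 0, 0), quat_normalize(rnorm(4)))
      exact <- allatom_energy(sA, sB, pot)
      for (oi in 1:3) {
        vs <- interblob_energy(sA, sB, pot,
                               truncation_scheme(c(0, 2, 4)[oi]))
        errs[ri, oi, d] <- abs(vs - exact)
      }
    }
  }
  med <- apply(errs, c(1, 2), median)
  # median error non-increasing with order at each distance ratio
  for (ri in 1:3) {
    expect_lte(med[ri, 2], med[ri, 1] * (1 + 1e-12))
    expect_lte(med[ri, 3], med[ri, 2] * (1 + 1e-12))
  }
  # and vanishing with distance at fixed (highest) order
  expect_lt(med[3, 3], med[1, 3])
  expect_lt(med[3, 3] / abs(med[1, 1]), 1)
})

test_that("C60 pair series error shrinks monotonically with order", {
  # with an exponential (Morse) atomic potential the expansion parameter is
  # alpha * rho ~ 4.6 for C60, so low orders recover only part of the
  # all-atom energy even at large R; the error must still fall with order
  c60 <- c60_cached()
  pot <- atomic_carbon_morse()
  ori <- c(1, 0, 0, 0)
  sA <- blob_state(c60, c(0, 0, 13), ori)
  sB <- blob_state(c60, c(0, 0, 0), ori)
  exact <- allatom_energy(sA, sB, pot)
  errs <- vapply(c(0, 2, 4), function(mm)
    abs(interblob_energy(sA, sB, pot, truncation_scheme(mm)) - exact),
    numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.75 * errs[1])
  # all-atom energy is symmetric under swapping the two blobs
  expect_equal(allatom_energy(sB, sA, pot), exact)
})

test_that("analytic force and torques agree with finite differences", {
  pot <- morse_potential(0.4, 1.1, 4.2)
  for (seed in c(3, 8)) {
    st <- random_pair_state(seed, R = 7)
    for (mm in c(0, 2, 3, 4)) {
      sch <- truncation_scheme(mm)
      an <- interblob_force_torque(st$A, st$B, pot, sch, method = "analytic")
      fd <- interblob_force_torque(st$A, st$B, pot, sch, method = "fd")
      expect_equal(an$energy, fd$energy, tolerance = 1e-10)
      expect_lt(max(abs(an$force - fd$force)) / max(abs(fd$force)), 1e-5)
      tden <- max(abs(fd$torque_A), abs(fd$torque_B), 1e-8)
      expect_lt(max(abs(an$torque_A - fd$torque_A)) / tden, 1e-5)
      expect_lt(max(abs(an$torque_B - fd$torque_B)) / tden, 1e-5)
    }
  }
})

test_that("point blobs feel a central force and no torque", {
  pot <- morse_potential(0.5, 1.2, 3.3)
  pt <- blob_template(matrix(0, 1, 3))
  sA <- blob_state(pt, c(0, 0, 5)); sB <- blob_state(pt, c(0, 0, 0))
  out <- interblob_force_torque(sA, sB, pot, truncation_scheme(4))
  expect_equal(out$force, c(0, 0, -potential_deriv(pot, 5, 1)),
               tolerance = 1e-12)
  expect_equal(out$torque_A, c(0, 0, 0))
  expect_equal(out$torque_B, c(0, 0, 0))
})

test_that("inversion-symmetric blobs feel vanishing torque under even-only schemes", {
  # C60 has Gamma(1) = Gamma(3) = 0 and nearly isotropic Gamma(2); torques
  # from the m <= 2 scheme must vanish to numerical precision
  c60 <- c60_cached()
  pot <- morse_potential(0.00177, 1.3, 9.65)
  sA <- blob_state(c60, c(0, 0, 10.2), quat_normalize(c(0.9, 0.2, -0.1, 0.33)))
  sB <- blob_state(c60, c(0, 0, 0), quat_normalize(c(0.7, -0.4, 0.5, 0.1)))
  out <- interblob_force_torque(sA, sB, pot, truncation_scheme(2))
  fmag <- sqrt(sum(out$force^2))
  expect_lt(sqrt(sum(out$torque_A^2)) / fmag, 1e-3)
  expect_lt(sqrt(sum(out$torque_B^2)) / fmag, 1e-3)
})
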