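test_that("moment tensors match hand-computed examples", {
  # single atom at the origin: Gamma(0) = 1, everything else 0
  single <- blob_template(matrix(c(0.3, -0.1, 0.7), 1, 3))
  mt <- compute_moment_tensors(single, 4)
  expect_equal(mt$gamma0, 1)
  expect_equal(mt$gamma1, c(0, 0, 0))
  expect_equal(max(abs(mt$gamma4)), 0)

  # two atoms at (+-1, 0, 0): Gamma(2) has only the (1,1) component = 2
  two <- blob_template(rbind(c(1, 0, 0), c(-1, 0, 0)))
  mt2 <- compute_moment_tensors(two, 2)
  expect_equal(mt2$gamma2, diag(c(2, 0, 0)))
  expect_equal(mt2$tr2_gamma2, 2)
  expect_equal(mt2$gamma1, c(0, 0, 0))

  # traces agree with independent contractions of the full tensors
  b <- weighted_blob(9, seed = 5)
  mt3 <- compute_moment_tensors(b, 4)
  expect_equal(mt3$tr2_gamma2, sum(diag(mt3$gamma2)))
  expect_equal(mt3$tr2_gamma3,
               vapply(1:3, function(i) sum(diag(mt3$gamma3[, , i])),
                      numeric(1)))
  tr2g4 <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    tr2g4[i, j] <- sum(diag(mt3$gamma4[, , i, j]))
  expect_equal(mt3$tr2_gamma4, tr2g4)
  expect_equal(mt3$tr4_gamma4, sum(rowSums(b$xyz^2)^2))
})

test_that("blob templates are re-centered and validated", {
  b <- blob_template(matrix(rnorm(30) + 5, ncol = 3), masses = runif(10, 1, 2))
  com <- colSums(b$xyz * b$masses) / sum(b$masses)
  expect_lt(max(abs(com)), 1e-9)
  expect_error(blob_template(matrix(numeric(0), 0, 3)), "at least one atom")
  expect_error(blob_template(matrix(c(1, NA, 0), 1, 3)), "finite")
  expect_error(compute_moment_tensors(list()), "blob_template")
})

test_that("symmetric index map reproduces the flat rank-major layout", {
  # component counts per rank: 1, 3, 6, 10, 15
  expect_equal(vapply(0:4, count_components, numeric(1)),
               c(1, 3, 6, 10, 15))
  expect_equal(count_components(2, 3), 6)
  expect_equal(count_components(4, 3), length(sym_tuples(4, 3)))

  # anchor locations of the layout
  expect_identical(sym_index(integer(0)), 0L)
  expect_identical(sym_index(1), 1L)
  expect_identical(sym_index(c(1, 1)), 4L)
  expect_identical(sym_index(c(3, 3)), 9L)
  expect_identical(sym_index(c(1, 1, 1)), 10L)
  expect_identical(sym_index(c(3, 3, 3)), 19L)
  expect_identical(sym_index(c(1, 1, 1, 1)), 20L)
  expect_identical(sym_index(c(3, 3, 3, 3)), 34L)

  # bijectivity rank by rank: all sorted tuples map onto a contiguous
  # gap-free range
  off <- 0L
  for (m in 0:4) {
    locs <- vapply(sym_tuples(m), sym_index, integer(1))
    expect_identical(sort(locs), off + seq_len(count_components(m)) - 1L)
    off <- off + as.integer(count_components(m))
  }

  # unsorted tuples are canonicalized by sorting
  expect_identical(sym_index(c(3, 1, 2)), sym_index(c(1, 2, 3)))
  expect_identical(sym_index(c(2, 1, 1, 3)), sym_index(c(1, 1, 2, 3)))
  expect_error(sym_index(c(0, 1)), "1..N")
  expect_error(sym_index(c(1, 4)), "1..N")
})

test_that("stored value is reached through any index permutation", {
  b <- weighted_blob(6, seed = 9)
  mt <- compute_moment_tensors(b, 4)
  flat <- tensors_to_flat(mt)
  perms <- list(c(2, 4, 1, 3), c(4, 3, 2, 1), c(1, 3, 2, 4))
  for (t in sym_tuples(4)) {
    stored <- flat[[sym_index(t) + 1L]]
    for (p in perms)
      expect_identical(tensor_element(mt, t[p]), stored)
  }
})

test_that("rotation oracle: rotating tensors equals recomputing from rotated atoms", {
  set.seed(101)
  for (rep in 1:100) {
    b <- weighted_blob(sample(2:8, 1), seed = 1000 + rep)
    Q <- random_rotation()
    rotated <- rotate_tensors(compute_moment_tensors(b, 4), Q)
    recomputed <- compute_moment_tensors(
      blob_template(b$xyz %*% t(Q), masses = b$masses), 4)
    ref <- max(abs(recomputed$gamma4))
    expect_lt(max(abs(rotated$gamma4 - recomputed$gamma4)) / ref, 1e-10)
    expect_lt(max(abs(rotated$gamma3 - recomputed$gamma3)) /
                max(max(abs(recomputed$gamma3)), 1e-12), 1e-9)
    expect_equal(rotated$gamma2, recomputed$gamma2, tolerance = 1e-10)
    expect_equal(rotated$tr2_gamma4, recomputed$tr2_gamma4,
                 tolerance = 1e-10)
  }
  # scalar traces are rotation invariants
  b <- weighted_blob(7, seed = 77)
  mt <- compute_moment_tensors(b, 4)
  rt <- rotate_tensors(mt, random_rotation())
  expect_identical(rt$tr2_gamma2, mt$tr2_gamma2)
  expect_identical(rt$tr4_gamma4, mt$tr4_gamma4)
  expect_identical(rt$frame, "lab")
  # identity leaves everything unchanged
  id <- rotate_tensors(mt, diag(3))
  expect_equal(id$gamma4, mt$gamma4)
  expect_error(rotate_tensors(mt, diag(3) * 1.01), "orthonormal")
})

test_that("moment tensors scale as s^m under coordinate scaling", {
  b <- weighted_blob(5, seed = 3)
  s <- 2.5
  scaled <- blob_template(b$xyz * s, masses = b$masses)
  m1 <- compute_moment_tensors(b, 4)
  m2 <- compute_moment_tensors(scaled, 4)
  expect_equal(m2$gamma1, s * m1$gamma1)
  expect_equal(m2$gamma2, s^2 * m1$gamma2)
  expect_equal(m2$gamma3, s^3 * m1$gamma3)
  expect_equal(m2$gamma4, s^4 * m1$gamma4)
  expect_equal(m2$tr4_gamma4, s^4 * m1$tr4_gamma4)
})

test_that("tensor tables round-trip through the plain-text format", {
  b <- weighted_blob(8, seed = 21)
  mt <- compute_moment_tensors(b, 4)
  path <- tempfile(fileext = ".tsv")
  write_tensor_table(mt, path)
  back <- read_tensor_table(path)
  expect_equal(tensors_to_flat(back), tensors_to_flat(mt), tolerance = 1e-12)
  expect_equal(back$tr2_gamma3, mt$tr2_gamma3, tolerance = 1e-12)
  unlink(path)
})

test_that("published C60 tensor table loads as a fixture", {
  path <- system.file("extdata", "c60_moment_tensors_table.txt",
                      package = "cgrb")
  expect_true(nzchar(path))
  mt <- read_tensor_table(path)
  expect_equal(mt$gamma0, 60)
  # inversion symmetry: odd ranks essentially zero
  expect_lt(sqrt(sum(mt$gamma1^2)), 1e-3)
  expect_lt(max(abs(mt$gamma3)), 0.1)
  # near-isotropic rank 2; trace equals the sum of the diagonal
  expect_equal(mt$tr2_gamma2, sum(diag(mt$gamma2)))
  expect_equal(unname(diag(mt$gamma2) / mt$tr2_gamma2), rep(1 / 3, 3),
               tolerance = 1e-3)
})
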