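# Interaction moment tensors and their symmetric flat storage.
#
# A rank-m moment tensor of a blob is the sum over its atoms of the m-fold
# outer product of the atom position vectors about the center of mass:
#   Gamma(0) = N_atoms, Gamma(1) = sum rho, Gamma(2) = sum rho rho, ...
# up to rank 4, together with the trace contractions
#   Tr2 Gamma(2) = sum |rho|^2          (scalar)
#   Tr2 Gamma(3) = sum |rho|^2 rho      (vector)
#   Tr2 Gamma(4) = sum |rho|^2 rho rho  (rank 2)
#   Tr4 Gamma(4) = sum |rho|^4          (scalar)

#' Construct a rigid-blob template
#'
#' A blob is a rigid group of atoms treated as a single coarse-grained
#' interaction site. Positions are re-centered so the center of mass sits at
#' the origin (body frame).
#'
#' @param positions N x 3 matrix of atom coordinates (Angstrom).
#' @param masses Atom masses (amu); a scalar is recycled. Default 12.011
#'   (carbon).
#' @param label Optional text label.
#' @return Object of class `blob_template` with elements `xyz` (N x 3,
#'   center of mass at origin), `masses`, `label`.
#' @export
blob_template <- function(positions, masses = 12.011, label = "blob") {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("a blob needs at least one atom")
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (!all(is.finite(positions))) stop("non-finite atom coordinates")
  masses <- rep_len(as.numeric(masses), nrow(positions))
  if (any(masses <= 0)) stop("atom masses must be positive")
  com <- colSums(positions * masses) / sum(masses)
  xyz <- sweep(positions, 2, com)
  structure(list(xyz = unname(xyz), masses = masses, label = label),
            class = "blob_template")
}

#' @export
print.blob_template <- function(x, ...) {
  cat(sprintf("blob_template '%s': %d atoms, total mass %.3f amu, max |rho| %.3f A\n",
              x$label, nrow(x$xyz), sum(x$masses),
              sqrt(max(rowSums(x$xyz^2)))))
  invisible(x)
}

#' Maximum atom distance from the blob center
#' @param template A `blob_template`.
#' @return Scalar (Angstrom).
#' @export
blob_radius <- function(template) sqrt(max(rowSums(template$xyz^2)))

#' Number of independent components of a symmetric tensor
#'
#' A symmetric rank-m tensor in N dimensions has choose(N + m - 1, m)
#' independent components.
#'
#' @param rank Tensor rank (>= 0).
#' @param N Spatial dimension (default 3).
#' @return Integer count.
#' @export
count_components <- function(rank, N = 3) {
  if (rank < 0 || N < 1) stop("rank must be >= 0 and N >= 1")
  choose(N + rank - 1, rank)
}

#' All sorted index tuples of a symmetric rank-m tensor
#'
#' Row-major (lexicographic) enumeration of non-decreasing tuples over 1..N,
#' i.e. the storage order of the flat layout.
#'
#' @param rank Tensor rank (0 gives a single empty tuple).
#' @param N Spatial dimension.
#' @return List of integer vectors (length `rank`).
#' @export
sym_tuples <- function(rank, N = 3) {
  if (rank == 0) return(list(integer(0)))
  rec <- function(len, lo) {
    if (len == 0) return(list(integer(0)))
    out <- list()
    for (v in lo:N)
      out <- c(out, lapply(rec(len - 1, v), function(t) c(v, t)))
    out
  }
  rec(rank, 1L)
}

# lexicographic position (0-based) of a sorted tuple among all sorted tuples
.sym_rank_position <- function(idx, N) {
  m <- length(idx)
  if (m == 0) return(0L)
  pos <- 0
  prev <- 1L
  for (k in seq_len(m)) {
    L <- m - k                       # remaining slots after this one
    if (idx[k] > prev) for (v in prev:(idx[k] - 1L))
      pos <- pos + count_components(L, N - v + 1L)
    prev <- idx[k]
  }
  as.integer(pos)
}

#' Flat storage location of a symmetric tensor element
#'
#' Ranks 0..4 are stored contiguously (rank-major), each rank enumerated
#' row-major over sorted index tuples, so that rank 0 occupies location 0,
#' rank 1 locations 1..3, rank 2 locations 4..9, rank 3 locations 10..19 and
#' rank 4 locations 20..34. Unsorted index tuples are canonicalized by
#' sorting (the tensors are symmetric).
#'
#' @param indices Integer vector of axis labels in 1..N; `integer(0)` (or
#'   `NULL`) addresses the rank-0 scalar.
#' @param N Spatial dimension (default 3).
#' @return 0-based storage location (integer).
#' @export
sym_index <- function(indices, N = 3) {
  if (is.null(indices)) indices <- integer(0)
  indices <- as.integer(indices)
  m <- length(indices)
  if (m > 4) stop("ranks above 4 are not supported")
  if (m > 0 && (any(indices < 1L) || any(indices > N)))
    stop("axis labels must lie in 1..N")
  indices <- sort(indices)
  offset <- if (m == 0) 0L else sum(vapply(0:(m - 1), count_components,
                                           numeric(1), N = N))
  as.integer(offset + .sym_rank_position(indices, N))
}

#' Storage labels of the flat moment-tensor layout
#'
#' @param max_rank Highest rank included (default 4).
#' @return Character vector "G0".."G34" of length `sum(count_components(0:max_rank))`.
#' @export
sym_labels <- function(max_rank = 4) {
  n <- sum(vapply(0:max_rank, count_components, numeric(1)))
  paste0("G", seq_len(n) - 1L)
}

.trace_set <- function(xyz) {
  r2 <- rowSums(xyz^2)
  list(
    tr2_gamma2 = sum(r2),
    tr2_gamma3 = colSums(xyz * r2),
    tr2_gamma4 = crossprod(xyz * sqrt(r2)),   # sum r^2 rho rho
    tr4_gamma4 = sum(r2^2)
  )
}

#' Interaction moment tensors of a blob
#'
#' Computes Gamma(m) = sum over atoms of the m-fold outer product of the
#' atom position vectors (body frame, about the center of mass), for
#' m = 0..`max_rank`, plus the trace contractions used by the angular parts
#' of the potential series.
#'
#' @param blob A `blob_template`.
#' @param max_rank Highest rank, 0..4 (default 4).
#' @return Object of class `moment_tensors`: list with `gamma0` (scalar =
#'   atom count), `gamma1` (3-vector), `gamma2` (3x3), `gamma3` (3x3x3),
#'   `gamma4` (3x3x3x3), traces `tr2_gamma2`, `tr2_gamma3`, `tr2_gamma4`,
#'   `tr4_gamma4`, and `frame` ("body" or "lab").
#' @export
compute_moment_tensors <- function(blob, max_rank = 4) {
  if (!inherits(blob, "blob_template")) stop("blob must be a blob_template")
  if (max_rank < 0 || max_rank > 4) stop("max_rank must be in 0..4")
  xyz <- blob$xyz
  n <- nrow(xyz)
  out <- list(gamma0 = n,
              gamma1 = NULL, gamma2 = NULL, gamma3 = NULL, gamma4 = NULL,
              max_rank = as.integer(max_rank), frame = "body")
  if (max_rank >= 1) out$gamma1 <- colSums(xyz)
  if (max_rank >= 2) out$gamma2 <- crossprod(xyz)
  if (max_rank >= 3) {
    # compute each independent component once (sorted tuple) and replicate
    # over permutations, so symmetry holds exactly, not just to round-off
    g3 <- array(0, c(3, 3, 3))
    perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1))
    for (t in sym_tuples(3)) {
      v <- sum(xyz[, t[1]] * xyz[, t[2]] * xyz[, t[3]])
      for (p in perms3) g3[t[p[1]], t[p[2]], t[p[3]]] <- v
    }
    out$gamma3 <- g3
  }
  if (max_rank >= 4) {
    g4 <- array(0, c(3, 3, 3, 3))
    perms4 <- .permutations4()
    for (t in sym_tuples(4)) {
      v <- sum(xyz[, t[1]] * xyz[, t[2]] * xyz[, t[3]] * xyz[, t[4]])
      for (p in perms4) g4[t[p[1]], t[p[2]], t[p[3]], t[p[4]]] <- v
    }
    out$gamma4 <- g4
  }
  if (max_rank >= 2) {
    tr <- .trace_set(xyz)
    out$tr2_gamma2 <- tr$tr2_gamma2
    if (max_rank >= 3) out$tr2_gamma3 <- tr$tr2_gamma3
    if (max_rank >= 4) {
      out$tr2_gamma4 <- tr$tr2_gamma4
      out$tr4_gamma4 <- tr$tr4_gamma4
    }
  }
  class(out) <- "moment_tensors"
  out
}

#' @export
print.moment_tensors <- function(x, ...) {
  cat(sprintf("moment_tensors (frame = %s, max_rank = %d): Gamma(0) = %g",
              x$frame, x$max_rank, x$gamma0))
  if (x$max_rank >= 2)
    cat(sprintf(", Tr2 Gamma(2) = %.5g A^2", x$tr2_gamma2))
  cat("\n")
  invisible(x)
}

#' Rotate moment tensors into another frame
#'
#' Applies a rotation matrix to every index of every tensor (body -> lab
#' frame). Scalar traces are rotation invariants; vector/matrix traces are
#' rotated directly.
#'
#' @param tensors A `moment_tensors` object.
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @return Rotated `moment_tensors` with `frame = "lab"`.
#' @export
rotate_tensors <- function(tensors, rotation) {
  if (!inherits(tensors, "moment_tensors")) stop("not a moment_tensors object")
  if (!is_rotation_matrix(rotation, tol = 1e-10))
    stop("rotation must be orthonormal (det +1) within 1e-10")
  Q <- rotation
  out <- tensors
  mr <- tensors$max_rank
  if (mr >= 1) out$gamma1 <- as.numeric(Q %*% tensors$gamma1)
  if (mr >= 2) {
    out$gamma2 <- Q %*% tensors$gamma2 %*% t(Q)
    out$tr2_gamma2 <- tensors$tr2_gamma2
  }
  if (mr >= 3) {
    # apply Q to the leading index, then rotate the index order; after 3
    # rounds every index is transformed and the original order is restored
    g3 <- tensors$gamma3
    for (r in 1:3) {
      g3 <- array(Q %*% matrix(g3, nrow = 3), c(3, 3, 3))
      g3 <- aperm(g3, c(2, 3, 1))
    }
    out$gamma3 <- g3
    out$tr2_gamma3 <- as.numeric(Q %*% tensors$tr2_gamma3)
  }
  if (mr >= 4) {
    g4 <- tensors$gamma4
    for (r in 1:4) {
      g4 <- array(Q %*% matrix(g4, nrow = 3), c(3, 3, 3, 3))
      g4 <- aperm(g4, c(2, 3, 4, 1))
    }
    out$gamma4 <- g4
    out$tr2_gamma4 <- Q %*% tensors$tr2_gamma4 %*% t(Q)
    out$tr4_gamma4 <- tensors$tr4_gamma4
  }
  out$frame <- "lab"
  out
}

#' Read a tensor element through arbitrary (unsorted) indices
#' @param tensors A `moment_tensors` object.
#' @param indices Integer vector (length = rank) of axis labels in 1..3;
#'   `integer(0)` for the rank-0 scalar.
#' @return Numeric scalar.
#' @export
tensor_element <- function(tensors, indices) {
  m <- length(indices)
  switch(as.character(m),
         "0" = tensors$gamma0,
         "1" = tensors$gamma1[indices],
         "2" = tensors$gamma2[indices[1], indices[2]],
         "3" = tensors$gamma3[indices[1], indices[2], indices[3]],
         "4" = tensors$gamma4[indices[1], indices[2], indices[3], indices[4]],
         stop("rank above 4"))
}

#' Flatten moment tensors into the 35-slot storage vector
#'
#' One value per independent component, ordered by [sym_index()] (ranks 0..4
#' contiguous, sorted tuples row-major within each rank).
#'
#' @param tensors A `moment_tensors` with `max_rank = 4`.
#' @return Named numeric vector of length 35 (names "G0".."G34").
#' @export
tensors_to_flat <- function(tensors) {
  if (tensors$max_rank < 4) stop("flat storage expects max_rank = 4")
  out <- numeric(35)
  for (m in 0:4) for (t in sym_tuples(m)) {
    out[sym_index(t) + 1L] <- tensor_element(tensors, t)
  }
  names(out) <- sym_labels(4)
  out
}

#' Rebuild moment tensors from the flat storage vector
#'
#' Inverse of [tensors_to_flat()]: symmetric components are replicated over
#' all index permutations and the trace contractions are recomputed.
#'
#' @param flat Numeric vector of length 35 in storage order.
#' @param frame Frame tag ("body" or "lab").
#' @return A `moment_tensors` object.
#' @export
flat_to_tensors <- function(flat, frame = "body") {
  if (length(flat) != 35) stop("flat storage vector must have length 35")
  out <- list(gamma0 = flat[[1]],
              gamma1 = numeric(3), gamma2 = matrix(0, 3, 3),
              gamma3 = array(0, c(3, 3, 3)), gamma4 = array(0, c(3, 3, 3, 3)),
              max_rank = 4L, frame = frame)
  for (t in sym_tuples(1)) out$gamma1[t] <- flat[[sym_index(t) + 1L]]
  for (t in sym_tuples(2)) {
    v <- flat[[sym_index(t) + 1L]]
    out$gamma2[t[1], t[2]] <- v; out$gamma2[t[2], t[1]] <- v
  }
  perms3 <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (t in sym_tuples(3)) {
    v <- flat[[sym_index(t) + 1L]]
    for (p in perms3) out$gamma3[t[p[1]], t[p[2]], t[p[3]]] <- v
  }
  perms4 <- .permutations4()
  for (t in sym_tuples(4)) {
    v <- flat[[sym_index(t) + 1L]]
    for (p in perms4) out$gamma4[t[p[1]], t[p[2]], t[p[3]], t[p[4]]] <- v
  }
  # recompute traces by contraction
  out$tr2_gamma2 <- sum(diag(out$gamma2))
  out$tr2_gamma3 <- vapply(1:3, function(i) sum(diag(out$gamma3[, , i])),
                           numeric(1))
  t2g4 <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) t2g4[i, j] <- sum(diag(out$gamma4[, , i, j]))
  out$tr2_gamma4 <- t2g4
  out$tr4_gamma4 <- sum(diag(t2g4))
  class(out) <- "moment_tensors"
  out
}

.permutations4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (c in setdiff(1:4, c(a, b)))
    out[[length(out) + 1L]] <- c(a, b, c, setdiff(1:4, c(a, b, c)))
  out
}

#' Write moment tensors as a plain-text key-value table
#'
#' Columns: rank, storage label (G0..G34), sorted index tuple, value.
#' The format mirrors the flat storage layout so published tensor tables can
#' be used directly as fixtures.
#'
#' @param tensors A `moment_tensors` (max_rank 4).
#' @param path Output file.
#' @export
write_tensor_table <- function(tensors, path) {
  flat <- tensors_to_flat(tensors)
  rows <- data.frame(
    rank = unlist(lapply(0:4, function(m) rep(m, count_components(m)))),
    label = names(flat),
    indices = unlist(lapply(0:4, function(m)
      vapply(sym_tuples(m), function(t)
        if (length(t)) paste(t, collapse = "") else "-", character(1)))),
    value = unname(flat))
  write.table(rows, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read moment tensors from a key-value table
#' @param path File written by [write_tensor_table()] (or hand-prepared in
#'   the same layout).
#' @param frame Frame tag for the result.
#' @return A `moment_tensors` object.
#' @export
read_tensor_table <- function(path, frame = "body") {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "character",
                                   "numeric"))
  flat <- numeric(35)
  for (r in seq_len(nrow(tab))) {
    lab <- tab$label[r]
    loc <- as.integer(sub("^G", "", lab))
    if (is.na(loc) || loc < 0 || loc > 34)
      stop("bad storage label: ", lab)
    flat[loc + 1L] <- tab$value[r]
  }
  flat_to_tensors(flat, frame = frame)
}
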