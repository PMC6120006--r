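# Molecular geometry: truncated-icosahedron C60 builder, XYZ input/output,
# random blob fixtures.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                     Ar = 39.948, X = 12.011)

#' Build a C60 fullerene template
#'
#' Places 60 carbon atoms at the vertices of a truncated icosahedron with
#' full icosahedral (Ih) symmetry. The two crystallographically distinct
#' edge classes are set independently: pentagon edges carry the C-C single
#' bonds, hexagon-hexagon shared edges the shorter C=C double bonds.
#'
#' Construction: the 60 vertices are the points A + t (B - A) over directed
#' edges (A, B) of a regular icosahedron. The pentagon edge length is then
#' t*a and the hexagon-hexagon edge (1 - 2t)*a, with a the icosahedron edge,
#' so the two requested bond lengths fix t = p / (h + 2 p) and the overall
#' scale exactly.
#'
#' @param bond_pentagon Pentagon edge (C-C single bond), Angstrom.
#'   Default 1.450.
#' @param bond_hexagon Hexagon-hexagon shared edge (C=C double bond),
#'   Angstrom. Default 1.386.
#' @return A `blob_template` of 60 carbons (mass 12.011 amu each) with
#'   attributes `pentagon_axes` (12 unit vectors through pentagon-face
#'   centers) and `hexagon_axes` (20 unit vectors through hexagon-face
#'   centers).
#' @export
build_c60 <- function(bond_pentagon = 1.450, bond_hexagon = 1.386) {
  stopifnot(bond_pentagon > 0, bond_hexagon > 0)
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
    c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  a_unit <- 2                      # icosahedron edge at this coordinate scale
  t <- bond_pentagon / (bond_hexagon + 2 * bond_pentagon)
  scale <- (bond_pentagon / t) / a_unit
  ico <- ico * scale

  d2 <- as.matrix(dist(ico))
  adj <- abs(d2 - a_unit * scale) < 1e-9 * max(1, a_unit * scale)
  verts <- NULL
  for (i in 1:12) for (j in 1:12) if (i != j && adj[i, j])
    verts <- rbind(verts, ico[i, ] + t * (ico[j, ] - ico[i, ]))
  stopifnot(nrow(verts) == 60)

  tmpl <- blob_template(verts, masses = 12.011, label = "C60")
  pent <- ico / sqrt(rowSums(ico^2))
  hexes <- NULL
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12)
    if (adj[i, j] && adj[j, k] && adj[i, k])
      hexes <- rbind(hexes, (ico[i, ] + ico[j, ] + ico[k, ]) / 3)
  hexes <- hexes / sqrt(rowSums(hexes^2))
  attr(tmpl, "pentagon_axes") <- unname(pent)
  attr(tmpl, "hexagon_axes") <- unname(hexes)
  tmpl
}

#' Reproducible random blob fixture
#'
#' Gaussian atom cloud with the requested length scale, re-centered so the
#' center of mass is at the origin. Unit masses.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param radius_scale Standard deviation of the coordinates (Angstrom).
#' @param seed Integer seed (local to this call).
#' @return A `blob_template`.
#' @export
random_blob <- function(n_atoms, radius_scale = 1, seed = 1) {
  stopifnot(n_atoms >= 1)
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(seed)
  xyz <- matrix(rnorm(3 * n_atoms, sd = radius_scale), ncol = 3)
  if (n_atoms == 1) xyz[] <- 0
  blob_template(xyz, masses = 1, label = sprintf("random-%d", n_atoms))
}

#' Write atoms to an XYZ file
#'
#' @param x A `blob_template` or an N x 3 coordinate matrix.
#' @param path Output file.
#' @param comment Comment line (second line of the XYZ format).
#' @param elements Element symbols, recycled (default "C").
#' @export
write_xyz <- function(x, path, comment = "", elements = "C") {
  xyz <- if (inherits(x, "blob_template")) x$xyz else as.matrix(x)
  elements <- rep_len(elements, nrow(xyz))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(xyz)), comment), con)
  writeLines(sprintf("%s %.10f %.10f %.10f", elements,
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}

#' Read a blob template from an XYZ file
#'
#' @param path XYZ file (element, x, y, z per atom line).
#' @param masses Optional explicit masses; by default looked up from the
#'   element symbols (unknown symbols get the carbon mass).
#' @return A `blob_template` (re-centered to zero center of mass).
#' @export
read_xyz <- function(path, masses = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed XYZ file '", path, "': fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("malformed XYZ file '", path, "': line 1 must be the atom count")
  if (length(lines) < 2 + n)
    stop("malformed XYZ file '", path, "': expected ", n, " atom lines")
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[2 + i]), "\\s+")[[1]]
    if (length(parts) < 4)
      stop("malformed XYZ file '", path, "' at line ", 2 + i,
           ": need 'element x y z'")
    el[i] <- parts[1]
    xyz[i, ] <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz[i, ])))
      stop("malformed XYZ file '", path, "' at line ", 2 + i,
           ": non-numeric coordinate")
  }
  if (is.null(masses)) {
    masses <- .element_masses[el]
    masses[is.na(masses)] <- 12.011
  }
  blob_template(xyz, masses = masses,
                label = sub("\\.xyz$", "", basename(path)))
}
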