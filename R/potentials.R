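# Pair potentials with high-order analytic radial derivatives, and the
# radial coefficients V(mn) of the multipolar series:
#
#   V(mn) = [1 / (n! (m-n)!!)] R^n (1/R d/dR)^((m+n)/2) U(R)
#
# with (m, n) restricted so m+n and m-n are both even and 0 <= n <= m
# (n = m, m-2, ..., down to 0 or 1).

#' Morse pair potential
#'
#' U(R) = De * (exp(-2 a (R - R0)) - 2 exp(-a (R - R0))).
#'
#' @param De Well depth (kcal/mol).
#' @param alpha Width parameter a (1/Angstrom).
#' @param R0 Equilibrium distance (Angstrom).
#' @return Object of class `pair_potential`.
#' @export
morse_potential <- function(De, alpha, R0) {
  stopifnot(De > 0, alpha > 0, R0 > 0)
  structure(list(kind = "morse", De = De, alpha = alpha, R0 = R0,
                 derivative_order_supported = 8L),
            class = "pair_potential")
}

#' Lennard-Jones (Mie) pair potential
#'
#' U(R) = 4 eps * ((sigma/R)^alpha - (sigma/R)^beta), with general exponents
#' alpha > beta > 0 (12-6 by default).
#'
#' @param epsilon Well depth parameter eps (kcal/mol).
#' @param sigma Zero-crossing distance (Angstrom).
#' @param alpha Repulsive exponent (default 12).
#' @param beta Attractive exponent (default 6).
#' @return Object of class `pair_potential`.
#' @export
lj_potential <- function(epsilon, sigma, alpha = 12, beta = 6) {
  stopifnot(epsilon > 0, sigma > 0, alpha > beta, beta > 0)
  structure(list(kind = "lennard_jones", epsilon = epsilon, sigma = sigma,
                 alpha = alpha, beta = beta,
                 derivative_order_supported = 8L),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  if (x$kind == "morse")
    cat(sprintf("Morse potential: De = %g kcal/mol, alpha = %g 1/A, R0 = %g A\n",
                x$De, x$alpha, x$R0))
  else
    cat(sprintf("LJ potential: eps = %g kcal/mol, sigma = %g A, exponents %g-%g\n",
                x$epsilon, x$sigma, x$alpha, x$beta))
  invisible(x)
}

#' Evaluate a pair potential or one of its radial derivatives
#'
#' @param potential A `pair_potential`.
#' @param R Separation(s), Angstrom (> 0).
#' @param deriv Derivative order d^k U / dR^k, 0..8.
#' @return Numeric vector, kcal/mol / Angstrom^deriv.
#' @export
potential_deriv <- function(potential, R, deriv = 0) {
  stopifnot(all(R > 0), deriv >= 0, deriv <= 8)
  if (potential$kind == "morse") {
    a <- potential$alpha
    e2 <- exp(-2 * a * (R - potential$R0))
    e1 <- exp(-a * (R - potential$R0))
    potential$De * ((-2 * a)^deriv * e2 - 2 * (-a)^deriv * e1)
  } else {
    al <- potential$alpha; be <- potential$beta; s <- potential$sigma
    # d^k/dR^k R^-p = (-1)^k p (p+1) ... (p+k-1) R^-(p+k)
    ff <- function(p, k) if (k == 0) 1 else prod(p + 0:(k - 1))
    4 * potential$epsilon * (-1)^deriv *
      (ff(al, deriv) * s^al * R^(-al - deriv) -
       ff(be, deriv) * s^be * R^(-be - deriv))
  }
}

#' Valid (m, n) index pairs of the multipolar series
#'
#' n runs over m, m-2, ... down to 0 (m even) or 1 (m odd), so that both
#' m+n and m-n are even and each term is a scalar.
#'
#' @param max_m Highest tensor order m retained (0..4).
#' @return Two-column integer matrix of (m, n) pairs.
#' @export
series_index_pairs <- function(max_m) {
  stopifnot(max_m >= 0, max_m <= 4)
  out <- NULL
  for (m in 0:max_m) {
    n <- seq(m, if (m %% 2 == 0) 0 else 1, by = -2)
    out <- rbind(out, cbind(m = m, n = sort(n)))
  }
  out
}

#' Truncation scheme for the coarse-grained series
#'
#' Presets: "cg0" keeps only (0,0) (a bare single-site potential), "cg3"
#' keeps all terms with m <= 3, "cg4" all with m <= 4.
#'
#' @param max_m Highest order m (0..4), or a preset name "cg0"/"cg3"/"cg4".
#' @return Object of class `truncation_scheme` with `max_m` and the matrix
#'   `pairs` of retained (m, n) indices.
#' @export
truncation_scheme <- function(max_m = 4) {
  if (is.character(max_m))
    max_m <- switch(max_m, cg0 = 0, cg1 = 1, cg2 = 2, cg3 = 3, cg4 = 4,
                    stop("unknown truncation preset: ", max_m))
  structure(list(max_m = as.integer(max_m), pairs = series_index_pairs(max_m)),
            class = "truncation_scheme")
}

#' @export
print.truncation_scheme <- function(x, ...) {
  cat(sprintf("truncation_scheme: m <= %d, %d (m,n) terms\n",
              x$max_m, nrow(x$pairs)))
  invisible(x)
}

.check_mn <- function(m, n) {
  if (m < 0 || m > 4 || n < 0 || n > m || (m - n) %% 2 != 0)
    stop(sprintf("invalid series indices (m = %d, n = %d): need 0 <= n <= m <= 4 with m - n even", m, n))
}

# (1/R d/dR)^k U as sum_j c_j U^(j) R^(j - 2k); coefficient recursion
# c[k+1, j] = c[k, j-1] + (j - 2k) c[k, j]
.iterated_radial_operator <- function(potential, R, k) {
  if (k == 0) return(potential_deriv(potential, R, 0))
  cvec <- c(1)                 # c_j for j = 1..k at current level (start k=1)
  if (k > 1) for (lev in 1:(k - 1)) {
    newc <- numeric(lev + 1)
    for (j in seq_len(lev + 1)) {
      prev <- if (j >= 2) cvec[j - 1] else 0
      cur <- if (j <= lev) (j - 2 * lev) * cvec[j] else 0
      newc[j] <- prev + cur
    }
    cvec <- newc
  }
  out <- 0
  for (j in seq_len(k))
    out <- out + cvec[j] * potential_deriv(potential, R, j) * R^(j - 2 * k)
  out
}

.double_factorial <- function(x) if (x <= 0) 1 else prod(seq(x, 1, by = -2))

#' Radial coefficient V(mn) of the multipolar series
#'
#' V(mn) = R^n (1/R d/dR)^((m+n)/2) U(R) / (n! (m-n)!!), the coefficient
#' multiplying the angular part Theta(mn) in the inter-blob series. Uses the
#' analytic radial derivatives of the potential.
#'
#' @param potential A `pair_potential`.
#' @param R Separation(s), Angstrom.
#' @param m,n Series indices (m + n and m - n even, 0 <= n <= m <= 4).
#' @return V(mn) in kcal/mol / Angstrom^m.
#' @export
radial_coefficient <- function(potential, R, m, n) {
  .check_mn(m, n)
  stopifnot(all(R > 0))
  k <- (m + n) / 2
  R^n * .iterated_radial_operator(potential, R, k) /
    (factorial(n) * .double_factorial(m - n))
}

#' Radial derivative of V(mn)
#'
#' d V(mn) / dR, needed by the analytic force. Follows from
#' d/dR of the iterated operator: D_k' = R * D_{k+1}.
#'
#' @inheritParams radial_coefficient
#' @return dV(mn)/dR in kcal/mol / Angstrom^(m+1).
#' @export
radial_coefficient_deriv <- function(potential, R, m, n) {
  .check_mn(m, n)
  k <- (m + n) / 2
  Dk <- .iterated_radial_operator(potential, R, k)
  Dk1 <- .iterated_radial_operator(potential, R, k + 1)
  (n * R^(n - 1) * Dk + R^(n + 1) * Dk1) /
    (factorial(n) * .double_factorial(m - n))
}

#' Closed-form Lennard-Jones radial coefficient
#'
#' For the generalized LJ potential the iterated radial operator has the
#' closed form
#'   V(mn) = 4 eps (-1)^((m+n)/2) / (n! (m-n)!! R^m) *
#'           (P(alpha) (sigma/R)^alpha - P(beta) (sigma/R)^beta),
#' where P(x) = x (x+2) (x+4) ... (x + m + n - 2) (empty product = 1).
#'
#' @param potential A `pair_potential` of kind "lennard_jones".
#' @param R Separation(s), Angstrom.
#' @param m,n Series indices.
#' @return V(mn) in kcal/mol / Angstrom^m.
#' @export
lj_radial_closed_form <- function(potential, R, m, n) {
  if (potential$kind != "lennard_jones") stop("closed form is LJ-specific")
  .check_mn(m, n)
  k <- (m + n) / 2
  P <- function(x) if (k == 0) 1 else prod(x + 2 * (0:(k - 1)))
  4 * potential$epsilon * (-1)^k /
    (factorial(n) * .double_factorial(m - n) * R^m) *
    (P(potential$alpha) * (potential$sigma / R)^potential$alpha -
     P(potential$beta) * (potential$sigma / R)^potential$beta)
}
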