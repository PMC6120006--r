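# Liquid-state observables: radial distribution function, velocity
# autocorrelation, Green-Kubo self-diffusion, mean-squared displacement.

#' Center-of-mass radial distribution function
#'
#' Minimum-image pair histogram over trajectory frames, normalized by the
#' ideal-gas shell count at the same number density, so g -> 1 at large r.
#'
#' @param trajectory A `cg_trajectory`.
#' @param bin_width Bin width, Angstrom (default 0.1).
#' @param r_max Histogram range; defaults to (just under) half the box
#'   edge. Must not exceed box/2.
#' @param skip_frames Frames to drop from the start (default 0; run_md
#'   already discards equilibration).
#' @return Object of class `rdf_result`: data frame `r` (bin centers), `g`,
#'   plus `bin_width`, `n_frames`.
#' @export
rdf <- function(trajectory, bin_width = 0.1, r_max = NULL, skip_frames = 0) {
  box <- trajectory$box
  if (box <= 0) stop("rdf requires a periodic box")
  if (is.null(r_max)) r_max <- 0.4999 * box
  if (r_max > box / 2 + 1e-9) stop("r_max must not exceed half the box edge")
  pos <- trajectory$positions
  F <- dim(pos)[3]
  keep <- (skip_frames + 1):F
  if (length(keep) < 10) stop("need at least 10 frames for an RDF")
  pos <- pos[, , keep, drop = FALSE]
  N <- dim(pos)[1]
  counts <- rdf_hist_cpp(pos, box, bin_width, r_max)
  nb <- length(counts)
  edges <- bin_width * (0:nb)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  rho_pairs <- N * (N - 1) / 2 / box^3
  ideal <- rho_pairs * shell * length(keep)
  structure(list(r = bin_width * (seq_len(nb) - 0.5),
                 g = counts / ideal,
                 bin_width = bin_width, n_frames = length(keep),
                 n_molecules = N, box = box),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result: %d bins of %.3g A over %d frames (%d molecules)\n",
              length(x$r), x$bin_width, x$n_frames, x$n_molecules))
  pk <- tryCatch(first_peak(x), error = function(e) NULL)
  if (!is.null(pk))
    cat(sprintf("  first peak: g = %.3f at r = %.3f A\n",
                pk$height, pk$position))
  invisible(x)
}

#' First peak of a radial distribution function
#'
#' Locates the first local maximum with g > 1.5 and refines height and
#' position by parabolic interpolation through the maximum bin and its two
#' neighbors (sub-bin resolution).
#'
#' @param rdf_result An `rdf_result`.
#' @return List with `height` and `position` (Angstrom).
#' @export
first_peak <- function(rdf_result) {
  g <- rdf_result$g
  r <- rdf_result$r
  nb <- length(g)
  idx <- NA
  for (i in 2:(nb - 1)) {
    if (g[i] > 1.5 && g[i] >= g[i - 1] && g[i] >= g[i + 1]) { idx <- i; break }
  }
  if (is.na(idx)) stop("no RDF peak found (no local maximum with g > 1.5)")
  y1 <- g[idx - 1]; y2 <- g[idx]; y3 <- g[idx + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  list(height = y2 - 0.25 * (y1 - y3) * delta,
       position = r[idx] + delta * rdf_result$bin_width)
}

#' Normalized center-of-mass velocity autocorrelation function
#'
#' C_v(t) = <v(t0 + t) . v(t0)> / <v(t0)^2>, averaged over molecules and
#' time origins. C_v(0) = 1 by construction.
#'
#' @param trajectory A `cg_trajectory` with stored velocities.
#' @param max_lag_ps Longest lag, ps (default 0.5).
#' @param origin_stride Use every k-th stored frame as a time origin
#'   (default 1: all origins).
#' @return Object of class `vaf_result`: `lags` (ps), `C` (normalized),
#'   `v2_mean` (<v^2(0)>, A^2/ps^2), `n_origins`.
#' @export
vaf <- function(trajectory, max_lag_ps = 0.5, origin_stride = 1) {
  vel <- trajectory$velocities
  if (is.null(vel) || length(vel) == 0) stop("trajectory has no velocity data")
  tv <- trajectory$times_vel
  F <- dim(vel)[3]
  if (F < 3) stop("need multiple velocity frames for a VAF")
  dtv <- tv[2] - tv[1]
  L <- min(F - 1, round(max_lag_ps / dtv))
  vm <- matrix(vel, ncol = F)          # (3N) x F
  origins <- seq(1, F - L, by = origin_stride)
  C <- numeric(L + 1)
  for (l in 0:L)
    C[l + 1] <- sum(vm[, origins, drop = FALSE] *
                    vm[, origins + l, drop = FALSE])
  N <- dim(vel)[1]
  v2_mean <- C[1] / (length(origins) * N)
  structure(list(lags = dtv * (0:L), C = C / C[1], v2_mean = v2_mean,
                 n_origins = length(origins)),
            class = "vaf_result")
}

#' @export
print.vaf_result <- function(x, ...) {
  cat(sprintf(
    "vaf_result: %d lags to %.3g ps, %d origins, <v^2(0)> = %.4g A^2/ps^2\n",
    length(x$lags), max(x$lags), x$n_origins, x$v2_mean))
  invisible(x)
}

#' Green-Kubo self-diffusion coefficient
#'
#' D = (1/3) <v^2(0)> * integral of C_v(t) dt, by trapezoidal rule over the
#' stored lags; converted from A^2/ps to 1e-9 m^2/s (factor 10). The VAF
#' tail must have decayed (|C_v| < 0.05 at the last lag) unless
#' `override = TRUE`.
#'
#' @param vaf_result A `vaf_result`.
#' @param v2 Kinetic prefactor <v^2(0)> (A^2/ps^2); defaults to the value
#'   stored in `vaf_result`.
#' @param override Skip the decayed-tail precondition.
#' @return List with `D` (1e-9 m^2/s), `D_80` (same integral truncated at
#'   80% of the maximum lag, an upper-limit sensitivity check), and
#'   `tail_C` (C_v at the last lag).
#' @export
green_kubo_D <- function(vaf_result, v2 = NULL, override = FALSE) {
  C <- vaf_result$C
  lags <- vaf_result$lags
  if (is.null(v2)) v2 <- vaf_result$v2_mean
  tail_C <- C[length(C)]
  if (!override && abs(tail_C) >= 0.05)
    stop(sprintf(
      "VAF tail has not decayed (|C_v| = %.3f >= 0.05 at %.3g ps); extend the lag window or pass override = TRUE",
      abs(tail_C), max(lags)))
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  i80 <- max(2, floor(0.8 * length(lags)))
  D_Aps <- v2 * trapz(lags, C) / 3
  D80_Aps <- v2 * trapz(lags[1:i80], C[1:i80]) / 3
  list(D = 10 * D_Aps, D_80 = 10 * D80_Aps, tail_C = tail_C)
}

#' Mean-squared displacement diffusion estimate
#'
#' Unwraps the periodic trajectory (frame-to-frame minimum image), computes
#' the origin-averaged MSD and fits D = MSD/(6 t) over the second half of
#' the lag window. Cross-check for [green_kubo_D()].
#'
#' @param trajectory A `cg_trajectory`.
#' @param max_lag_ps Longest lag, ps.
#' @return List with `D` (1e-9 m^2/s), `lags`, `msd` (A^2).
#' @export
msd_diffusion <- function(trajectory, max_lag_ps = 5) {
  pos <- trajectory$positions
  box <- trajectory$box
  tp <- trajectory$times_pos
  F <- dim(pos)[3]; N <- dim(pos)[1]
  dtp <- tp[2] - tp[1]
  # unwrap
  un <- pos
  for (f in 2:F) {
    d <- pos[, , f] - pos[, , f - 1]
    if (box > 0) d <- d - box * round(d / box)
    un[, , f] <- un[, , f - 1] + d
  }
  L <- min(F - 1, round(max_lag_ps / dtp))
  lags <- dtp * (1:L)
  msd <- numeric(L)
  for (l in 1:L) {
    d <- un[, , (1 + l):F, drop = FALSE] - un[, , 1:(F - l), drop = FALSE]
    msd[l] <- sum(d^2) / (N * (F - l))
  }
  half <- ceiling(L / 2):L
  Dfit <- coef(stats::lm(msd[half] ~ lags[half]))[2] / 6
  list(D = 10 * as.numeric(Dfit), lags = lags, msd = msd)
}
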