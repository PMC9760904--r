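#' Traction forces
#'
#' The force each element exerts on the substrate: `f_traction_i = zeta_i v_i`.
#' Because the cell is inertialess and force-free, the sum of the traction
#' forces (the monopole) vanishes to solver tolerance in any simulation.
#'
#' @param zeta Per-element friction coefficients.
#' @param v N x 2 matrix of element velocities.
#' @return N x 2 matrix of traction forces.
#' @export
traction_forces <- function(zeta, v) {
  v <- as.matrix(v)
  zeta * v
}

#' Velocity-aligned comoving frame
#'
#' Builds the frame used for multipole analysis: origin at the center of
#' mass, first axis along the instantaneous center-of-mass velocity, second
#' axis rotated +90 degrees. If `|V_cm|` is below `threshold` the frame is
#' flagged undefined (callers fall back to the last valid frame).
#'
#' @param origin Center-of-mass position (length-2).
#' @param v_cm Center-of-mass velocity (length-2).
#' @param threshold Speed below which the frame is undefined.
#' @return A `traction_frame` list: `origin`, `axis1`, `axis2`, `phi_v`,
#'   `defined`.
#' @export
traction_frame <- function(origin, v_cm, threshold = 1e-6) {
  speed <- sqrt(sum(v_cm^2))
  if (!is.finite(speed) || speed < threshold) {
    return(structure(list(origin = origin, axis1 = c(1, 0), axis2 = c(0, 1),
                          phi_v = NA_real_, defined = FALSE),
                     class = "traction_frame"))
  }
  a1 <- v_cm / speed
  structure(list(origin = origin, axis1 = a1, axis2 = c(-a1[2], a1[1]),
                 phi_v = atan2(v_cm[2], v_cm[1]), defined = TRUE),
            class = "traction_frame")
}

#' Traction-force multipoles in the comoving frame
#'
#' Computes the monopole `M1_a = sum_i f_ia`, the dipole
#' `M2_ab = sum_i r_ia f_ib`, the torque `T = M2_12 - M2_21`, and the
#' quadrupole `M3_abg = sum_i r_ia r_ib f_ig`, with positions taken relative
#' to the frame origin (center of mass) and both positions and forces
#' rotated into the frame axes (axis 1 parallel to the center-of-mass
#' velocity). Negative diagonal dipole components are contractile, positive
#' extensile. The dipole eigenvalue `lambda1` is the one whose eigenvector
#' axis is closer (mod pi) to the velocity angle `phi_v`.
#'
#' @param positions N x 2 element positions (lab frame).
#' @param tractions N x 2 traction forces (lab frame).
#' @param frame A `traction_frame`.
#' @return A `multipole_record` list: `M1` (2-vector), `M2` (2 x 2), `M3`
#'   (2 x 2 x 2 array), `torque`, eigenvalues `lambda1`, `lambda2` (complex
#'   when the antisymmetric part dominates), eigen-angles `theta1`, `theta2`
#'   in `(-pi/2, pi/2]` (lab frame), and `phi_v`.
#' @export
multipoles <- function(positions, tractions, frame) {
  R <- rbind(frame$axis1, frame$axis2)        # rows: frame axes (rotation)
  rp <- t(R %*% t(sweep(positions, 2, frame$origin)))
  fp <- t(R %*% t(tractions))
  M1 <- colSums(fp)
  M2 <- t(rp) %*% fp                          # M2[a, b] = sum r_a f_b
  M3 <- array(0, c(2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (g in 1:2)
    M3[a, b, g] <- sum(rp[, a] * rp[, b] * fp[, g])
  torque <- M2[1, 2] - M2[2, 1]
  ev <- eigen(M2)
  lam <- ev$values
  # eigenvector axis angles in the lab frame
  phi_v <- if (isTRUE(frame$defined)) frame$phi_v else 0
  ang <- vapply(1:2, function(k) {
    vec <- ev$vectors[, k]
    if (is.complex(vec)) vec <- Re(vec)
    th <- atan2(vec[2], vec[1]) + phi_v       # rotate back to lab
    wrap_axis(th)
  }, 0)
  # lambda1 <- eigenvalue whose axis is closer to phi_v (mod pi)
  dist_axis <- function(th) {
    d <- abs(wrap_axis(th - phi_v)); pmin(d, pi - d)
  }
  ord <- order(dist_axis(ang))
  structure(list(M1 = M1, M2 = M2, M3 = M3, torque = torque,
                 lambda1 = lam[ord[1]], lambda2 = lam[ord[2]],
                 theta1 = ang[ord[1]], theta2 = ang[ord[2]],
                 phi_v = frame$phi_v, frame_defined = frame$defined),
            class = "multipole_record")
}

wrap_axis <- function(th) {
  th <- (th + pi / 2) %% pi - pi / 2
  ifelse(th <= -pi / 2, th + pi, th)
}

#' Center-of-mass velocity by centered differences
#'
#' @param times Snapshot times (uniform).
#' @param com S x 2 matrix of center-of-mass positions.
#' @return S x 2 matrix of velocities (one-sided at the ends).
#' @export
com_velocity <- function(times, com) {
  S <- nrow(com)
  v <- matrix(NA_real_, S, 2)
  if (S < 2) stop("need at least 2 samples")
  v[1, ] <- (com[2, ] - com[1, ]) / (times[2] - times[1])
  v[S, ] <- (com[S, ] - com[S - 1, ]) / (times[S] - times[S - 1])
  if (S > 2) {
    idx <- 2:(S - 1)
    v[idx, ] <- (com[idx + 1, ] - com[idx - 1, ]) / (times[idx + 1] - times[idx - 1])
  }
  v
}

#' Multipole time series of a trajectory
#'
#' Applies [multipoles()] at every snapshot of a simulated trajectory, using
#' the centered-difference center-of-mass velocity to orient the comoving
#' frame; snapshots where `|V_cm|` is below the threshold reuse the last
#' valid frame orientation.
#'
#' @param traj A `cell_trajectory` from [run_experiment()].
#' @param threshold Frame-undefined speed threshold.
#' @return Data frame with one row per snapshot: `time`, `M1_1`, `M1_2`,
#'   `M2_11`, `M2_12`, `M2_21`, `M2_22`, `torque`, `M3_111`, `M3_112`,
#'   `M3_221`, `M3_222`, `lambda1`, `lambda2` (real parts; imaginary part in
#'   `lambda_im`), `theta1`, `theta2`, `phi_v`, `frame_defined`.
#' @export
multipole_series <- function(traj, threshold = 1e-6) {
  stopifnot(inherits(traj, "cell_trajectory"))
  vcm <- com_velocity(traj$times, traj$com)
  S <- length(traj$times)
  last <- NULL
  out <- vector("list", S)
  for (s in seq_len(S)) {
    fr <- traction_frame(traj$com[s, ], vcm[s, ], threshold)
    if (!fr$defined && !is.null(last)) {
      fr <- last; fr$origin <- traj$com[s, ]; fr$defined <- FALSE
    }
    if (fr$defined) last <- fr
    mp <- multipoles(cbind(traj$x[s, ], traj$y[s, ]),
                     cbind(traj$trac_x[s, ], traj$trac_y[s, ]), fr)
    out[[s]] <- data.frame(
      time = traj$times[s],
      M1_1 = mp$M1[1], M1_2 = mp$M1[2],
      M2_11 = mp$M2[1, 1], M2_12 = mp$M2[1, 2],
      M2_21 = mp$M2[2, 1], M2_22 = mp$M2[2, 2],
      torque = mp$torque,
      M3_111 = mp$M3[1, 1, 1], M3_112 = mp$M3[1, 1, 2],
      M3_221 = mp$M3[2, 2, 1], M3_222 = mp$M3[2, 2, 2],
      lambda1 = Re(mp$lambda1), lambda2 = Re(mp$lambda2),
      lambda_im = Im(mp$lambda1),
      theta1 = mp$theta1, theta2 = mp$theta2,
      phi_v = ifelse(is.na(mp$phi_v), NA_real_, mp$phi_v),
      frame_defined = mp$frame_defined)
  }
  do.call(rbind, out)
}

#' Net displacement over one driving cycle
#'
#' Signed x-displacement of the center of mass over one period, measured
#' after discarding `n_relax` relaxation cycles (transients of the stick-slip
#' dynamics). Positive values are rightward motion, i.e. against the
#' leftward-traveling intracellular wave.
#'
#' @param times Snapshot times.
#' @param com_x Center-of-mass x positions (or an S x 2 `com` matrix).
#' @param period Driving period (stimulus or wave period).
#' @param n_relax Number of discarded relaxation cycles (default 5).
#' @return Signed displacement `Delta R`.
#' @export
displacement_per_cycle <- function(times, com_x, period, n_relax = 5) {
  if (is.matrix(com_x)) com_x <- com_x[, 1]
  t0 <- n_relax * period
  t1 <- (n_relax + 1) * period
  if (max(times) < t1 - 1e-9)
    stop(sprintf("trajectory too short: need %g, have %g", t1, max(times)))
  at <- function(tt) stats::approx(times, com_x, xout = tt, rule = 2)$y
  at(t1) - at(t0)
}

#' Mean-square displacement and velocity autocorrelation
#'
#' Time-averaged MSD `<(X(t0 + t) - X(t0))^2>` of the center of mass and the
#' autocorrelation `<u(t0 + t) . u(t0)>` of the velocity *direction*
#' `u = V_cm / |V_cm|` (so `VAC(0) = 1`), both averaged over all valid `t0`
#' at each lag. Lags are taken on a log-spaced grid of sample multiples.
#'
#' @param times Uniformly sampled snapshot times.
#' @param com S x 2 matrix of center-of-mass positions.
#' @param n_lags Approximate number of log-spaced lags.
#' @param max_lag_frac Largest lag as a fraction of the trajectory length.
#' @return List of data frames `msd` (`lag`, `msd`, `n`) and `vac`
#'   (`lag`, `vac`, `n`).
#' @export
msd_vac <- function(times, com, n_lags = 60, max_lag_frac = 0.5) {
  S <- nrow(com)
  if (S < 2) stop("need at least 2 samples")
  dt <- times[2] - times[1]
  max_k <- max(1L, floor((S - 1) * max_lag_frac))
  ks <- unique(pmax(1L, round(exp(seq(log(1), log(max_k), length.out = n_lags)))))
  msd <- vapply(ks, function(k) {
    d <- com[(1 + k):S, , drop = FALSE] - com[1:(S - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
  v <- com_velocity(times, com)
  sp <- sqrt(rowSums(v^2))
  u <- v / pmax(sp, 1e-300)
  ok <- sp > 1e-12
  vac <- vapply(ks, function(k) {
    i0 <- 1:(S - k)
    keep <- ok[i0] & ok[i0 + k]
    if (!any(keep)) return(NA_real_)
    mean(rowSums(u[i0[keep], , drop = FALSE] * u[i0[keep] + k, , drop = FALSE]))
  }, 0)
  list(msd = data.frame(lag = ks * dt, msd = msd, n = S - ks),
       vac = data.frame(lag = ks * dt, vac = vac, n = S - ks))
}

#' Ballistic-to-diffusive crossover time of an MSD curve
#'
#' Local log-log slope of the MSD by centered differences; the crossover is
#' the first lag at which the slope falls below `threshold` (1.5 by default,
#' halfway between the ballistic slope 2 and the diffusive slope 1).
#'
#' @param lag,msd MSD curve (positive lags).
#' @param threshold Slope threshold.
#' @return The crossover lag (time units), or `NA` if the slope never drops
#'   below the threshold.
#' @export
msd_crossover <- function(lag, msd, threshold = 1.5) {
  ok <- is.finite(lag) & is.finite(msd) & lag > 0 & msd > 0
  lag <- lag[ok]; msd <- msd[ok]
  if (length(lag) < 3) return(NA_real_)
  lx <- log(lag); ly <- log(msd)
  n <- length(lx)
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (ly[3:n] - ly[1:(n - 2)]) / (lx[3:n] - lx[1:(n - 2)])
  idx <- which(slope < threshold)
  if (!length(idx)) return(NA_real_)
  lag[idx[1]]
}
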