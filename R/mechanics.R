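#' Mechanical parameters of the subcellular-element model
#'
#' Default values follow the standard parameterization of the model: with a
#' cell of diameter `L_cell` and `N` elements, the slip friction coefficient
#' is `L_cell^2 / N`, the stick coefficient is ten times larger, the bond
#' elastic modulus is 10 (model force units of 10 nN), and the intracellular
#' dissipation rate is `L_cell^2 / L_bond` where `L_bond` is the total rest
#' bond length. The area-penalty strength `sigma_area` (default `1e-6`)
#' controls the soft-core potential `U_area = sum sigma / S_ijk^2` that
#' prevents collapse of mesh triangles.
#'
#' @param mesh A `cell_mesh` used to derive the defaults.
#' @param zeta_slip,zeta_stick Slip/stick substrate friction coefficients
#'   (model force * time / length); must satisfy `zeta_slip < zeta_stick`.
#' @param kappa Bond elastic modulus (model force units).
#' @param xi Intracellular dissipation rate (model force * time / length^2).
#' @param sigma_area Area-penalty strength.
#' @return A `mech_params` list.
#' @export
mech_params <- function(mesh,
                        zeta_slip = mesh$L_cell^2 / nrow(mesh$positions),
                        zeta_stick = 10 * zeta_slip,
                        kappa = 10,
                        xi = mesh$L_cell^2 / sum(mesh$rest_length),
                        sigma_area = 1e-6) {
  stopifnot(zeta_slip > 0, zeta_stick > zeta_slip, kappa > 0, xi > 0,
            sigma_area >= 0)
  structure(list(zeta_slip = zeta_slip, zeta_stick = zeta_stick,
                 kappa = kappa, xi = xi, sigma_area = sigma_area),
            class = "mech_params")
}

#' Model-to-physical unit conversions
#'
#' The model is scaled by L0 = 10 um (length), T0 = 1 min (time) and
#' F0 = 10 nN (force). This helper converts common model quantities into
#' physical units.
#'
#' @return A list of unit scales and converter functions:
#'   `length_um(x)`, `time_min(t)`, `force_nN(f)`,
#'   `diffusion_um2_per_s(D)` and `friction_nN_min_per_um(zeta)`.
#' @examples
#' u <- model_units()
#' u$length_um(1 / sqrt(91))        # rest bond length of the 91-element cell
#' u$diffusion_um2_per_s(0.48)      # PIP2/PIP3 diffusion coefficient
#' @export
model_units <- function() {
  L0 <- 10; T0 <- 1; F0 <- 10   # um, min, nN
  list(L0_um = L0, T0_min = T0, F0_nN = F0,
       length_um = function(x) x * L0,
       time_min = function(t) t * T0,
       force_nN = function(f) f * F0,
       diffusion_um2_per_s = function(D) D * L0^2 / (T0 * 60),
       friction_nN_min_per_um = function(z) z * F0 * T0 / L0)
}

#' Conservative intracellular forces
#'
#' Evaluates the elastic bond forces and the triangle-area penalty force.
#' Each bond contributes a spring force of magnitude
#' `(kappa / l_ij) * (r_ij - l_ij - l_act_ij)` directed along the bond (the
#' strain-normalized spring constant `kappa / l_ij` makes the actuator force
#' `-kappa * l_act_ij / l_ij` along the bond; `l_act_ij` is the actuator
#' elongation added to the free length), applied equally and oppositely to
#' the bonded pair. The area term is the analytic gradient of
#' `U_area = sum sigma / S_ijk^2` over oriented triangles. The total force
#' and total torque about the centroid vanish by construction (action =
#' reaction; central + area forces).
#'
#' @param mesh A `cell_mesh`.
#' @param positions Current N x 2 positions (default: rest positions).
#' @param ell_act Per-bond actuator elongation (scalar or length-E vector).
#' @param params A `mech_params`.
#' @return N x 2 matrix of forces.
#' @export
conservative_forces <- function(mesh, positions = mesh$positions,
                                ell_act = 0, params = mech_params(mesh)) {
  N <- nrow(positions)
  E <- nrow(mesh$bonds)
  ell_act <- rep_len(ell_act, E)
  i <- mesh$bonds[, 1]; j <- mesh$bonds[, 2]
  d <- positions[j, , drop = FALSE] - positions[i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r <= 0)) stop("coincident bonded elements (r_ij = 0)")
  fmag <- params$kappa / mesh$rest_length * (r - mesh$rest_length - ell_act)
  fx <- fmag * d[, 1] / r
  fy <- fmag * d[, 2] / r
  f <- matrix(0, N, 2)
  for (e in seq_len(E)) {
    f[i[e], ] <- f[i[e], ] + c(fx[e], fy[e])
    f[j[e], ] <- f[j[e], ] - c(fx[e], fy[e])
  }

  if (params$sigma_area > 0) {
    tri <- mesh$triangles
    S <- signed_area(positions, tri)
    if (any(abs(S) < 1e-8))
      stop("degenerate triangle (|S| < 1e-8): ",
           paste(which(abs(S) < 1e-8), collapse = ", "))
    S_rest <- signed_area(mesh$positions, tri)
    if (any(abs(S) < 1e-3 * abs(S_rest)))
      warning("triangle area below 1e-3 of rest area; mesh close to collapse")
    coef <- 2 * params$sigma_area / S^3   # f = + (2 sigma / S^3) dS/dr
    px <- positions[, 1]; py <- positions[, 2]
    for (v in 1:3) {
      a <- tri[, v]; b <- tri[, v %% 3 + 1]; cc <- tri[, (v + 1) %% 3 + 1]
      # dS/dr_a = ( (y_b - y_c)/2 , (x_c - x_b)/2 )
      gx <- coef * (py[b] - py[cc]) / 2
      gy <- coef * (px[cc] - px[b]) / 2
      acc <- rowsum(cbind(gx, gy), group = a, reorder = TRUE)
      ids <- as.integer(rownames(acc))
      f[ids, 1] <- f[ids, 1] + acc[, 1]
      f[ids, 2] <- f[ids, 2] + acc[, 2]
    }
  }
  f
}

#' Area-penalty potential energy
#'
#' `U_area = sum_{<i,j,k>} sigma / S_ijk^2` over oriented mesh triangles;
#' used mainly to verify the analytic gradient in [conservative_forces()].
#'
#' @inheritParams conservative_forces
#' @return Scalar energy.
#' @export
area_energy <- function(mesh, positions = mesh$positions,
                        params = mech_params(mesh)) {
  S <- signed_area(positions, mesh$triangles)
  sum(params$sigma_area / S^2)
}

#' Solve the overdamped force balance for element velocities
#'
#' The force balance couples the velocities of bonded elements through the
#' intracellular dissipation term: per spatial component it reads
#' `[diag(zeta_i) + xi * W] v = F`, where `W` is the graph Laplacian of the
#' bond network with edge weights `l_ij` (`W_ii = sum_j l_ij`,
#' `W_ij = -l_ij` for bonded pairs). The system is symmetric positive
#' definite for `zeta_i > 0` and is solved directly (the mesh has at most a
#' few hundred elements). The identity `sum_i zeta_i v_i = sum_i F_i` holds
#' for the exact solution, so internal (force-free) forcing gives zero
#' center-of-mass drift whenever the friction is spatially homogeneous.
#'
#' @param mesh A `cell_mesh`.
#' @param zeta Per-element friction coefficients (scalar or length-N).
#' @param forces N x 2 matrix of forces.
#' @param params A `mech_params` (supplies `xi`).
#' @return N x 2 matrix of velocities.
#' @export
solve_velocities <- function(mesh, zeta, forces, params = mech_params(mesh)) {
  N <- nrow(mesh$positions)
  zeta <- rep_len(zeta, N)
  if (any(zeta <= 0)) stop("friction coefficients must be positive")
  A <- friction_matrix(mesh, zeta, params$xi)
  v <- solve(A, forces)
  res <- max(abs(A %*% v - forces)) / max(1e-300, max(abs(forces)))
  if (!is.finite(res) || res > 1e-8)
    stop("velocity solve ill-conditioned (relative residual ", res, ")")
  unname(v)
}

friction_matrix <- function(mesh, zeta, xi) {
  N <- nrow(mesh$positions)
  A <- diag(zeta, N)
  i <- mesh$bonds[, 1]; j <- mesh$bonds[, 2]; w <- xi * mesh$rest_length
  for (e in seq_along(i)) {
    A[i[e], i[e]] <- A[i[e], i[e]] + w[e]
    A[j[e], j[e]] <- A[j[e], j[e]] + w[e]
    A[i[e], j[e]] <- A[i[e], j[e]] - w[e]
    A[j[e], i[e]] <- A[j[e], i[e]] - w[e]
  }
  A
}

#' Explicit Euler position update
#'
#' @param positions N x 2 positions.
#' @param velocities N x 2 velocities.
#' @param dt Time increment (> 0).
#' @return Updated N x 2 positions `r + v * dt`.
#' @export
step_positions <- function(positions, velocities, dt) {
  stopifnot(dt > 0)
  positions + velocities * dt
}
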