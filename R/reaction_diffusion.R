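#' Parameters of the excitable PIP2/PIP3 reaction-diffusion system
#'
#' The intracellular signaling is a two-variable Gray-Scott-type system for
#' the PIP2 concentration `U` and PIP3 concentration `V` with global
#' couplings `<U>` and `<V^2>` (population mean and mean square) arising from
#' conservation of the eliminated kinase/phosphatase pools. The default
#' constants put the system in the excitable regime with stable rest state
#' `(U, V) = (S/gamma, 0)`.
#'
#' @param D_U,D_V Diffusion coefficients (model units; 0.48 corresponds to
#'   0.8 um^2/s).
#' @param alpha,beta,K_K,K_P,S,gamma,mu Reaction constants.
#' @param I_excite Stimulus amplitude applied as `(dU, dV) = (-I, +I)`.
#' @param stimulus_period Time between periodic stimuli on the activator.
#' @param r_e Cutoff radius of the MPS Laplacian kernel; default `4 * ell0`
#'   where `ell0` is the mean rest bond length (supply either `r_e` or
#'   `ell0`).
#' @param ell0 Mean rest bond length used to derive the default `r_e`.
#' @param lambda MPS normalization, default `r_e^2 / 6`.
#' @return An `rd_params` list.
#' @export
rd_params <- function(D_U = 0.48, D_V = 0.48, alpha = 240, beta = 90,
                      K_K = 5, K_P = 5, S = 30, gamma = 6, mu = 30,
                      I_excite = 0.75, stimulus_period = 1.5,
                      ell0 = NULL, r_e = if (!is.null(ell0)) 4 * ell0 else NULL,
                      lambda = if (!is.null(r_e)) r_e^2 / 6 else NULL) {
  stopifnot(D_U >= 0, D_V >= 0, alpha >= 0, beta >= 0, K_K >= 0, K_P >= 0,
            S >= 0, gamma >= 0, mu >= 0)
  structure(list(D_U = D_U, D_V = D_V, alpha = alpha, beta = beta,
                 K_K = K_K, K_P = K_P, S = S, gamma = gamma, mu = mu,
                 I_excite = I_excite, stimulus_period = stimulus_period,
                 r_e = r_e, lambda = lambda),
            class = "rd_params")
}

#' Resting chemical state
#'
#' @param mesh A `cell_mesh` (or an integer element count).
#' @param params An `rd_params`.
#' @return A `chem_state` list with per-element `U = S/gamma` and `V = 0`.
#' @export
chem_rest_state <- function(mesh, params = rd_params()) {
  N <- if (inherits(mesh, "cell_mesh")) nrow(mesh$positions) else as.integer(mesh)
  structure(list(U = rep(params$S / params$gamma, N), V = rep(0, N)),
            class = "chem_state")
}

#' Reaction terms of the PIP2/PIP3 system
#'
#' `G_U = -alpha U V^2 K_K/(K_K + <V^2>)`... more precisely:
#' \deqn{G_U = -\frac{\alpha U V^2}{K_K + \langle V^2\rangle}
#'        + \frac{\beta U V}{K_P + \langle U\rangle} + S - \gamma U}
#' \deqn{G_V = +\frac{\alpha U V^2}{K_K + \langle V^2\rangle}
#'        - \frac{\beta U V}{K_P + \langle U\rangle} - \mu V}
#' The phosphorylation/dephosphorylation exchange terms appear with opposite
#' signs in the two equations, so `G_U + G_V = S - gamma U - mu V`
#' identically.
#'
#' @param U,V Concentration vectors (or scalars).
#' @param mean_U,mean_V2 Global couplings `<U>` and `<V^2>`; default to the
#'   population mean / mean square of the supplied vectors.
#' @param params An `rd_params`.
#' @return List with components `G_U` and `G_V`.
#' @export
reaction_terms <- function(U, V, mean_U = mean(U), mean_V2 = mean(V^2),
                           params = rd_params()) {
  stopifnot(mean_U >= 0, mean_V2 >= 0)
  ex <- params$alpha * U * V^2 / (params$K_K + mean_V2) -
        params$beta * U * V / (params$K_P + mean_U)
  list(G_U = -ex + params$S - params$gamma * U,
       G_V = ex - params$mu * V)
}

#' Meshfree MPS discrete Laplacian
#'
#' Approximates the Laplacian on a particle cloud by the moving-particle
#' semi-implicit (MPS) kernel: for a field `c`,
#' `Lap c_i = (4 / lambda) * sum_{j != i} (c_j - c_i) w(r_ij) / n_ij`, with
#' weight `w(r) = r_e / r - 1` for `r < r_e` (0 beyond), particle number
#' densities `n_i = sum_j w(r_ij)` and `n_ij = (n_i + n_j)/2`, and
#' normalization `lambda = r_e^2 / 6`. The operator is exactly zero on
#' constant fields and pairwise antisymmetric in the exchange terms.
#'
#' @param values Per-element field values.
#' @param positions N x 2 element positions.
#' @param r_e Kernel cutoff radius.
#' @param lambda Normalization (default `r_e^2/6`).
#' @return Per-element vector approximating the Laplacian of `values`.
#' @export
mps_laplacian <- function(values, positions, r_e, lambda = r_e^2 / 6) {
  N <- nrow(positions)
  dx <- outer(positions[, 1], positions[, 1], "-")
  dy <- outer(positions[, 2], positions[, 2], "-")
  r <- sqrt(dx^2 + dy^2)
  w <- ifelse(r > 0 & r < r_e, r_e / pmax(r, 1e-300) - 1, 0)
  diag(w) <- 0
  n_i <- rowSums(w)
  if (any(n_i == 0))
    stop("isolated element(s) with no neighbor within r_e: ",
         paste(which(n_i == 0), collapse = ", "))
  n_ij <- (outer(n_i, n_i, "+")) / 2
  dc <- outer(values, values, function(a, b) b - a)  # dc[i, j] = c_j - c_i
  (4 / lambda) * rowSums(w * dc / n_ij)
}

#' Apply a chemical stimulus to one element
#'
#' Models enhanced phosphorylation of PIP2 to PIP3 at the activator element:
#' `(dU, dV) = (-I_excite, +I_excite)`.
#'
#' @param chem A `chem_state`.
#' @param element Element index.
#' @param I_excite Stimulus amplitude.
#' @return Updated `chem_state`.
#' @export
stimulate <- function(chem, element, I_excite) {
  stopifnot(element >= 1, element <= length(chem$U))
  chem$U[element] <- chem$U[element] - I_excite
  chem$V[element] <- chem$V[element] + I_excite
  chem
}

#' One explicit Euler step of the reaction-diffusion system
#'
#' Fully explicit update with the global couplings and the MPS Laplacian
#' evaluated from the beginning-of-step state. The time step must satisfy
#' the diffusive stability bound `dt < ell0^2 / (8 max(D_U, D_V))` with
#' `ell0 = r_e / 4`.
#'
#' @param chem A `chem_state`.
#' @param positions Current element positions.
#' @param dt Time increment.
#' @param params An `rd_params` carrying `r_e` and `lambda`.
#' @return Updated `chem_state`.
#' @export
step_rd <- function(chem, positions, dt, params) {
  stopifnot(!is.null(params$r_e))
  ell0 <- params$r_e / 4
  bound <- ell0^2 / (8 * max(params$D_U, params$D_V, 1e-300))
  if (dt >= bound)
    stop(sprintf("dt = %g violates the diffusive stability bound %g", dt, bound))
  g <- reaction_terms(chem$U, chem$V, mean(chem$U), mean(chem$V^2), params)
  lapU <- if (params$D_U > 0)
    mps_laplacian(chem$U, positions, params$r_e, params$lambda) else 0
  lapV <- if (params$D_V > 0)
    mps_laplacian(chem$V, positions, params$r_e, params$lambda) else 0
  chem$U <- chem$U + dt * (params$D_U * lapU + g$G_U)
  chem$V <- chem$V + dt * (params$D_V * lapV + g$G_V)
  if (any(chem$U < 0) || any(chem$V < 0))
    warning("negative concentration encountered")
  chem
}

#' Phase-plane tables for the reaction kinetics
#'
#' Evaluates the spatially uniform kinetics (so `<U> = U`, `<V^2> = V^2`) on
#' a grid and extracts the `G_U = 0` and `G_V = 0` nullclines as contour
#' lines; useful for plotting the excitable phase portrait.
#'
#' @param params An `rd_params`.
#' @param U_range,V_range Ranges of the grid.
#' @param n Grid resolution per axis.
#' @return List with `flow` (data frame of `U`, `V`, `G_U`, `G_V`) and
#'   `nullclines` (data frame of `U`, `V`, `which`).
#' @export
rd_phase_plane <- function(params = rd_params(), U_range = c(0, 8),
                           V_range = c(0, 4), n = 121) {
  Us <- seq(U_range[1], U_range[2], length.out = n)
  Vs <- seq(V_range[1], V_range[2], length.out = n)
  GU <- GV <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    g <- reaction_terms(Us[a], Vs[b], mean_U = Us[a], mean_V2 = Vs[b]^2,
                        params = params)
    GU[a, b] <- g$G_U; GV[a, b] <- g$G_V
  }
  flow <- data.frame(U = rep(Us, times = n), V = rep(Vs, each = n),
                     G_U = as.vector(GU), G_V = as.vector(GV))
  nc <- function(M, lab) {
    cl <- grDevices::contourLines(Us, Vs, M, levels = 0)
    if (!length(cl)) return(NULL)
    do.call(rbind, lapply(cl, function(s)
      data.frame(U = s$x, V = s$y, which = lab)))
  }
  list(flow = flow,
       nullclines = rbind(nc(GU, "G_U"), nc(GV, "G_V")))
}
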