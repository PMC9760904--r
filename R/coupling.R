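#' Mechanochemical coupling parameters
#'
#' Controls how the chemical state drives the mechanics: the actuator
#' elongation follows the bond-averaged PIP3 concentration as
#' `l_act = l_V * tanh(a * V_ij)`, and the substrate friction relaxes with
#' time delay `tau_zeta` under the mixed mechanical/chemical drive
#' `tau_zeta dzeta/dt = h_zeta(zeta) - A_v h_v(v) - (1 - A_v) h_V(V)`.
#'
#' @param mech A `mech_params` (supplies the default transition sharpness
#'   `eps_zeta = zeta_slip / 2`).
#' @param a Actuator sensitivity (default `pi`).
#' @param A_v Mixing ratio in `[0, 1]`: 1 = purely mechanical (velocity)
#'   control of adhesion, 0 = purely chemical (PIP3) control.
#' @param tau_zeta Time delay of the friction response.
#' @param eps_zeta Sharpness of the stick-slip transition walls.
#' @param v_star Velocity threshold of the mechanical drive (default 1).
#' @param sigma_V Chemical adhesion sensitivity; positive values de-adhere at
#'   high PIP3 (+2*pi reproduces retrograde-wave crawling, -2*pi direct-wave).
#' @param V_star PIP3 threshold of the chemical drive (default 0.5).
#' @param zeta_init Initial friction state, `"stick"` (default; a resting
#'   cell adheres) or `"slip"`.
#' @param ell_V_scale Actuator amplitude as a multiple of each bond's rest
#'   length (default 1, i.e. `l_V = l_ij`; 0 switches the actuator off).
#' @return A `coupling_params` list.
#' @export
coupling_params <- function(mech = NULL, a = pi, A_v = 0, tau_zeta = 0.01,
                            eps_zeta = if (!is.null(mech)) mech$zeta_slip / 2 else NULL,
                            v_star = 1, sigma_V = 2 * pi, V_star = 0.5,
                            zeta_init = c("stick", "slip"), ell_V_scale = 1) {
  stopifnot(A_v >= 0, A_v <= 1, tau_zeta > 0,
            is.null(eps_zeta) || eps_zeta > 0, ell_V_scale >= 0)
  structure(list(a = a, A_v = A_v, tau_zeta = tau_zeta, eps_zeta = eps_zeta,
                 v_star = v_star, sigma_V = sigma_V, V_star = V_star,
                 zeta_init = match.arg(zeta_init), ell_V_scale = ell_V_scale),
            class = "coupling_params")
}

#' Actuator elongation from PIP3 concentration
#'
#' `l_act_ij = l_V * tanh(a * V_ij)` with `V_ij = (V_i + V_j)/2`; saturates
#' at `l_V` so an unusually strong excitation cannot produce an unbounded
#' protrusion.
#'
#' @param V_i,V_j PIP3 concentrations of the bonded elements.
#' @param a Sensitivity.
#' @param ell_V Elongation magnitude (typically the bond rest length).
#' @return Actuator elongation (same shape as the inputs).
#' @export
actuator_from_chem <- function(V_i, V_j, a = pi, ell_V = 1) {
  ell_V * tanh(a * (V_i + V_j) / 2)
}

#' Stick-slip transition functions
#'
#' The friction dynamics balance a double-wall term `h_zeta` that pins
#' `zeta` near `zeta_slip` or `zeta_stick`, a mechanical drive `h_v`
#' (de-adhesion at speeds above `v_star`) and a chemical drive `h_V`
#' (de-adhesion at PIP3 above `V_star` when `sigma_V > 0`):
#' \deqn{h_\zeta(\zeta) = -\tfrac12\tanh\frac{\zeta-\zeta_{stick}}{\epsilon_\zeta}
#'   - \tfrac12\tanh\frac{\zeta-\zeta_{slip}}{\epsilon_\zeta}}
#' \deqn{h_v(v) = \frac{(v/v^*)^2}{1 + (v/v^*)^2} - \tfrac12, \qquad
#'   h_V(V) = \tfrac12\tanh(\sigma_V (V - V^*))}
#' Both drives are bounded in `[-1/2, 1/2]`, so `zeta` stays in
#' `[zeta_slip, zeta_stick]` up to the transition width.
#'
#' @param zeta Friction coefficient.
#' @param zeta_slip,zeta_stick Slip/stick friction levels.
#' @param eps_zeta Transition sharpness.
#' @param v Local speed (non-negative).
#' @param v_star Velocity threshold.
#' @param V PIP3 concentration.
#' @param sigma_V Chemical sensitivity.
#' @param V_star Concentration threshold.
#' @return Function value(s).
#' @export
h_zeta <- function(zeta, zeta_slip, zeta_stick, eps_zeta) {
  -0.5 * tanh((zeta - zeta_stick) / eps_zeta) -
   0.5 * tanh((zeta - zeta_slip) / eps_zeta)
}

#' @rdname h_zeta
#' @export
h_v <- function(v, v_star = 1) {
  s2 <- (v / v_star)^2
  s2 / (1 + s2) - 0.5
}

#' @rdname h_zeta
#' @export
h_V <- function(V, sigma_V = 2 * pi, V_star = 0.5) {
  0.5 * tanh(sigma_V * (V - V_star))
}

#' Friction relaxation rate
#'
#' Right-hand side of the delayed stick-slip dynamics:
#' `dzeta/dt = [h_zeta(zeta) - A_v h_v(v) - (1 - A_v) h_V(V)] / tau_zeta`.
#'
#' @param zeta Current friction coefficient(s).
#' @param v Local speed(s).
#' @param V Local PIP3 concentration(s).
#' @param mech A `mech_params` (for `zeta_slip`, `zeta_stick`).
#' @param params A `coupling_params`.
#' @return `dzeta/dt`, same shape as `zeta`.
#' @export
friction_drive <- function(zeta, v, V, mech, params) {
  eps <- if (is.null(params$eps_zeta)) mech$zeta_slip / 2 else params$eps_zeta
  (h_zeta(zeta, mech$zeta_slip, mech$zeta_stick, eps) -
     params$A_v * h_v(v, params$v_star) -
     (1 - params$A_v) * h_V(V, params$sigma_V, params$V_star)) /
    params$tau_zeta
}

#' Prescribed sinusoidal wave driver parameters
#'
#' Instead of the reaction-diffusion system, a traveling harmonic
#' concentration wave `c_i(t) = c_0 (1 - cos(phi_i))` can drive the cell,
#' with phase `phi_i = omega t + q_w (x_i - x*)` so that the crest travels
#' from the rightmost (activator) element to the left at speed `omega/q_w`.
#' The actuator follows `l_act_ij = l_c (c_i + c_j)/2` and the friction is a
#' two-state function of the shifted phase: slip for
#' `(phi_i - psi_zeta) mod 2pi` in `(0, pi]`, stick in `(pi, 2pi]`.
#'
#' @param q_w Wavenumber (> 0).
#' @param psi_zeta Phase shift between the friction switching and the wave.
#' @param c_0 Maximum half-amplitude (default 0.5, so `0 <= c <= 1`).
#' @param omega Angular frequency (default `2*pi`, period 1).
#' @param literal_sign If `TRUE`, use the phase `omega t - q_w (x - x*)`
#'   (crest traveling rightward) instead of the default leftward convention.
#' @param ell_c_scale Actuator amplitude as a multiple of each bond's rest
#'   length (default 1, i.e. `l_c = l_ij`; 0 switches the actuator off).
#' @return A `wave_driver_params` list.
#' @export
wave_driver_params <- function(q_w, psi_zeta, c_0 = 0.5, omega = 2 * pi,
                               literal_sign = FALSE, ell_c_scale = 1) {
  stopifnot(q_w > 0, omega > 0, ell_c_scale >= 0)
  structure(list(c_0 = c_0, omega = omega, q_w = q_w, psi_zeta = psi_zeta,
                 literal_sign = literal_sign, ell_c_scale = ell_c_scale),
            class = "wave_driver_params")
}

#' Evaluate the prescribed traveling wave
#'
#' @param t Time.
#' @param x Element x coordinates.
#' @param x_star Activator x position (wave origin).
#' @param params A `wave_driver_params`.
#' @param zeta_slip,zeta_stick Friction levels for the two-state switch.
#' @return List with `phase`, concentration `c`, and `zeta` per element.
#' @export
prescribed_wave <- function(t, x, x_star, params, zeta_slip = NULL,
                            zeta_stick = NULL) {
  sgn <- if (isTRUE(params$literal_sign)) -1 else 1
  phase <- params$omega * t + sgn * params$q_w * (x - x_star)
  conc <- params$c_0 * (1 - cos(phase))
  zeta <- NULL
  if (!is.null(zeta_slip)) {
    frac <- (phase - params$psi_zeta) %% (2 * pi)
    # slip on (0, pi], stick on (pi, 2pi] (equivalently at frac == 0)
    zeta <- ifelse(frac > 0 & frac <= pi, zeta_slip, zeta_stick)
  }
  list(phase = phase, c = conc, zeta = zeta)
}
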