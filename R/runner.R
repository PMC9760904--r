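#' Assemble a simulation configuration
#'
#' Collects the mesh, parameter groups, driver choice and integration
#' settings into a validated `run_config`. Exactly one driver is active:
#' `"wave"` (prescribed sinusoidal traveling wave, Sect. of the prescribed
#' driver) or `"rd"` (excitable PIP2/PIP3 reaction-diffusion system coupled
#' through the actuator and the stick-slip friction).
#'
#' @param mesh A `cell_mesh`.
#' @param driver `"rd"` or `"wave"`.
#' @param mech A `mech_params` (default derived from the mesh).
#' @param rd An `rd_params` (RD driver; `r_e` defaults to 4x the mean rest
#'   bond length).
#' @param coupling A `coupling_params` (RD driver).
#' @param wave A `wave_driver_params` (wave driver).
#' @param dt Time increment; defaults to `1e-5` for the RD driver and
#'   `1e-4` for the wave driver.
#' @param duration Total simulated time.
#' @param stimulus Stimulus schedule for the RD driver: a list with
#'   `mode` (`"periodic"`, `"random"` or `"none"`), `interval` (default 1.5
#'   periodic / 0.15 random) and `I_excite` (default 0.75). Random mode draws
#'   the stimulated element uniformly using R's RNG (seed it with
#'   `set.seed()` or the `seed` argument).
#' @param stride Snapshot interval in time units (default 0.01).
#' @param neighbor_every Steps between MPS neighbor-list rebuilds (weights
#'   are always recomputed from current positions).
#' @param seed Optional integer seed recorded in the output and applied
#'   before the run.
#' @param uniform_zeta If `TRUE`, hold the friction spatially homogeneous at
#'   `zeta_stick` (useful to verify that homogeneous adhesion forbids net
#'   migration).
#' @return A `run_config` list.
#' @export
run_config <- function(mesh, driver = c("rd", "wave"),
                       mech = mech_params(mesh),
                       rd = rd_params(ell0 = mean_bond_length(mesh)),
                       coupling = coupling_params(mech),
                       wave = NULL,
                       dt = NULL, duration = 9,
                       stimulus = list(mode = "periodic"),
                       stride = 0.01, neighbor_every = 50L,
                       seed = NULL, uniform_zeta = FALSE) {
  driver <- match.arg(driver)
  stopifnot(inherits(mesh, "cell_mesh"), inherits(mech, "mech_params"))
  if (driver == "wave" && is.null(wave))
    stop("wave driver requires wave_driver_params")
  if (is.null(dt)) dt <- if (driver == "rd") 1e-5 else 1e-4
  stopifnot(dt > 0, duration > 0, stride >= dt)
  if (driver == "rd") {
    if (is.null(rd$r_e)) rd$r_e <- 4 * mean_bond_length(mesh)
    if (is.null(rd$lambda)) rd$lambda <- rd$r_e^2 / 6
    ell0 <- rd$r_e / 4
    bound <- ell0^2 / (8 * max(rd$D_U, rd$D_V, 1e-300))
    if (dt >= bound)
      stop(sprintf("dt = %g violates the diffusive stability bound %g", dt, bound))
    stimulus$mode <- match.arg(stimulus$mode %||% "periodic",
                               c("periodic", "random", "none"))
    if (is.null(stimulus$interval))
      stimulus$interval <- if (stimulus$mode == "random") 0.15 else 1.5
    if (is.null(stimulus$I_excite)) stimulus$I_excite <- rd$I_excite
  }
  structure(list(mesh = mesh, driver = driver, mech = mech, rd = rd,
                 coupling = coupling, wave = wave, dt = dt,
                 duration = duration, stimulus = stimulus, stride = stride,
                 neighbor_every = as.integer(neighbor_every), seed = seed,
                 uniform_zeta = uniform_zeta),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a crawling-cell simulation
#'
#' Executes the full explicit-Euler time loop (driver update, coupling
#' update, force evaluation, velocity solve, position update) in compiled
#' code and returns the sampled trajectory together with summary metrics and
#' the force-free / torque-free invariant residuals at every snapshot.
#'
#' @param config A `run_config`.
#' @return A `cell_trajectory`: list with `times`, per-snapshot matrices
#'   `x`, `y`, `U`, `V`, `zeta`, `trac_x`, `trac_y` (snapshots x elements),
#'   `com` (snapshots x 2), residual vectors `res_force` and `res_torque`,
#'   the echoed `config`, and `metrics` (final center of mass, maximal
#'   residuals, and per-cycle displacement when the driver is periodic).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mesh <- config$mesh
  mech <- config$mech
  n_steps <- round(config$duration / config$dt)
  stride_steps <- max(1L, round(config$stride / config$dt))

  zeta_init <- if (identical(config$coupling$zeta_init, "slip"))
    mech$zeta_slip else mech$zeta_stick
  eps_zeta <- config$coupling$eps_zeta %||% (mech$zeta_slip / 2)
  wave <- config$wave
  rd <- config$rd
  stim_mode <- if (config$driver == "wave") 2L else
    switch(config$stimulus$mode, periodic = 0L, random = 1L, none = 2L)

  par <- list(
    kappa = mech$kappa, xi = mech$xi, sigma_area = mech$sigma_area,
    zeta_slip = mech$zeta_slip, zeta_stick = mech$zeta_stick,
    dt = config$dt, n_steps = as.double(n_steps),
    stride_steps = as.integer(stride_steps),
    neighbor_every = config$neighbor_every,
    driver = if (config$driver == "wave") 0L else 1L,
    activator = mesh$activator - 1L,
    uniform_zeta = isTRUE(config$uniform_zeta),
    c0 = wave$c_0 %||% 0.5, omega = wave$omega %||% (2 * pi),
    qw = wave$q_w %||% 1, psi_zeta = wave$psi_zeta %||% 0,
    wave_sign = if (isTRUE(wave$literal_sign)) -1 else 1,
    ell_amp = mesh$rest_length *
      (if (config$driver == "wave") wave$ell_c_scale %||% 1
       else config$coupling$ell_V_scale %||% 1),
    D_U = rd$D_U, D_V = rd$D_V, alpha = rd$alpha, beta = rd$beta,
    K_K = rd$K_K, K_P = rd$K_P, S = rd$S, gamma = rd$gamma, mu = rd$mu,
    r_e = rd$r_e %||% (4 * mean_bond_length(mesh)),
    lambda = rd$lambda %||% ((rd$r_e %||% (4 * mean_bond_length(mesh)))^2 / 6),
    I_excite = config$stimulus$I_excite %||% 0.75,
    stim_mode = stim_mode,
    stim_interval = config$stimulus$interval %||% 1.5,
    a = config$coupling$a, A_v = config$coupling$A_v,
    tau_zeta = config$coupling$tau_zeta, eps_zeta = eps_zeta,
    v_star = config$coupling$v_star, sigma_V = config$coupling$sigma_V,
    V_star = config$coupling$V_star, zeta_init_value = zeta_init)

  out <- cpp_simulate(mesh$positions, mesh$bonds - 1L, mesh$rest_length,
                      mesh$triangles - 1L, par)
  S <- out$snapshots
  if (isTRUE(out$aborted))
    warning("simulation aborted early: ", out$abort_msg,
            " (returning ", S, " snapshots)")
  keep <- seq_len(S)
  # relative force-free / torque-free residuals; snapshots where the cell is
  # mechanically quiescent (traction scale at roundoff) carry no information
  # about the monopole, so the ratio is taken against an activity floor
  trac_scale <- out$trac_scale[keep]
  torque_scale <- out$torque_scale[keep]
  active <- trac_scale > 1e-6 * max(trac_scale)
  res_force <- out$mono_abs[keep] / pmax(trac_scale, 1e-300)
  res_torque <- out$torque_abs[keep] / pmax(torque_scale, 1e-300)
  traj <- structure(list(
    times = out$times[keep],
    x = out$x[keep, , drop = FALSE], y = out$y[keep, , drop = FALSE],
    U = out$U[keep, , drop = FALSE], V = out$V[keep, , drop = FALSE],
    zeta = out$zeta[keep, , drop = FALSE],
    trac_x = out$trac_x[keep, , drop = FALSE],
    trac_y = out$trac_y[keep, , drop = FALSE],
    com = out$com[keep, , drop = FALSE],
    res_force = res_force, res_torque = res_torque,
    mono_abs = out$mono_abs[keep], trac_scale = trac_scale,
    active = active,
    aborted = isTRUE(out$aborted),
    config = config), class = "cell_trajectory")

  period <- if (config$driver == "wave") 2 * pi / (wave$omega %||% (2 * pi))
            else if (stim_mode == 0L) config$stimulus$interval else NA_real_
  dR <- NA_real_
  if (is.finite(period)) {
    n_relax <- max(0L, min(5L, floor(config$duration / period) - 1L))
    if ((n_relax + 1) * period <= max(traj$times) + 1e-9)
      dR <- displacement_per_cycle(traj$times, traj$com[, 1], period, n_relax)
  }
  traj$metrics <- list(
    seed = config$seed,
    final_com = traj$com[S, ],
    max_res_force = if (any(active)) max(res_force[active]) else 0,
    max_res_torque = if (any(active)) max(res_torque[active]) else 0,
    period = period, delta_R = dR,
    delta_R_over_L = dR / mesh$L_cell)
  traj
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("cell_trajectory: %d snapshots over t = [%g, %g], N = %d elements\n",
              length(x$times), min(x$times), max(x$times), ncol(x$x)))
  cat(sprintf("  driver = %s%s, dt = %g\n", x$config$driver,
              if (x$aborted) " (ABORTED)" else "", x$config$dt))
  m <- x$metrics
  cat(sprintf("  final COM = (%.5g, %.5g); max |M1|/sum|f| = %.3g; max torque resid = %.3g\n",
              m$final_com[1], m$final_com[2], m$max_res_force, m$max_res_torque))
  if (is.finite(m$delta_R %||% NA))
    cat(sprintf("  displacement per cycle Delta R = %.5g (Delta R / L_cell = %.5g)\n",
                m$delta_R, m$delta_R_over_L))
  invisible(x)
}

#' @export
summary.cell_trajectory <- function(object, ...) {
  print(object)
  invisible(object$metrics)
}

#' @export
plot.cell_trajectory <- function(x, what = c("com", "snapshot"),
                                 snapshot = length(x$times), ...) {
  what <- match.arg(what)
  if (what == "com") {
    plot(x$com, type = "l", asp = 1, xlab = "x", ylab = "y",
         main = "center-of-mass trajectory", ...)
    points(x$com[1, 1], x$com[1, 2], pch = 19)
  } else {
    s <- snapshot
    plot(x$x[s, ], x$y[s, ], asp = 1, pch = 19,
         cex = 0.4 + 0.8 * (x$zeta[s, ] - min(x$zeta[s, ])) /
           max(1e-12, diff(range(x$zeta[s, ]))),
         col = grDevices::hcl.colors(100, "viridis")[
           pmax(1, pmin(100, 1 + round(99 * x$V[s, ] / max(1e-12, max(x$V[s, ])))))],
         xlab = "x", ylab = "y",
         main = sprintf("t = %g", x$times[s]), ...)
  }
  invisible(x)
}

#' Parameter scans of the per-cycle displacement
#'
#' `scan_wave` runs one prescribed-wave simulation per `(q_w, psi_zeta)`
#' grid point; `scan_coupled` runs one coupled RD simulation per
#' `(A_v, tau_zeta)` point. Runs are independent; a failing point is
#' recorded with `NA` instead of aborting the scan.
#'
#' @param config A `run_config` used as template (its driver-specific
#'   parameters are overridden per grid point).
#' @param q_w,psi_zeta,A_v,tau_zeta Grid values.
#' @return Data frame with the grid parameters, `delta_R` and
#'   `delta_R_over_L`.
#' @export
scan_wave <- function(config, q_w, psi_zeta) {
  grid <- expand.grid(q_w = q_w, psi_zeta = psi_zeta)
  res <- apply(grid, 1L, function(g) {
    cfg <- config
    cfg$wave$q_w <- g[["q_w"]]
    cfg$wave$psi_zeta <- g[["psi_zeta"]]
    tryCatch(run_experiment(cfg)$metrics$delta_R, error = function(e) NA_real_)
  })
  grid$delta_R <- res
  grid$delta_R_over_L <- res / config$mesh$L_cell
  grid
}

#' @rdname scan_wave
#' @export
scan_coupled <- function(config, A_v, tau_zeta) {
  grid <- expand.grid(A_v = A_v, tau_zeta = tau_zeta)
  res <- apply(grid, 1L, function(g) {
    cfg <- config
    cfg$coupling$A_v <- g[["A_v"]]
    cfg$coupling$tau_zeta <- g[["tau_zeta"]]
    tryCatch(run_experiment(cfg)$metrics$delta_R, error = function(e) NA_real_)
  })
  grid$delta_R <- res
  grid$delta_R_over_L <- res / config$mesh$L_cell
  grid
}

#' Deterministic test fixtures
#'
#' Builds the small deterministic inputs used throughout the test suite:
#' tiny meshes, a two-element dumbbell, and synthetic traction point-force
#' sets with analytically known multipoles.
#'
#' @param kind `"tiny-hex"` (7-element single-ring cell), `"dumbbell"`
#'   (2 elements, 1 bond) or `"synthetic-forces"` (random positions/forces
#'   with their exact monopole/dipole/torque computed by definition).
#' @param seed Seed for the synthetic force set.
#' @return The fixture: a `cell_mesh` or, for `"synthetic-forces"`, a list
#'   with `positions`, `forces`, and reference `M1`, `M2`, `torque`.
#' @export
make_fixture <- function(kind = c("tiny-hex", "dumbbell", "synthetic-forces"),
                         seed = 1) {
  kind <- match.arg(kind)
  if (kind == "tiny-hex") return(build_hexagonal_cell(1, 1))
  if (kind == "dumbbell") {
    mesh <- structure(list(
      positions = rbind(c(0, 0), c(1, 0)),
      bonds = matrix(c(1L, 2L), 1L, 2L),
      rest_length = 1,
      triangles = matrix(integer(0), 0L, 3L),
      activator = 2L, L_cell = 1, shape = "dumbbell"), class = "cell_mesh")
    return(mesh)
  }
  set.seed(seed)
  n <- 12L
  pos <- matrix(stats::rnorm(2 * n), n, 2)
  f <- matrix(stats::rnorm(2 * n), n, 2)
  f <- sweep(f, 2, colMeans(f))              # force-free by construction
  M2 <- t(pos) %*% f
  list(positions = pos, forces = f,
       M1 = colSums(f), M2 = M2, torque = M2[1, 2] - M2[2, 1])
}

#' Trajectory serialization
#'
#' Writes a trajectory as a long columnar CSV (one row per snapshot and
#' element: `time, element, x, y, U, V, zeta, trac_x, trac_y`) plus a JSON
#' sidecar with the scalar metadata (seed, dt, driver, metrics). Reading the
#' pair back reproduces the numeric arrays bit-exactly.
#'
#' @param traj A `cell_trajectory`.
#' @param prefix Output path prefix (`<prefix>.csv`, `<prefix>.json`).
#' @return Invisibly, the file paths.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "cell_trajectory"))
  S <- length(traj$times); N <- ncol(traj$x)
  df <- data.frame(
    time = rep(traj$times, each = N),
    element = rep(seq_len(N), times = S),
    x = as.vector(t(traj$x)), y = as.vector(t(traj$y)),
    U = as.vector(t(traj$U)), V = as.vector(t(traj$V)),
    zeta = as.vector(t(traj$zeta)),
    trac_x = as.vector(t(traj$trac_x)), trac_y = as.vector(t(traj$trac_y)))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  meta <- list(driver = traj$config$driver, dt = traj$config$dt,
               stride = traj$config$stride,
               seed = traj$config$seed,
               res_force = traj$res_force, res_torque = traj$res_torque,
               metrics = traj$metrics[c("max_res_force", "max_res_torque",
                                        "period", "delta_R", "delta_R_over_L")])
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, js))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  times <- unique(df$time)
  S <- length(times); N <- max(df$element)
  shape <- function(col) matrix(df[[col]], S, N, byrow = TRUE)
  traj <- structure(list(
    times = times,
    x = shape("x"), y = shape("y"), U = shape("U"), V = shape("V"),
    zeta = shape("zeta"), trac_x = shape("trac_x"), trac_y = shape("trac_y"),
    com = cbind(rowMeans(shape("x")), rowMeans(shape("y"))),
    res_force = meta$res_force, res_torque = meta$res_torque,
    aborted = FALSE,
    config = list(driver = meta$driver, dt = meta$dt, stride = meta$stride,
                  seed = meta$seed)), class = "cell_trajectory")
  traj$metrics <- as.list(meta$metrics)
  traj
}

#' Write a metrics summary as JSON
#'
#' @param traj A `cell_trajectory`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(traj, path) {
  m <- traj$metrics
  m$final_com <- as.numeric(m$final_com)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
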