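test_that("actuator elongation saturates and matches direct evaluation", {
  expect_identical(actuator_from_chem(0, 0), 0)
  expect_equal(actuator_from_chem(1e6, 1e6, a = pi, ell_V = 0.3), 0.3,
               tolerance = 1e-9)
  # V_ij = 0.5, a = pi -> l_V tanh(pi/2)
  ell <- 0.104828
  expect_equal(actuator_from_chem(0.5, 0.5, a = pi, ell_V = ell),
               ell * tanh(pi / 2))
  # monotone in V_ij, bounded by l_V
  v <- seq(0, 5, by = 0.1)
  out <- actuator_from_chem(v, v, a = pi, ell_V = 1)
  expect_true(all(diff(out) > 0))
  expect_true(all(out >= 0 & out < 1))
})

test_that("stick-slip transition functions have the stated limits", {
  expect_equal(h_v(1, v_star = 1), 0)
  expect_equal(h_v(0), -0.5)
  expect_equal(h_v(1e9), 0.5, tolerance = 1e-12)
  expect_equal(h_V(0.5, sigma_V = 2 * pi, V_star = 0.5), 0)
  expect_true(h_V(0.9, 2 * pi, 0.5) > 0 && h_V(0.1, 2 * pi, 0.5) < 0)
  expect_true(h_V(0.9, -2 * pi, 0.5) < 0)   # sign follows sigma_V (V - V*)
  zs <- 0.011; zt <- 0.11; eps <- zs / 2
  expect_equal(h_zeta((zs + zt) / 2, zs, zt, eps), 0, tolerance = 1e-7)
  # the slip-side wall saturates within a few transition widths eps
  expect_equal(h_zeta(zs / 10, zs, zt, eps), 1, tolerance = 0.03)
  expect_equal(h_zeta(3 * zt, zs, zt, eps), -1, tolerance = 1e-12)
})

test_that("friction dynamics: mixing ratio selects the drive and zeta stays bounded", {
  mesh <- build_hexagonal_cell(1)
  mech <- mech_params(mesh, zeta_slip = 0.011, zeta_stick = 0.11)
  pmech <- coupling_params(mech, A_v = 1)
  pchem <- coupling_params(mech, A_v = 0)
  # A_v = 1: independent of V; A_v = 0: independent of v
  expect_identical(friction_drive(0.05, 0.3, 0.1, mech, pmech),
                   friction_drive(0.05, 0.3, 0.9, mech, pmech))
  expect_identical(friction_drive(0.05, 0.3, 0.1, mech, pchem),
                   friction_drive(0.05, 7.0, 0.1, mech, pchem))

  # chemically driven de-adhesion: V jumps 0 -> 1 relaxes stick toward slip
  # on a timescale of order tau * (zeta_stick - zeta_slip) / 0.5
  p <- coupling_params(mech, A_v = 0, tau_zeta = 0.01, sigma_V = 2 * pi)
  dt <- 1e-5
  zeta <- mech$zeta_stick
  t_half <- NA
  mid <- (mech$zeta_slip + mech$zeta_stick) / 2
  for (k in seq_len(50000)) {
    zeta <- zeta + dt * friction_drive(zeta, 0, 1, mech, p)
    if (is.na(t_half) && zeta < mid) t_half <- k * dt
  }
  t_scale <- p$tau_zeta * (mech$zeta_stick - mech$zeta_slip) / 0.5
  expect_lt(abs(zeta - mech$zeta_slip), 3 * mech$zeta_slip / 2)
  expect_true(t_half > 0.2 * t_scale && t_half < 5 * t_scale)

  # the h_zeta walls confine zeta for any bounded drive
  for (drive in list(c(v = 1e3, V = 1), c(v = 0, V = 0))) {
    zeta <- mid
    for (k in seq_len(30000))
      zeta <- zeta + dt * friction_drive(zeta, drive["v"], drive["V"], mech, p)
    expect_true(zeta >= mech$zeta_slip * 0.9 && zeta <= mech$zeta_stick * 1.1)
  }
})

test_that("prescribed wave: values, two-state friction, periodicity, direction", {
  w <- wave_driver_params(q_w = pi, psi_zeta = 0)
  # at the activator: c = 0 at t = 0 and c = 2 c_0 = 1 at omega t = pi
  expect_equal(prescribed_wave(0, 0, 0, w)$c, 0)
  expect_equal(prescribed_wave(0.5, 0, 0, w)$c, 1)   # omega = 2 pi
  # friction branches (psi = 0): slip on (0, pi], stick on (pi, 2 pi]
  out <- prescribed_wave(0.25, 0, 0, w, zeta_slip = 1, zeta_stick = 9)  # phi = pi/2
  expect_identical(out$zeta, 1)
  out <- prescribed_wave(0.75, 0, 0, w, zeta_slip = 1, zeta_stick = 9)  # phi = 3 pi/2
  expect_identical(out$zeta, 9)
  # 2 pi / omega periodicity for every element
  x <- seq(-0.5, 0.5, by = 0.1)
  a <- prescribed_wave(0.3, x, 0.5, w, 1, 9)
  b <- prescribed_wave(1.3, x, 0.5, w, 1, 9)
  expect_equal(a$c, b$c, tolerance = 1e-12)
  expect_identical(a$zeta, b$zeta)
  # crest propagates from the activator (right) to the left at speed omega/q_w
  xg <- seq(-2, 0.5, by = 0.001)
  crest <- vapply(c(0.25, 0.35), function(t)
    xg[which.max(prescribed_wave(t, xg, 0.5, w)$c)], 0)
  expect_lt(crest[2], crest[1])
  expect_equal(crest[1] - crest[2], 2 * pi / pi * 0.1, tolerance = 0.05)
  # the literal printed sign propagates the crest rightward instead
  wl <- wave_driver_params(q_w = pi, psi_zeta = 0, literal_sign = TRUE)
  crest_l <- vapply(c(0.25, 0.35), function(t)
    xg[which.max(prescribed_wave(t, xg, 0.5, wl)$c)], 0)
  expect_gt(crest_l[2], crest_l[1])
})
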