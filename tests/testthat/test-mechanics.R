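test_that("parameter bookkeeping matches the model scalings", {
  for (L in c(1, 1.4)) {
    n <- if (L == 1) 5 else 7
    mesh <- build_hexagonal_cell(n, L)
    p <- mech_params(mesh)
    N <- nrow(mesh$positions)
    expect_equal(p$zeta_slip, L^2 / N)
    expect_equal(p$zeta_stick, 10 * L^2 / N)
    L_bond <- sum(mesh$rest_length)
    expect_equal(p$xi, L^2 / L_bond)
    # dimensionless identity: 2 pi xi_cell / (k_cell T0) = 0.2 pi L^3
    xi_cell <- p$xi * L_bond
    k_cell <- p$kappa / L
    expect_equal(2 * pi * xi_cell / k_cell, 0.2 * pi * L^3, tolerance = 1e-12)
  }
  u <- model_units()
  expect_equal(u$length_um(1 / sqrt(91)), 10 / sqrt(91))
  expect_equal(u$diffusion_um2_per_s(0.48), 0.8)
})

test_that("bond forces vanish at rest and match the two-element solution", {
  mesh <- build_hexagonal_cell(2)
  p0 <- mech_params(mesh, sigma_area = 0)
  f <- conservative_forces(mesh, params = p0)
  expect_lt(max(abs(f)), 1e-12)
  # with the area term only the total force/torque vanish
  p <- mech_params(mesh)
  f <- conservative_forces(mesh, params = p)
  expect_lt(max(abs(colSums(f))), 1e-12)
  rel <- sweep(mesh$positions, 2, colMeans(mesh$positions))
  torque <- sum(rel[, 1] * f[, 2] - rel[, 2] * f[, 1])
  expect_lt(abs(torque), 1e-12 * sum(sqrt(rowSums(rel^2)) * sqrt(rowSums(f^2))))

  # dumbbell stretched to r: strain-normalized spring, magnitude kappa/l * (r - l)
  db <- make_fixture("dumbbell")
  dbp <- mech_params(db, zeta_slip = 0.1, xi = 0.3, sigma_area = 0)
  fd <- conservative_forces(db, rbind(c(0, 0), c(1.3, 0)), 0, dbp)
  expect_equal(fd[1, ], c(dbp$kappa * 0.3, 0))
  expect_equal(fd[2, ], c(-dbp$kappa * 0.3, 0))
})

test_that("analytic forces agree with the finite-difference energy gradient", {
  mesh <- build_hexagonal_cell(2)
  p <- mech_params(mesh)
  set.seed(7)
  pos <- mesh$positions + 0.02 * mean_bond_length(mesh) *
    matrix(rnorm(2 * nrow(mesh$positions)), ncol = 2)
  ell_act <- 0.1 * mesh$rest_length
  f <- conservative_forces(mesh, pos, ell_act, p)
  g <- fd_gradient(function(x) total_energy(mesh, matrix(x, ncol = 2), ell_act, p),
                   as.vector(pos))
  expect_equal(as.vector(f), -g, tolerance = 1e-6)
})

test_that("velocity solve satisfies the coupled force balance", {
  mesh <- build_hexagonal_cell(3)
  p <- mech_params(mesh)
  N <- nrow(mesh$positions)
  # F = 0 -> v = 0
  expect_equal(solve_velocities(mesh, p$zeta_stick, matrix(0, N, 2), p),
               matrix(0, N, 2))
  # homogeneous friction + force-free internal forces -> no COM motion
  set.seed(11)
  pos <- mesh$positions + 0.05 * mean_bond_length(mesh) * matrix(rnorm(2 * N), ncol = 2)
  f <- conservative_forces(mesh, pos, 0, p)
  v <- solve_velocities(mesh, p$zeta_stick, f, p)
  expect_lt(max(abs(colMeans(v))), 1e-12 * max(abs(v)))
  # residual of the linear system
  zeta <- runif(N, p$zeta_slip, p$zeta_stick)
  v <- solve_velocities(mesh, zeta, f, p)
  # sum zeta_i v_i = sum F_i for the exact solution
  expect_equal(colSums(zeta * v), colSums(f), tolerance = 1e-10)
})

test_that("dumbbell velocities match the hand-solved 2x2 system", {
  db <- make_fixture("dumbbell")
  p <- mech_params(db, zeta_slip = 0.19, zeta_stick = 0.51, kappa = 10,
                   xi = 0.3, sigma_area = 0)
  z1 <- 0.2; z2 <- 0.5; f <- 2; xl <- p$xi * 1   # xi * rest length
  forces <- rbind(c(f, 0), c(-f, 0))
  v <- solve_velocities(db, c(z1, z2), forces, p)
  det <- z1 * z2 + xl * (z1 + z2)
  expect_equal(v[, 1], c(f * z2 / det, -f * z1 / det), tolerance = 1e-12)
  expect_equal(v[, 2], c(0, 0))
})

test_that("explicit Euler position update is exact for constant velocity", {
  pos <- matrix(rnorm(10), 5, 2)
  v <- matrix(rnorm(10), 5, 2)
  p2 <- pos
  for (k in 1:7) p2 <- step_positions(p2, v, 0.01)
  expect_equal(p2, pos + 7 * 0.01 * v, tolerance = 1e-14)
  expect_identical(step_positions(pos, 0 * v, 0.5), pos)
  expect_error(step_positions(pos, v, -1))
})

test_that("degenerate triangles are a hard error", {
  mesh <- build_hexagonal_cell(1)
  pos <- mesh$positions
  tri1 <- mesh$triangles[1, ]
  # collapse the first triangle onto a line
  pos[tri1[3], ] <- (pos[tri1[1], ] + pos[tri1[2], ]) / 2
  expect_error(conservative_forces(mesh, pos, 0, mech_params(mesh)),
               "degenerate")
})
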