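test_that("traction forces are the elementwise friction-velocity product", {
  expect_identical(traction_forces(2, rbind(c(0, 0))), rbind(c(0, 0)))
  expect_identical(traction_forces(2, rbind(c(1, -1))), rbind(c(2, -2)))
  z <- c(1, 3)
  v <- rbind(c(1, 2), c(-1, 0.5))
  expect_equal(traction_forces(z, v), z * v)
})

lab_frame <- function() traction_frame(c(0, 0), c(1, 0))

test_that("multipoles of point-force pairs match the defining sums", {
  d <- 0.8; f <- 1.5
  pos <- rbind(c(d / 2, 0), c(-d / 2, 0))
  # contractile pair: tractions point inward along the separation
  mp <- multipoles(pos, rbind(c(-f, 0), c(f, 0)), lab_frame())
  expect_equal(mp$M1, c(0, 0))
  expect_equal(mp$M2, rbind(c(-f * d, 0), c(0, 0)))
  expect_equal(mp$torque, 0)
  # tractions rotated +90 degrees: M12 = sum r1 f2 = -f d, M21 = sum r2 f1 = 0,
  # so the torque is M12 - M21 = -f d
  mp <- multipoles(pos, rbind(c(0, -f), c(0, f)), lab_frame())
  expect_equal(mp$M2, rbind(c(0, -f * d), c(0, 0)))
  expect_equal(mp$torque, -f * d)
  # mirror-symmetric configuration: the quadrupole vanishes exactly
  set.seed(2)
  P <- matrix(rnorm(10), 5, 2); Q <- matrix(rnorm(10), 5, 2)
  mp <- multipoles(rbind(P, -P), rbind(Q, -Q), lab_frame())
  expect_lt(max(abs(mp$M3)), 1e-12)
})

test_that("torque and monopole norm are invariant under frame rotation", {
  set.seed(4)
  pos <- matrix(rnorm(16), 8, 2)
  f <- matrix(rnorm(16), 8, 2)
  ref <- multipoles(pos, f, lab_frame())
  for (th in c(0.3, 1.2, -2.1)) {
    fr <- traction_frame(c(0, 0), c(cos(th), sin(th)))
    mp <- multipoles(pos, f, fr)
    expect_equal(mp$torque, ref$torque, tolerance = 1e-12)
    expect_equal(sqrt(sum(mp$M1^2)), sqrt(sum(ref$M1^2)), tolerance = 1e-12)
  }
})

test_that("dipole eigenvalue 1 is the one aligned with the velocity", {
  # forces f = (a x, b y) on a balanced grid give a diagonal dipole with
  # eigen-axes x and y (sum x = sum y = 0 makes the cross moments vanish)
  g <- as.matrix(expand.grid(x = c(-1, -0.4, 0.4, 1), y = c(-1, -0.4, 0.4, 1)))
  pos <- unname(g)
  f <- cbind(3 * pos[, 1], -1 * pos[, 2])
  mp <- multipoles(pos, f, lab_frame())     # velocity along x
  expect_equal(mp$theta1, 0, tolerance = 1e-8)
  expect_equal(Re(mp$lambda1), 3 * sum(pos[, 1]^2), tolerance = 1e-8)
  expect_equal(abs(mp$theta2), pi / 2, tolerance = 1e-8)
})

test_that("per-cycle displacement handles rest, drift, and short input", {
  times <- seq(0, 10, by = 0.01)
  expect_equal(displacement_per_cycle(times, rep(1.5, length(times)), 1.5), 0)
  expect_equal(displacement_per_cycle(times, 0.7 * times, 1.5, n_relax = 5),
               0.7 * 1.5, tolerance = 1e-10)
  expect_error(displacement_per_cycle(times[1:100], times[1:100], 1.5),
               "too short")
})

test_that("MSD and VAC: ballistic line, circular motion, diffusive walk", {
  times <- seq(0, 20, by = 0.05)
  # straight line at constant speed: MSD = v^2 t^2, VAC = 1
  v <- c(0.3, -0.4)
  com <- cbind(v[1] * times, v[2] * times)
  mv <- msd_vac(times, com)
  expect_equal(mv$msd$msd, sum(v^2) * mv$msd$lag^2, tolerance = 1e-10)
  expect_equal(mv$vac$vac, rep(1, nrow(mv$vac)), tolerance = 1e-10)
  # circular motion at angular rate Omega: VAC(t) = cos(Omega t)
  Om <- 1.3
  com <- cbind(cos(Om * times), sin(Om * times))
  mv <- msd_vac(times, com)
  expect_equal(mv$vac$vac, cos(Om * mv$vac$lag), tolerance = 1e-3)
  # isotropic random walk: log-log MSD slope near 1 at large lag
  set.seed(9)
  n <- 20000
  com <- cbind(cumsum(rnorm(n, sd = 0.1)), cumsum(rnorm(n, sd = 0.1)))
  mv <- msd_vac(seq_len(n) * 0.01, com, max_lag_frac = 0.05)
  d <- mv$msd[mv$msd$lag > quantile(mv$msd$lag, 0.5), ]
  slope <- coef(lm(log(msd) ~ log(lag), d))[2]
  expect_equal(unname(slope), 1, tolerance = 0.2)
})

test_that("crossover extraction finds the slope-1.5 lag of a known curve", {
  lag <- exp(seq(log(0.01), log(100), length.out = 120))
  msd <- lag^2 / (1 + lag)   # log-slope 2 - t/(1+t); equals 1.5 at t = 1
  expect_equal(msd_crossover(lag, msd), 1, tolerance = 0.15)
  # ballistic-only curve has no crossover
  expect_true(is.na(msd_crossover(lag, lag^2)))
})

test_that("frame is flagged undefined below the speed threshold", {
  fr <- traction_frame(c(0, 0), c(1e-9, 0))
  expect_false(fr$defined)
  expect_true(is.na(fr$phi_v))
  fr <- traction_frame(c(0, 0), c(1e-3, 0))
  expect_true(fr$defined)
  expect_equal(fr$axis2, c(0, 1))
})
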