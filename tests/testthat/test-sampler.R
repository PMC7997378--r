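kT300 <- kB() * 300

test_that("collective variables: Rg of two masses, contact limits, trans dihedral", {
  x2 <- rbind(c(0, 0, 0), c(6, 0, 0))
  cv <- collective_variable("rg", 1:2)
  expect_equal(cv_value(x2, c(1, 1), cv)$value, 3)  # d/2 for equal masses

  ## contacts: all pairs far beyond r0 -> ~0; at r = 0 -> full count
  cvc <- collective_variable("contacts", list(1, 2), r0 = 5, n = 6, m = 12)
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_lt(cv_value(far, c(1, 1), cvc)$value, 1e-6)
  near <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  expect_equal(cv_value(near, c(1, 1), cvc)$value, 1, tolerance = 1e-3)

  ## 4 coplanar centroids, trans arrangement: dihedral = +-180 deg
  xd <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  cvd <- collective_variable("dihedral", list(1, 2, 3, 4))
  expect_equal(abs(cv_value(xd, rep(1, 4), cvd)$value), pi, tolerance = 1e-12)

  expect_error(collective_variable("rg", integer(0)), "empty")
})

test_that("collective variable gradients agree with finite differences", {
  set.seed(15)
  x <- matrix(rnorm(24, sd = 4), 8, 3)
  m <- runif(8, 1, 3)
  cvs <- list(collective_variable("rg", 1:8),
              collective_variable("distance", list(1:4, 5:8)),
              collective_variable("contacts", list(1:4, 5:8), r0 = 6),
              collective_variable("dihedral", list(1:2, 3:4, 5:6, 7:8)))
  h <- 1e-6
  for (cv in cvs) {
    g <- cv_value(x, m, cv)$grad
    for (k in c(2, 6)) for (d in 1:3) {
      xp <- x; xp[k, d] <- xp[k, d] + h
      xm <- x; xm[k, d] <- xm[k, d] - h
      fd <- (cv_value(xp, m, cv)$value - cv_value(xm, m, cv)$value) / (2 * h)
      expect_equal(g[k, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("PBMetaD deposits: first height h0, well-tempered decay, gamma = Inf", {
  cv <- collective_variable("distance", list(1, 2))
  b <- pbmetad_bias(list(cv), list(c(0, 10, 101)), widths = 0.5,
                    height = 1.0, bias_factor = 30)
  b1 <- pbmetad_update(b, 5)
  expect_equal(b1$deposits[[1]]$height, 1.0)     # V = 0 everywhere at first
  ## repeated deposits at one point decay under well-tempering
  b2 <- b1
  for (k in 1:20) b2 <- pbmetad_update(b2, 5)
  h <- b2$deposits[[1]]$height
  expect_true(all(diff(h) < 0))
  ## height after bias V follows the well-tempered rule
  V_before <- metasaxs:::.bias_eval(b1, 5)
  expect_equal(b2$deposits[[1]]$height[2],
               1.0 * exp(-V_before / ((30 - 1) * kT300)))

  binf <- pbmetad_bias(list(cv), list(c(0, 10, 101)), widths = 0.5,
                       height = 1.0, bias_factor = Inf)
  for (k in 1:5) binf <- pbmetad_update(binf, 5)
  expect_equal(binf$deposits[[1]]$height, rep(1.0, 5))
})

test_that("parallel-bias weights split deposits across multiple CVs", {
  cv1 <- collective_variable("distance", list(1, 2))
  cv2 <- collective_variable("rg", 1:2)
  b <- pbmetad_bias(list(cv1, cv2), list(c(0, 10, 101), c(0, 5, 51)),
                    widths = c(0.5, 0.25), height = 1.0)
  b <- pbmetad_update(b, c(5, 2.5))
  ## equal (zero) starting bias: each CV gets height h0 * 1/2
  expect_equal(b$deposits[[1]]$height, 0.5)
  expect_equal(b$deposits[[2]]$height, 0.5)
  ## V_PB of multiple CVs is bounded above by each single-CV bias
  vpb <- pbmetad_vpb(b, c(5, 2.5))
  expect_lte(vpb, metasaxs:::.bias_eval(b, c(5, 2.5))[1] + 1e-12)
})

test_that("multiple-walker sharing: 1 x N and N x (1 each round-robin) give one pool", {
  cv <- collective_variable("distance", list(1, 2))
  pts <- seq(2, 8, length.out = 12)
  mk <- function() pbmetad_bias(list(cv), list(c(0, 10, 201)), widths = 0.4)
  ## one walker depositing the whole schedule
  b1 <- mk()
  for (s in pts) b1 <- pbmetad_update(b1, s)
  ## four walkers sharing the pool, interleaved on the same schedule
  b4 <- mk()
  for (k in seq_along(pts)) b4 <- pbmetad_update(b4, pts[k])
  expect_equal(b1$pots[[1]]$V, b4$pots[[1]]$V, tolerance = 1e-14)
  expect_equal(b1$deposits[[1]], b4$deposits[[1]], tolerance = 1e-14)
})

test_that("Langevin integrator: zero-friction energy conservation, determinism", {
  ## harmonic dimer, no thermostat: total energy drift < 1e-4 relative
  x <- rbind(c(-1, 0, 0), c(1, 0, 0))
  bonds <- data.frame(i = 1, j = 2, k = 20, r0 = 1.6)
  sys <- toy_system(x, c(10, 10), bonds = bonds)
  sys$v <- rbind(c(0.1, 0.05, 0), c(-0.1, -0.05, 0))
  ## kick-drift leapfrog keeps velocities at half steps: total energy is
  ## evaluated with the midpoint kinetic energy (v_{k-1/2} + v_{k+1/2})/2
  energy_at <- function(x, vmid, m) {
    s2 <- sys; s2$x <- x
    prior_energy_forces(s2)$energy +
      sum(0.5 * m * rowSums(vmid^2)) / metasaxs:::ENERGY_TO_DYN
  }
  e0 <- energy_at(sys$x, sys$v, sys$masses)
  es <- numeric(10000)
  s <- sys
  for (k in 1:10000) {
    x_prev <- s$x; v_prev <- s$v
    f <- prior_energy_forces(s)$forces
    s <- langevin_step(s, f, dt = 0.001, friction = 0, temperature = 300)
    es[k] <- energy_at(x_prev, (v_prev + s$v) / 2, s$masses)
  }
  drift <- abs(mean(es[9001:10000]) - mean(es[1:1000])) / abs(e0)
  expect_lt(drift, 1e-4)

  ## same seed twice: bitwise identical trajectory
  run1 <- { set.seed(99); s1 <- sys
    for (k in 1:50) s1 <- langevin_step(s1, prior_energy_forces(s1)$forces,
                                        0.01, 1.0, 300); s1$x }
  run2 <- { set.seed(99); s2 <- sys
    for (k in 1:50) s2 <- langevin_step(s2, prior_energy_forces(s2)$forces,
                                        0.01, 1.0, 300); s2$x }
  expect_identical(run1, run2)

  expect_error(langevin_step(sys, matrix(NaN, 2, 3), 0.01, 1, 300), "particle")
  expect_error(langevin_step(sys, matrix(0, 2, 3), 0, 1, 300), "positive")
})

test_that("thermostat reaches equipartition: velocity variance ~ kB T / m", {
  set.seed(123)
  sys <- toy_system(matrix(0, 1, 3), 10)
  v2 <- numeric(0)
  s <- sys
  f0 <- matrix(0, 1, 3)
  n <- 2e5
  vs <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    s <- langevin_step(s, f0, dt = 0.02, friction = 4.0, temperature = 300)
    vs[k, ] <- s$v
  }
  ## target variance in dynamics units
  target <- kT300 * metasaxs:::ENERGY_TO_DYN / 10
  est <- mean(apply(vs[-(1:1000), ], 2, var))
  expect_equal(est, target, tolerance = 0.02)
})

test_that("well-tempered PBMetaD reconstructs the double-well free energy", {
  ## 2-particle dumbbell, one distance CV; analytic profile includes the
  ## -2 kT log(s) Jacobian of a distance coordinate
  x <- rbind(c(-12, 0, 0), c(12, 0, 0))
  sys <- toy_system(x, c(5, 5),
                    double_well = list(groupA = 1, groupB = 2, center = 18,
                                       half_sep = 6, height = 6))
  cv <- collective_variable("distance", list(1, 2))
  bias <- pbmetad_bias(list(cv), list(c(6, 34, 281)), widths = 0.5,
                       height = 1.0, bias_factor = 4, temperature = 300)
  run <- run_restrained(sys, n_replicas = 1, n_steps = 200000, dt = 0.02,
                        friction = 0.5, bias = bias, bias_stride = 100,
                        record_stride = 200, seed = 5)
  fes <- pbmetad_fes(run$bias)
  U <- 6 * ((fes$s - 18)^2 / 36 - 1)^2
  Fan <- U - 2 * kT300 * log(fes$s)
  Fan <- Fan - min(Fan)
  sel <- Fan < 8                      # thermally relevant region (~3 kT)
  dev <- fes$F - Fan
  dev <- dev - mean(dev[sel])
  expect_lt(max(abs(dev[sel])) / kT300, 0.5)
  ## both wells visited: finite weight on each side of the barrier
  d <- dumbbell_distance(run, 1, 2)
  expect_gt(mean(d < 18), 0.15)
  expect_gt(mean(d > 18), 0.15)
})

test_that("restraint stride: exactly floor(n/10) evaluations; null restraint = control", {
  sys <- make_dumbbell_system()
  inp <- dumbbell_recovery_inputs()
  run <- run_restrained(sys, n_replicas = 2, n_steps = 205,
                        restraints = inp$restraints, restraint_stride = 10,
                        record_stride = 50, seed = 3)
  expect_length(run$traces$step, 20)  # floor(205/10)

  ## no restraints, no bias: identical to the plain sampler with same seed
  a <- run_restrained(sys, n_replicas = 2, n_steps = 300, restraints = NULL,
                      record_stride = 50, seed = 8)
  b <- run_restrained(sys, n_replicas = 2, n_steps = 300, restraints = NULL,
                      record_stride = 50, seed = 8)
  expect_identical(a$frames, b$frames)
})

test_that("unbiased replicas sample the double-well Boltzmann populations", {
  ## flat-bottom check at reduced barrier so both states are visited often
  sys <- make_dumbbell_system(barrier = 2)
  gA <- attr(sys, "groupA"); gB <- attr(sys, "groupB")
  run <- run_restrained(sys, n_replicas = 6, n_steps = 60000,
                        restraints = NULL, record_stride = 20, seed = 17)
  frac <- compact_fraction(run, gA, gB, 18)
  ## reference from direct 1-d integration over the COM-distance marginal:
  ## p(D) ~ D^2 exp(-U(D)/kT) (internal globule modes factor out)
  D <- seq(6, 34, by = 0.01)
  U <- 2 * ((D - 18)^2 / 36 - 1)^2
  p <- D^2 * exp(-U / kT300)
  ref <- sum(p[D < 18]) / sum(p)
  expect_lt(abs(frac - ref), 0.06)
})

test_that("restraint pulls the forward mean toward the target as priors tighten", {
  inp <- dumbbell_recovery_inputs()
  ## pin sigma at three prior widths by collapsing the bounds
  dev <- vapply(c(20, 6, 1.5), function(s) {
    run <- run_restrained(inp$sys, n_replicas = 4, n_steps = 30000,
                          restraints = inp$restraints,
                          meta_options = list(sigma_bounds = c(s * 0.999, s * 1.001),
                                              sigma0 = s,
                                              sample_lambda = FALSE),
                          record_stride = 50, seed = 31)
    nf <- nrow(run$traces$fbar)
    keep <- seq(floor(nf / 2), nf)
    mean(abs(colMeans(run$traces$fbar[keep, , drop = FALSE]) /
             run$traces$targets - 1))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})
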