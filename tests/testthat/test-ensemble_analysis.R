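kT300 <- kB() * 300

test_that("chi2 with scale: exact match, factor-2 curve, grid-search oracle", {
  q <- seq(0.02, 0.2, by = 0.01)
  I <- 100 * exp(-150 * q^2)
  e <- 0.03 * I
  expt <- saxs_curve(q, I, e)
  calc <- saxs_curve(q, I)
  res <- chi2_with_scale(calc, expt, lambda_bounds = c(0.5, 1.5))
  expect_equal(res$chi2, 0, tolerance = 1e-20)
  expect_equal(res$lambda, 1)
  expect_equal(res$n_q, 19)

  res2 <- chi2_with_scale(saxs_curve(q, 2 * I), expt, lambda_bounds = c(0, 2))
  expect_equal(res2$lambda, 0.5)
  expect_equal(res2$chi2, 0, tolerance = 1e-20)

  ## random curves: closed-form lambda equals a fine grid search
  set.seed(18)
  Ic <- I * (1 + rnorm(length(q), sd = 0.15))
  calc3 <- saxs_curve(q, Ic)
  res3 <- chi2_with_scale(calc3, expt)
  grid <- seq(res3$lambda - 0.1, res3$lambda + 0.1, length.out = 20001)
  chi_at <- vapply(grid, function(l) mean((l * Ic - I)^2 / e^2), numeric(1))
  expect_equal(res3$lambda, grid[which.min(chi_at)], tolerance = 1e-5)

  ## invariances: common rescale leaves chi2; calc rescale inverts lambda
  resc <- chi2_with_scale(saxs_curve(q, 3 * Ic), saxs_curve(q, 3 * I, 3 * e))
  expect_equal(resc$chi2, res3$chi2, tolerance = 1e-10)
  resl <- chi2_with_scale(saxs_curve(q, 4 * Ic), expt)
  expect_equal(resl$lambda, res3$lambda / 4, tolerance = 1e-10)

  expect_error(chi2_with_scale(calc, expt, q_range = c(0.5, 0.9)), "overlap")
  expect_warning(chi2_with_scale(calc, saxs_curve(q, I)), "unit errors")
})

test_that("correlation trace: proportional, anti-correlated, covariance oracle", {
  targ <- c(5, 4, 3, 2.5, 2, 1.5, 1, 0.8, 0.6, 0.5, 0.4)
  expect_equal(correlation_trace(2.5 * targ, targ)$r, 1)
  expect_equal(correlation_trace(-targ + 6, targ)$r, -1)

  set.seed(7)
  fbar <- matrix(rnorm(33), 3, 11)
  tr <- correlation_trace(fbar, targ)
  for (k in 1:3) {
    x <- fbar[k, ]
    r_direct <- sum((x - mean(x)) * (targ - mean(targ))) /
      sqrt(sum((x - mean(x))^2) * sum((targ - mean(targ))^2))
    expect_equal(tr$r[k], r_direct, tolerance = 1e-12)
    expect_equal(tr$ss_dev[k], sum((x - targ)^2))
    fit <- stats::lm(x ~ targ)
    expect_equal(tr$slope[k], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(tr$intercept[k], unname(coef(fit)[1]), tolerance = 1e-10)
  }
  expect_true(is.na(correlation_trace(rep(2, 11), targ)$r))
})

test_that("Kratky: 1/q^2 plateau, Guinier-form maximum at sqrt(3)/Rg, pointwise", {
  q <- seq(0.01, 0.3, by = 0.001)
  flat <- kratky(saxs_curve(q, 7 / q^2))
  expect_equal(flat$kratky, rep(7, length(q)), tolerance = 1e-12)

  rg <- 15
  gcur <- saxs_curve(q, 50 * exp(-q^2 * rg^2 / 3))
  km <- kratky(gcur)
  expect_equal(km$q[which.max(km$kratky)], sqrt(3) / rg, tolerance = 0.01)

  set.seed(2)
  I <- runif(length(q), 1, 5)
  expect_equal(kratky(saxs_curve(q, I))$kratky, q^2 * I)
})

test_that("Guinier fit: exact model, hard-sphere oracle, no-regime error", {
  q <- seq(0.002, 0.2, by = 0.002)
  rg <- 21
  exact <- saxs_curve(q, 123 * exp(-q^2 * rg^2 / 3))
  fit <- guinier_rg(exact)
  expect_equal(fit$Rg, 21, tolerance = 1e-6)
  expect_equal(fit$I0, 123, tolerance = 1e-6)

  ## homogeneous sphere of radius R: Rg = R sqrt(3/5)
  R <- 30
  qr <- q * R
  Isph <- (3 * (sin(qr) - qr * cos(qr)) / qr^3)^2
  fs <- guinier_rg(saxs_curve(q, Isph))
  expect_equal(fs$Rg, R * sqrt(3 / 5), tolerance = 0.02)

  expect_error(guinier_rg(saxs_curve(q, 1 + q)), "Guinier")
})

test_that("Rg distribution: degenerate ensembles and two-state mean", {
  fr <- matrix(rnorm(30, sd = 5), 10, 3)
  same <- replica_ensemble(list(fr, fr, fr, fr))
  rd <- rg_distribution(same)
  expect_equal(rd$mean, frame_rg(fr))
  expect_equal(rd$se, 0, tolerance = 1e-12)
  expect_equal(unname(diff(range(rd$rg))), 0)

  ## 50:50 two-state with Rg 15 and 25: mean 20
  mk <- function(rg) {
    ## 2 particles at distance 2 rg have Rg = rg
    rbind(c(-rg, 0, 0), c(rg, 0, 0))
  }
  frames <- c(replicate(50, mk(15), simplify = FALSE),
              replicate(50, mk(25), simplify = FALSE))
  rd2 <- rg_distribution(replica_ensemble(frames))
  expect_equal(rd2$mean, 20)
})

test_that("block-average error matches AR(1) analytic standard error within 20%", {
  ## frames whose Rg follows an AR(1) series: encode scalar series as the
  ## separation of a 2-particle frame
  set.seed(77)
  n <- 1e4
  phi <- 0.9; sd_e <- 0.3
  z <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = sd_e))
  rgs <- 20 + z
  frames <- lapply(rgs, function(r) rbind(c(-r, 0, 0), c(r, 0, 0)))
  rd <- rg_distribution(replica_ensemble(frames))
  ## analytic SE of the mean of an AR(1) process
  se_an <- sqrt(sd_e^2 / (1 - phi^2) * (1 + phi) / (1 - phi) / n)
  expect_equal(rd$se, se_an, tolerance = 0.2)
})

test_that("free-energy surface: uniform flat, Gaussian quadratic, empty-bin sentinel", {
  set.seed(30)
  ## uniform samples on both CVs: flat F up to binomial noise
  n <- 20000
  frames <- lapply(seq_len(n), function(k) {
    d <- runif(1, 10, 30); rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))
  })
  ens <- replica_ensemble(frames)
  cvd <- collective_variable("distance", list(1, 2))
  cvr <- collective_variable("rg", 1:2)
  fes <- free_energy_surface(ens, cvd, cvr, bins = c(8, 8))
  vis <- fes$F[is.finite(fes$F)]
  ## D and Rg = D/2 are perfectly correlated: diagonal visited, rest Inf
  expect_true(any(!is.finite(fes$F)))
  expect_equal(min(vis), 0)
  expect_lt(max(vis), 1.0)   # flat along the visited diagonal

  ## Gaussian CV samples give a quadratic F: F(2 sd) - F(0) ~ 2 kT
  d0 <- 20; sdv <- 1.5
  frames2 <- lapply(rnorm(40000, d0, sdv), function(d)
    rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)))
  fes2 <- free_energy_surface(replica_ensemble(frames2), cvd, cvr,
                              bins = c(41, 1))
  prof <- fes2$F[, 1]
  s <- fes2$s1
  sel <- is.finite(prof) & abs(s - d0) < 2.5 * sdv
  quad <- (s[sel] - d0)^2 / (2 * sdv^2)
  expect_lt(max(abs(prof[sel] - quad - mean(prof[sel] - quad))), 0.35)
})

test_that("gromos clustering: repeated frame, constructed 60:40 fixture, cutoffs", {
  set.seed(55)
  base <- matrix(rnorm(36, sd = 3), 12, 3)
  ens1 <- replica_ensemble(replicate(5, base, simplify = FALSE))
  cl1 <- cluster_compact(ens1, rg_cutoff = 1e6, rmsd_cutoff = 6)
  expect_equal(nrow(cl1$clusters), 1)
  expect_equal(cl1$clusters$population, 1)
  expect_equal(cl1$compact_fraction, 1)

  ## two conformers ~12 A apart in RMSD, 60:40 weights, cutoff 6 A
  confA <- base
  confB <- base + matrix(rnorm(36, sd = 12), 12, 3)
  ## verify the constructed separation actually exceeds the cutoff
  expect_gt(metasaxs:::kabsch_rmsd(confA, confB), 8)
  frames <- c(replicate(6, confA, simplify = FALSE),
              replicate(4, confB, simplify = FALSE))
  ens2 <- replica_ensemble(frames)
  cl2 <- cluster_compact(ens2, rg_cutoff = 1e6, rmsd_cutoff = 6)
  expect_equal(nrow(cl2$clusters), 2)
  expect_equal(cl2$clusters$population, c(0.6, 0.4))
  expect_equal(sum(cl2$clusters$population), cl2$compact_fraction)

  ## infinite cutoff: one cluster holding everything
  cl3 <- cluster_compact(ens2, rg_cutoff = 1e6, rmsd_cutoff = 1e9)
  expect_equal(nrow(cl3$clusters), 1)

  ## rg filter: population reported over the FULL ensemble
  small <- matrix(rnorm(36, sd = 1), 12, 3)   # compact
  mix <- c(replicate(3, small, simplify = FALSE),
           replicate(7, 10 * base, simplify = FALSE))
  cl4 <- cluster_compact(replica_ensemble(mix),
                         rg_cutoff = frame_rg(small) + 1, rmsd_cutoff = 6)
  expect_equal(cl4$compact_fraction, 0.3)
  expect_equal(sum(cl4$clusters$population), 0.3)
})

test_that("best-fit RMSD agrees with an independent superposition (bio3d)", {
  set.seed(66)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- sweep((A + matrix(rnorm(30, sd = 0.5), 10, 3)) %*% t(R), 2, c(3, 1, -2), "+")
  ours <- metasaxs:::kabsch_rmsd(A, B)
  ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("interdomain maps: zero when apart, Coulomb constant, transpose symmetry", {
  ## two 2-particle residues per domain, far apart: all zero
  frA <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 2, 0))
  frFar <- rbind(frA, frA + matrix(rep(c(100, 0, 0), each = 4), 4, 3))
  ensF <- replica_ensemble(list(frFar))
  domA <- list(1:2, 3:4); domB <- list(5:6, 7:8)
  mpF <- interdomain_maps(ensF, domA, domB, charges = rep(1, 8))
  expect_equal(mpF$contact, matrix(0, 2, 2))
  expect_equal(mpF$coulomb, matrix(0, 2, 2))

  ## two unit opposite charges at 7 A: E = -ke/7 ~ -198.5 kJ/mol
  fr2 <- rbind(c(0, 0, 0), c(7, 0, 0))
  ens2 <- replica_ensemble(list(fr2))
  mp2 <- interdomain_maps(ens2, list(1), list(2), charges = c(1, -1),
                          coulomb_cutoff = 9)
  expect_equal(mp2$coulomb[1, 1], -1389.35457644382 / 7, tolerance = 1e-10)
  expect_equal(round(mp2$coulomb[1, 1], 1), -198.5)

  ## swapping domains transposes the maps
  set.seed(9)
  fr3 <- matrix(rnorm(24, sd = 4), 8, 3)
  ens3 <- replica_ensemble(list(fr3))
  q3 <- runif(8, -1, 1)
  m1 <- interdomain_maps(ens3, domA, domB, charges = q3)
  m2 <- interdomain_maps(ens3, domB, domA, charges = q3)
  expect_equal(m1$contact, t(m2$contact))
  expect_equal(m1$coulomb, t(m2$coulomb))

  expect_error(interdomain_maps(ens3, list(1:2), list(2:3)), "overlap")
})

test_that("Guinier Rg of a rigid toy's Debye curve matches its geometric Rg", {
  b <- random_beads(40, seed = 31, sd = 10)
  rg_geo <- frame_rg(b$centers)
  q <- seq(0.2 / rg_geo, 1.25 / rg_geo, length.out = 30)
  I <- debye_intensity(b, toy_ff(1), q, warn = FALSE)
  fit <- guinier_rg(as_saxs_curve(I), qRg_max = 1.3)
  expect_equal(fit$Rg, rg_geo, tolerance = 0.02)
})
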