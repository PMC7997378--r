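#' Construct a toy particle system
#'
#' Desk-scale stand-in for the molecular force field: point particles with
#' a harmonic bond network and, optionally, a double-well potential on the
#' distance between the centers of mass of two particle groups (the
#' compact/extended interdomain coordinate of a dumbbell).
#'
#' @param positions N x 3 matrix (Angstrom).
#' @param masses Length-N masses (Da).
#' @param bonds Data frame with columns `i`, `j`, `k` (kJ/mol/A^2), `r0`
#'   (A), or `NULL`.
#' @param double_well `NULL` or list with `groupA`, `groupB` (index
#'   vectors), `center` (A), `half_sep` (A) and `height` (kJ/mol): the
#'   potential h ((D - center)^2 / half_sep^2 - 1)^2 on the group-COM
#'   distance D, with minima at center +- half_sep and barrier h.
#' @param velocities Optional N x 3 start velocities (A/ps); default zero.
#' @return Object of class `toy_system`.
#' @export
toy_system <- function(positions, masses, bonds = NULL, double_well = NULL,
                       velocities = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(masses) == nrow(positions))
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  sys <- structure(list(x = unname(positions), v = unname(velocities),
                        masses = as.numeric(masses), bonds = bonds,
                        double_well = double_well),
                   class = "toy_system")
  pf <- prior_energy_forces(sys)
  if (!is.finite(pf$energy) || !all(is.finite(pf$forces))) {
    stop("prior potential or gradient not finite at the start configuration")
  }
  sys
}

#' Prior potential energy and forces of a toy system
#'
#' @param sys `toy_system` (or a list with the same fields; `x` may be a
#'   stacked multi-replica coordinate matrix if `n_replicas` is given).
#' @param x Optional coordinate matrix overriding `sys$x`.
#' @param n_replicas Treat `x` as `n_replicas` stacked copies. Default 1.
#' @param cache Optional precomputed topology from [prior_cache()] (built
#'   on the fly when absent; supply it in tight loops).
#' @return List with `energy` (total, kJ/mol) and `forces` (same shape as
#'   the coordinates, kJ/mol/A).
#' @export
prior_energy_forces <- function(sys, x = NULL, n_replicas = 1, cache = NULL) {
  if (is.null(x)) x <- sys$x
  if (is.null(cache)) cache <- prior_cache(sys, n_replicas)
  Fm <- matrix(0, nrow(x), 3)
  E <- 0
  if (!is.null(cache$ii)) {
    dx <- x[cache$ii, , drop = FALSE] - x[cache$jj, , drop = FALSE]
    r <- sqrt(.rowSums(dx^2, length(cache$ii), 3))
    E <- E + sum(0.5 * cache$kk * (r - cache$r0)^2)
    fij <- (-(cache$kk * (r - cache$r0) / pmax(r, 1e-12))) * dx
    Fm <- Fm + cache$inc %*% fij
  }
  dw <- sys$double_well
  if (!is.null(dw)) {
    dvec <- cache$Wab %*% x                       # per-replica comA - comB
    D <- sqrt(.rowSums(dvec^2, n_replicas, 3))
    u <- (D - dw$center)^2 / dw$half_sep^2 - 1
    E <- E + sum(dw$height * u^2)
    dUdD <- 4 * dw$height * u * (D - dw$center) / dw$half_sep^2
    fA <- (-dUdD / pmax(D, 1e-12)) * dvec         # force on A's COM, R x 3
    Fm <- Fm + crossprod(cache$Wab, fA)
  }
  list(energy = E, forces = Fm)
}

#' Precompute toy-system topology for repeated force evaluations
#'
#' Builds the replicated bond index vectors, a (signed) bond incidence
#' matrix and the COM-difference aggregation matrix so the per-step force
#' evaluation is pure dense linear algebra.
#'
#' @param sys `toy_system`.
#' @param n_replicas Number of stacked replicas.
#' @return List used by [prior_energy_forces()].
#' @export
prior_cache <- function(sys, n_replicas = 1) {
  N <- length(sys$masses)
  out <- list()
  if (!is.null(sys$bonds) && nrow(sys$bonds) > 0) {
    b <- sys$bonds
    off <- rep((seq_len(n_replicas) - 1) * N, each = nrow(b))
    out$ii <- rep(b$i, n_replicas) + off
    out$jj <- rep(b$j, n_replicas) + off
    out$kk <- rep(b$k, n_replicas); out$r0 <- rep(b$r0, n_replicas)
    nb <- length(out$ii)
    inc <- matrix(0, N * n_replicas, nb)
    inc[cbind(out$ii, seq_len(nb))] <- 1
    inc[cbind(out$jj, seq_len(nb))] <- inc[cbind(out$jj, seq_len(nb))] - 1
    out$inc <- inc
  }
  dw <- sys$double_well
  if (!is.null(dw)) {
    Wab <- matrix(0, n_replicas, N * n_replicas)
    mA <- sys$masses[dw$groupA]; mB <- sys$masses[dw$groupB]
    for (r_ in seq_len(n_replicas)) {
      off <- (r_ - 1) * N
      Wab[r_, dw$groupA + off] <- mA / sum(mA)
      Wab[r_, dw$groupB + off] <- -mB / sum(mB)
    }
    out$Wab <- Wab
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a collective variable
#'
#' Supported kinds: `"rg"` (mass-weighted radius of gyration of a
#' selection), `"distance"` (between mass-weighted centroids of two
#' selections), `"contacts"` (switched contact count between two
#' selections, s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)), and `"dihedral"`
#' (signed dihedral angle, radians, of four selection centroids).
#'
#' @param kind One of `"rg"`, `"distance"`, `"contacts"`, `"dihedral"`.
#' @param sel Index vector (for `rg`), or list of 2 (distance/contacts) or
#'   4 (dihedral) index vectors.
#' @param r0,n,m Switching parameters for `contacts` (defaults 5 A, 6, 12).
#' @return Object of class `collective_variable`.
#' @export
collective_variable <- function(kind = c("rg", "distance", "contacts", "dihedral"),
                                sel, r0 = 5, n = 6, m = 12) {
  kind <- match.arg(kind)
  if (kind == "rg") sel <- list(as.integer(sel))
  nsel <- switch(kind, rg = 1, distance = 2, contacts = 2, dihedral = 4)
  if (length(sel) != nsel) stop(kind, " needs ", nsel, " selection(s)")
  if (any(vapply(sel, length, integer(1)) == 0)) stop("empty selection")
  structure(list(kind = kind, sel = lapply(sel, as.integer),
                 r0 = r0, n = n, m = m),
            class = "collective_variable")
}

#' Evaluate a collective variable and its gradient
#'
#' @param x N x 3 coordinate matrix.
#' @param masses Length-N masses.
#' @param cv `collective_variable`.
#' @return List with `value` (scalar) and `grad` (N x 3).
#' @export
cv_value <- function(x, masses, cv) {
  G <- matrix(0, nrow(x), 3)
  centroid <- function(idx) colSums(x[idx, , drop = FALSE] * masses[idx]) / sum(masses[idx])
  if (cv$kind == "rg") {
    idx <- cv$sel[[1]]
    m <- masses[idx]; M <- sum(m)
    com <- centroid(idx)
    dxm <- sweep(x[idx, , drop = FALSE], 2, com)
    rg2 <- sum(m * rowSums(dxm^2)) / M
    rg <- sqrt(rg2)
    if (rg > 1e-12) G[idx, ] <- (m / (M * rg)) * dxm
    return(list(value = rg, grad = G))
  }
  if (cv$kind == "distance") {
    a <- cv$sel[[1]]; b <- cv$sel[[2]]
    dvec <- centroid(a) - centroid(b)
    D <- sqrt(sum(dvec^2))
    dir <- dvec / max(D, 1e-12)
    G[a, ] <- outer(masses[a] / sum(masses[a]), dir)
    G[b, ] <- -outer(masses[b] / sum(masses[b]), dir)
    return(list(value = D, grad = G))
  }
  if (cv$kind == "contacts") {
    a <- cv$sel[[1]]; b <- cv$sel[[2]]
    xa <- x[a, , drop = FALSE]; xb <- x[b, , drop = FALSE]
    total <- 0
    for (ia in seq_along(a)) {
      dx <- sweep(xb, 2, xa[ia, ], "-")
      r <- sqrt(rowSums(dx^2))
      sw <- .switch_fun(r, cv$r0, cv$n, cv$m)
      total <- total + sum(sw$s)
      gi <- (sw$ds / pmax(r, 1e-12)) * dx     # d s / d (r_b - r_a)
      G[b, ] <- G[b, ] + gi
      G[a[ia], ] <- G[a[ia], ] - colSums(gi)
    }
    return(list(value = total, grad = G))
  }
  ## dihedral of 4 centroids
  p <- t(vapply(cv$sel, centroid, numeric(3)))
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  phi <- atan2(sum(.cross(n1, n2) * b2) / nb2, sum(n1 * n2))
  Fg <- -nb2 / sum(n1^2) * n1
  Hg <- nb2 / sum(n2^2) * n2
  tt <- sum(b1 * b2) / sum(b2^2); uu <- sum(b3 * b2) / sum(b2^2)
  gp <- rbind(Fg,
              -(1 + tt) * Fg + uu * Hg,
              tt * Fg - (1 + uu) * Hg,
              Hg)
  for (k in 1:4) {
    idx <- cv$sel[[k]]
    G[idx, ] <- G[idx, ] + outer(masses[idx] / sum(masses[idx]), gp[k, ])
  }
  list(value = phi, grad = G)
}

.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

## rational switching function and derivative, safe at r = r0
.switch_fun <- function(r, r0, n, m) {
  x <- r / r0
  num <- 1 - x^n; den <- 1 - x^m
  s <- ifelse(abs(den) < 1e-10, n / m, num / den)
  ds <- ifelse(abs(den) < 1e-10,
               ## derivative at the removable singularity x -> 1
               -n * (m - n) / (2 * m) / r0,
               (-n * x^(n - 1) * den + num * m * x^(m - 1)) / den^2 / r0)
  list(s = s, ds = ds)
}

#' Create a parallel-bias metadynamics bias
#'
#' One 1-D well-tempered bias per collective variable, deposited in
#' parallel. Gaussian widths are fixed per CV (no dynamic adaptation);
#' potentials and their derivatives are accumulated on regular grids; the
#' full deposit history is kept so several walkers can share one pool.
#'
#' @param cvs List of `collective_variable`s.
#' @param grids List of `c(min, max, n_bins)` per CV.
#' @param widths Gaussian sigma per CV (CV units).
#' @param height Initial Gaussian height h0 in kJ/mol. Default 1.0.
#' @param bias_factor Well-tempered bias factor gamma. Default 30. `Inf`
#'   gives standard (non-tempered) metadynamics.
#' @param temperature K.
#' @return Object of class `pbmetad_bias`.
#' @export
pbmetad_bias <- function(cvs, grids, widths, height = 1.0, bias_factor = 30,
                         temperature = 300) {
  stopifnot(length(cvs) == length(grids), length(cvs) == length(widths))
  pots <- lapply(grids, function(g) {
    s <- seq(g[1], g[2], length.out = g[3])
    list(s = s, V = numeric(g[3]), dV = numeric(g[3]))
  })
  structure(list(cvs = cvs, pots = pots, widths = widths, h0 = height,
                 gamma = bias_factor, kT = KB * temperature,
                 deposits = lapply(cvs, function(.) data.frame(center = numeric(),
                                                               height = numeric()))),
            class = "pbmetad_bias")
}

## per-CV bias potentials (and derivatives) at CV values s
.bias_eval <- function(bias, s_values, deriv = FALSE) {
  vapply(seq_along(bias$pots), function(c_) {
    p <- bias$pots[[c_]]
    y <- if (deriv) p$dV else p$V
    stats::approx(p$s, y, xout = s_values[c_], rule = 2)$y
  }, numeric(1))
}

#' Total parallel-bias potential at a CV point
#'
#' V_PB(s) = -kT log sum_c exp(-V_c(s_c)/kT); the quantity whose
#' exponential reweights replica contributions to the forward-model
#' average.
#'
#' @param bias `pbmetad_bias`.
#' @param s_values Numeric vector of current CV values.
#' @return Scalar V_PB in kJ/mol (<= 0 for empty bias... equals
#'   -kT log(n_cv) at zero bias; the additive constant is irrelevant).
#' @export
pbmetad_vpb <- function(bias, s_values) {
  Vc <- .bias_eval(bias, s_values)
  mx <- max(-Vc / bias$kT)
  -bias$kT * (log(sum(exp(-Vc / bias$kT - mx))) + mx)
}

## parallel-bias weights P_c at a CV point
.pb_weights <- function(bias, s_values) {
  Vc <- .bias_eval(bias, s_values)
  w <- exp(-(Vc - min(Vc)) / bias$kT)
  w / sum(w)
}

#' Deposit a PBMetaD Gaussian
#'
#' Adds one Gaussian per CV at the walker's current CV values with the
#' well-tempered parallel-bias height
#' h_c = h0 exp(-V_c(s_c) / ((gamma - 1) kT)) P_c, where P_c is the
#' parallel-bias weight exp(-V_c/kT) / sum_c' exp(-V_c'/kT). All walkers
#' deposit into, and read from, the same pool.
#'
#' @param bias `pbmetad_bias`.
#' @param s_values CV values of the depositing walker.
#' @return Updated `pbmetad_bias`.
#' @export
pbmetad_update <- function(bias, s_values) {
  Vc <- .bias_eval(bias, s_values)
  P <- .pb_weights(bias, s_values)
  wt <- if (is.finite(bias$gamma)) exp(-Vc / ((bias$gamma - 1) * bias$kT)) else 1
  h <- bias$h0 * wt * P
  for (c_ in seq_along(bias$pots)) {
    p <- bias$pots[[c_]]
    w <- bias$widths[c_]
    g <- exp(-(p$s - s_values[c_])^2 / (2 * w^2))
    p$V <- p$V + h[c_] * g
    p$dV <- p$dV - h[c_] * (p$s - s_values[c_]) / w^2 * g
    bias$pots[[c_]] <- p
    bias$deposits[[c_]] <- rbind(bias$deposits[[c_]],
                                 data.frame(center = s_values[c_], height = h[c_]))
  }
  bias
}

#' Bias forces on particle coordinates
#'
#' F = -sum_c P_c dV_c/ds_c * ds_c/dr, the gradient of V_PB through each
#' CV.
#'
#' @param bias `pbmetad_bias`.
#' @param x N x 3 coordinates.
#' @param masses Particle masses.
#' @return List with `forces` (N x 3), `vpb` (scalar kJ/mol) and
#'   `s_values`.
#' @export
pbmetad_forces <- function(bias, x, masses) {
  cvres <- lapply(bias$cvs, function(cv) cv_value(x, masses, cv))
  s_values <- vapply(cvres, `[[`, numeric(1), "value")
  P <- .pb_weights(bias, s_values)
  dV <- .bias_eval(bias, s_values, deriv = TRUE)
  Fm <- matrix(0, nrow(x), 3)
  for (c_ in seq_along(bias$cvs)) {
    Fm <- Fm - P[c_] * dV[c_] * cvres[[c_]]$grad
  }
  list(forces = Fm, vpb = pbmetad_vpb(bias, s_values), s_values = s_values)
}

#' Estimate a free-energy profile from a 1-CV well-tempered bias
#'
#' F(s) = -(gamma / (gamma - 1)) V(s), shifted to min 0. When the bias
#' carries a time-averaged potential (accumulated by [run_restrained()]
#' over the converged tail of a run), that estimator is used by default:
#' averaging over deposit times removes the Gaussian-ripple
#' non-convergence of the instantaneous well-tempered bias.
#'
#' @param bias `pbmetad_bias` with a single CV.
#' @param cv_index Which CV's bias to convert. Default 1.
#' @param use_average Use the time-averaged potential when available.
#'   Default `TRUE`.
#' @return Data frame with `s` and `F` (kJ/mol).
#' @export
pbmetad_fes <- function(bias, cv_index = 1, use_average = TRUE) {
  p <- bias$pots[[cv_index]]
  V <- p$V
  if (use_average && !is.null(bias$V_avg) && bias$V_avg$count > 0) {
    V <- bias$V_avg$V[[cv_index]] / bias$V_avg$count
  }
  fac <- if (is.finite(bias$gamma)) bias$gamma / (bias$gamma - 1) else 1
  F <- -fac * V
  data.frame(s = p$s, F = F - min(F))
}

## one BAOA-discretized Langevin step on stacked coordinates; forces in
## kJ/mol/A, dt in ps, friction in 1/ps. Modifies x, v given as matrices.
.langevin_core <- function(x, v, forces, masses, dt, friction, temperature) {
  a <- forces * ENERGY_TO_DYN / masses          # A/ps^2
  v <- v + dt * a
  x <- x + 0.5 * dt * v
  if (friction > 0) {
    c1 <- exp(-friction * dt)
    kTd <- KB * temperature * ENERGY_TO_DYN
    c2 <- sqrt((1 - c1^2) * kTd / masses)
    v <- c1 * v + c2 * matrix(stats::rnorm(length(v)), nrow(v), 3)
  }
  x <- x + 0.5 * dt * v
  list(x = x, v = v)
}

#' Advance a toy system by one Langevin step
#'
#' Kick-drift-thermostat-drift discretization (BAOA scheme): with zero
#' friction it reduces to the symplectic leapfrog integrator; with
#' friction > 0 the Ornstein-Uhlenbeck half-step uses the exact velocity
#' autocorrelation. Deterministic given the R RNG state.
#'
#' @param sys `toy_system`.
#' @param forces N x 3 total forces (kJ/mol/A) at the current positions.
#' @param dt Time step (ps).
#' @param friction Langevin friction (1/ps); 0 disables the thermostat.
#' @param temperature K.
#' @return Updated `toy_system`.
#' @export
langevin_step <- function(sys, forces, dt, friction, temperature) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(is.finite(forces))) {
    stop("non-finite force on particle ",
         which(!is.finite(rowSums(forces)))[1])
  }
  st <- .langevin_core(sys$x, sys$v, forces, sys$masses, dt, friction, temperature)
  sys$x <- st$x; sys$v <- st$v
  sys
}

#' Run a (possibly SAXS-restrained) multi-replica toy simulation
#'
#' Evolves `n_replicas` copies of a toy system with Langevin dynamics.
#' Every `restraint_stride` steps the coarse-grained Debye intensities of
#' all replicas are recomputed at the restraint q-values, sigma_sem is
#' re-estimated over a sliding window, the metainference nuisance
#' parameters receive a Monte-Carlo sweep, and the restraint forces are
#' refreshed; between updates the forces are held constant (multiple
#' time-step protocol, justified by the slow temporal fluctuation of SAXS
#' observables). With `restraints = NULL` the run is an unrestrained
#' control that is step-for-step identical to the restrained code path
#' minus the restraint. Optionally a PBMetaD bias is applied and its V_PB
#' feeds the replica-averaging weights.
#'
#' @param sys Template `toy_system` (all replicas start from its state).
#' @param n_replicas Number of replicas.
#' @param n_steps Steps per replica.
#' @param dt,friction,temperature Integrator parameters (ps, 1/ps, K).
#' @param restraints `restraint_set` (targets at its `q`), or `NULL`.
#' @param table `ff_table` for the forward model (particles are treated as
#'   beads with `ff_id`s from `ff_id`).
#' @param ff_id Per-particle form-factor identifiers (default `"TOY"`).
#' @param restraint_stride Steps between restraint evaluations. Default 10.
#' @param meta_options List of extra arguments for [meta_state()].
#' @param sem_window Restraint evaluations retained for the sigma_sem
#'   estimate. Default 10.
#' @param bias Optional `pbmetad_bias`.
#' @param bias_stride Steps between bias deposits. Default 200.
#' @param record_stride Steps between recorded frames. Default 50.
#' @param burn_in Fraction of steps discarded before recording. Default 0.2.
#' @param seed Optional integer seed (sets the R RNG).
#' @return Object of class `replica_ensemble`: list with `frames` (array
#'   n_frames x N x 3), `replica`, `time`, `vpb`, `weights`, `masses`, and
#'   `traces` (per-evaluation lambda, mean sigma_bias, sigma_sem, replica-
#'   averaged forward values and targets), plus the final `meta_state` and
#'   `bias`.
#' @export
run_restrained <- function(sys, n_replicas, n_steps, dt = 0.02, friction = 0.5,
                           temperature = 300, restraints = NULL, table = NULL,
                           ff_id = NULL, restraint_stride = 10,
                           meta_options = list(), sem_window = 10,
                           bias = NULL, bias_stride = 200,
                           record_stride = 50, burn_in = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(sys$masses)
  R <- n_replicas
  x <- sys$x[rep(seq_len(N), R), , drop = FALSE]
  v <- sys$v[rep(seq_len(N), R), , drop = FALSE]
  masses <- rep(sys$masses, R)
  if (is.null(ff_id)) ff_id <- rep("TOY", N)
  if (is.null(table) && !is.null(restraints)) {
    table <- ff_table(NULL, stats::setNames(1, "TOY"))
  }
  restrained <- !is.null(restraints)
  state <- NULL
  if (restrained) {
    state <- do.call(meta_state, c(list(n_replicas = R,
                                        targets = restraints$intensity,
                                        temperature = temperature),
                                   meta_options))
  }
  qpts <- if (restrained) restraints$q else NULL
  Fr <- matrix(0, R * N, 3)                       # held restraint forces
  vpb_now <- rep(0, R)
  sem_hist <- list()
  frames <- list(); fr_rep <- integer(); fr_time <- numeric(); fr_vpb <- numeric()
  tr_step <- integer(); tr_lambda <- numeric(); tr_sigma <- numeric()
  tr_sem <- numeric(); tr_fbar <- list()
  rep_rows <- function(r_) ((r_ - 1) * N + 1):(r_ * N)
  n_burn <- floor(burn_in * n_steps)
  pcache <- prior_cache(sys, R)
  for (step in seq_len(n_steps)) {
    pf <- prior_energy_forces(sys, x = x, n_replicas = R, cache = pcache)
    Ftot <- pf$forces + Fr
    if (!is.null(bias)) {
      for (r_ in seq_len(R)) {
        rr <- rep_rows(r_)
        bf <- pbmetad_forces(bias, x[rr, , drop = FALSE], sys$masses)
        Ftot[rr, ] <- Ftot[rr, ] + bf$forces
        vpb_now[r_] <- bf$vpb
        if (step %% bias_stride == 0) bias <- pbmetad_update(bias, bf$s_values)
      }
      ## time-averaged bias estimator over the tail of the run
      if (step %% bias_stride == 0 && step > n_steps / 2) {
        if (is.null(bias$V_avg)) {
          bias$V_avg <- list(V = lapply(bias$pots, function(p) 0 * p$V),
                             count = 0)
        }
        bias$V_avg$V <- Map(`+`, bias$V_avg$V, lapply(bias$pots, `[[`, "V"))
        bias$V_avg$count <- bias$V_avg$count + 1
      }
    }
    st <- .langevin_core(x, v, Ftot, masses, dt, friction, temperature)
    x <- st$x; v <- st$v
    if (restrained && step %% restraint_stride == 0) {
      fvals <- matrix(0, R, length(qpts))
      grads <- vector("list", R)
      for (r_ in seq_len(R)) {
        beads <- bead_structure(x[rep_rows(r_), , drop = FALSE], ff_id)
        ir <- debye_intensity(beads, table, qpts, gradient = TRUE, warn = FALSE)
        fvals[r_, ] <- ir$intensity
        grads[[r_]] <- ir$gradient
      }
      sem_hist[[length(sem_hist) + 1]] <- fvals
      if (length(sem_hist) > sem_window) sem_hist <- sem_hist[-1]
      win <- Reduce(`+`, sem_hist) / length(sem_hist)
      state$sigma_sem <- if (R > 1) apply(win, 2, stats::sd) / sqrt(R) else rep(0, ncol(win))
      avg <- replica_average(fvals, vpb_now, temperature)
      state <- mc_update(state, avg)
      for (r_ in seq_len(R)) {
        Fr[rep_rows(r_), ] <- metainference_forces(avg, state, grads[[r_]], r_)
      }
      tr_step <- c(tr_step, step); tr_lambda <- c(tr_lambda, state$lambda)
      tr_sigma <- c(tr_sigma, mean(state$sigma_bias))
      tr_sem <- c(tr_sem, mean(state$sigma_sem))
      tr_fbar[[length(tr_fbar) + 1]] <- avg$mean
    }
    if (step > n_burn && step %% record_stride == 0) {
      for (r_ in seq_len(R)) {
        frames[[length(frames) + 1]] <- x[rep_rows(r_), , drop = FALSE]
        fr_rep <- c(fr_rep, r_); fr_time <- c(fr_time, step * dt)
        fr_vpb <- c(fr_vpb, vpb_now[r_])
      }
    }
  }
  replica_ensemble(frames, replica = fr_rep, time = fr_time, vpb = fr_vpb,
                   masses = sys$masses, temperature = temperature,
                   traces = list(step = tr_step, lambda = tr_lambda,
                                 sigma_bias = tr_sigma, sigma_sem = tr_sem,
                                 fbar = do.call(rbind, tr_fbar),
                                 targets = restraints$intensity),
                   meta_state = state, bias = bias)
}

#' Construct a replica ensemble
#'
#' Container for sampled frames and their statistical weights. Weights are
#' derived from the recorded bias potentials by the replica-averaging rule
#' w = exp(V_PB / kB T), normalized.
#'
#' @param frames List of N x 3 matrices, or an n_frames x N x 3 array.
#' @param replica,time,vpb Per-frame bookkeeping (defaults: replica 1,
#'   time index, vpb 0).
#' @param masses Per-particle masses.
#' @param temperature K (for the weight rule). Default 300.
#' @param weights Optional explicit per-frame weights (overrides vpb rule).
#' @param traces,meta_state,bias Optional run diagnostics.
#' @param labels Optional per-frame state labels (fixture ground truth).
#' @return Object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(frames, replica = NULL, time = NULL, vpb = NULL,
                             masses = NULL, temperature = 300, weights = NULL,
                             traces = NULL, meta_state = NULL, bias = NULL,
                             labels = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[1]), function(k) frames[k, , , drop = TRUE])
  }
  nf <- length(frames)
  if (nf == 0) stop("no frames")
  if (is.null(replica)) replica <- rep(1L, nf)
  if (is.null(time)) time <- seq_len(nf)
  if (is.null(vpb)) vpb <- rep(0, nf)
  if (is.null(masses)) masses <- rep(1, nrow(frames[[1]]))
  if (is.null(weights)) {
    u <- vpb / (KB * temperature)
    weights <- exp(u - max(u))
    weights <- weights / sum(weights)
  } else {
    if (any(weights <= 0) || !all(is.finite(weights))) stop("invalid weights")
    weights <- weights / sum(weights)
  }
  structure(list(frames = frames, replica = replica, time = time, vpb = vpb,
                 weights = weights, masses = masses, temperature = temperature,
                 traces = traces, meta_state = meta_state, bias = bias,
                 labels = labels),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat("Replica ensemble:", length(x$frames), "frames,",
      length(unique(x$replica)), "replica(s),",
      nrow(x$frames[[1]]), "particles\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens `replica_ensemble`.
#' @return Integer.
#' @export
n_frames <- function(ens) length(ens$frames)
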