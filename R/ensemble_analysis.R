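#' Chi-square agreement with optimal intensity scale
#'
#' Reduced chi-square between a calculated and an experimental SAXS curve,
#' chi2 = (1/N_q) sum_q (lambda I_calc - I_expt)^2 / sigma_expt^2, with the
#' scale lambda minimized in closed form (weighted least squares) and then
#' clipped to `lambda_bounds`. Calculated intensities are interpolated onto
#' the experimental grid inside `q_range`. The reduction is by N_q only (no
#' parameter penalty). Since I(0) is not measurable, this chi-square-
#' minimizing lambda is the standard way to put model and data on one
#' scale; the conventional validation range is 0.02-0.20 1/A.
#'
#' @param calc Calculated `saxs_curve` (or `intensity_result`).
#' @param expt Experimental `saxs_curve`; if it has no errors, unit errors
#'   are used with a warning.
#' @param q_range Length-2 q window. Default `c(0.02, 0.20)`.
#' @param lambda_bounds Clip range for lambda, default `c(-Inf, Inf)`.
#' @return List with `chi2`, `lambda`, `n_q`.
#' @export
chi2_with_scale <- function(calc, expt, q_range = c(0.02, 0.20),
                            lambda_bounds = c(-Inf, Inf)) {
  if (inherits(calc, "intensity_result")) calc <- as_saxs_curve(calc)
  sel <- expt$q >= q_range[1] & expt$q <= q_range[2] &
    expt$q >= min(calc$q) & expt$q <= max(calc$q)
  if (!any(sel)) stop("no overlapping q-points in the requested range")
  qe <- expt$q[sel]; Ie <- expt$intensity[sel]
  se <- expt$error[sel]
  if (all(is.na(se))) {
    warning("experimental curve has no errors; using unit errors")
    se <- rep(1, length(qe))
  }
  Ic <- stats::approx(calc$q, calc$intensity, xout = qe)$y
  w <- 1 / se^2
  lam <- sum(w * Ic * Ie) / sum(w * Ic^2)
  lam <- min(max(lam, lambda_bounds[1]), lambda_bounds[2])
  chi2 <- mean((lam * Ic - Ie)^2 * w)
  list(chi2 = chi2, lambda = lam, n_q = length(qe))
}

#' Correlation trace between back-calculated and target intensities
#'
#' Per restraint evaluation, the Pearson correlation between the
#' replica-averaged calculated intensities and the experimental targets,
#' together with the sum of squared deviations and the slope/intercept of
#' the linear fit — the on-the-fly restraint-effectiveness monitors.
#'
#' @param fbar Matrix, evaluations x data points, of replica-averaged
#'   calculated intensities (the `traces$fbar` of a run), or a numeric
#'   vector for a single evaluation.
#' @param targets Target intensities (length = data points, >= 2).
#' @return Data frame with `eval`, `r`, `ss_dev`, `slope`, `intercept`
#'   (`r` is NA where the calculated values have zero variance).
#' @export
correlation_trace <- function(fbar, targets) {
  if (is.vector(fbar)) fbar <- matrix(fbar, nrow = 1)
  if (length(targets) < 2) stop("need at least 2 restraint points")
  if (ncol(fbar) != length(targets)) stop("dimension mismatch")
  out <- lapply(seq_len(nrow(fbar)), function(k) {
    y <- fbar[k, ]
    ssd <- sum((y - targets)^2)
    if (stats::sd(y) == 0 || stats::sd(targets) == 0) {
      return(data.frame(eval = k, r = NA_real_, ss_dev = ssd,
                        slope = NA_real_, intercept = NA_real_))
    }
    fit <- stats::lm.fit(cbind(1, targets), y)
    data.frame(eval = k, r = stats::cor(y, targets), ss_dev = ssd,
               slope = fit$coefficients[2], intercept = fit$coefficients[1])
  })
  do.call(rbind, out)
}

#' Kratky transform of a SAXS curve
#'
#' Returns (q, q^2 I(q)); the plateau/peak shape distinguishes compact
#' from extended scatterers. Optionally normalized by I(0) (the first
#' intensity if q starts at 0, else the Guinier-extrapolated I0).
#'
#' @param curve `saxs_curve`.
#' @param normalize Divide by I(0)? Default `FALSE`.
#' @return Data frame with `q` and `kratky`.
#' @export
kratky <- function(curve, normalize = FALSE) {
  stopifnot(inherits(curve, "saxs_curve"))
  y <- curve$q^2 * curve$intensity
  if (normalize) {
    i0 <- if (curve$q[1] == 0) curve$intensity[1] else
      tryCatch(guinier_rg(curve)$I0, error = function(e) curve$intensity[1])
    y <- y / i0
  }
  data.frame(q = curve$q, kratky = y)
}

#' Guinier fit of the radius of gyration
#'
#' Iterative weighted linear fit of ln I versus q^2 on the low-q points
#' with q Rg <= `qRg_max` (default 1.3): starting from all points below
#' `q_start`, Rg = sqrt(-3 slope) is estimated, the included set updated,
#' and the fit repeated until the set is stable. Errors propagate as
#' sigma_lnI = sigma_I / I when available.
#'
#' @param curve `saxs_curve` (or `intensity_result`).
#' @param qRg_max Guinier validity bound. Default 1.3.
#' @param q_start Initial upper q for the first fit; default the 40%
#'   quantile of the grid.
#' @return List with `Rg` (Angstrom), `I0`, `n_points`, `qRg`,
#'   `iterations`.
#' @export
guinier_rg <- function(curve, qRg_max = 1.3, q_start = NULL) {
  if (inherits(curve, "intensity_result")) curve <- as_saxs_curve(curve)
  ok <- curve$intensity > 0
  q <- curve$q[ok]; I <- curve$intensity[ok]; e <- curve$error[ok]
  if (length(q) < 3) stop("not enough positive low-q intensities")
  if (is.null(q_start)) q_start <- stats::quantile(q[q > 0], 0.4)
  w <- if (all(is.na(e))) rep(1, length(q)) else (I / e)^2
  sel <- q <= q_start & q > 0
  fit_rg <- function(sel) {
    X <- cbind(1, q[sel]^2)
    fit <- stats::lm.wfit(X, log(I[sel]), w[sel])
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope >= 0) stop("no Guinier regime: ln I not decreasing in q^2")
    list(Rg = sqrt(-3 * slope), I0 = exp(unname(fit$coefficients[1])))
  }
  last_sel <- NULL; it <- 0
  repeat {
    it <- it + 1
    if (sum(sel) < 3) stop("no Guinier regime: fewer than 3 usable points")
    est <- fit_rg(sel)
    new_sel <- q > 0 & q * est$Rg <= qRg_max
    if (identical(new_sel, sel) || identical(new_sel, last_sel) || it > 50) break
    last_sel <- sel; sel <- new_sel
  }
  list(Rg = est$Rg, I0 = est$I0, n_points = sum(sel),
       qRg = max(q[sel]) * est$Rg, iterations = it)
}

#' Mass-weighted radius of gyration of one frame
#'
#' @param x N x 3 coordinates.
#' @param masses Per-particle masses.
#' @param sel Optional index selection.
#' @return Rg in Angstrom.
#' @export
frame_rg <- function(x, masses = rep(1, nrow(x)), sel = NULL) {
  if (!is.null(sel)) { x <- x[sel, , drop = FALSE]; masses <- masses[sel] }
  com <- colSums(x * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(x, 2, com)^2)) / sum(masses))
}

#' Ensemble Rg distribution with block-average error
#'
#' Weighted per-frame radii of gyration, their weighted mean, and the
#' standard error of that mean from block-average analysis: frames are cut
#' (in recording order) into blocks of increasing length, the variance of
#' the weighted block means yields an error estimate per block length, and
#' the plateau (the maximum across block lengths, the usual conservative
#' reading of the block curve) is reported as the statistical error in the
#' presence of time correlation.
#'
#' @param ensemble `replica_ensemble`.
#' @param sel Optional particle selection for the Rg.
#' @param breaks Histogram breaks (passed to [hist()]). Default 30.
#' @param block_lengths Block lengths to scan; default powers of 2 up to
#'   n/8.
#' @return List with `rg` (per frame), `mean`, `se` (plateau), `block`
#'   (data.frame of block length vs error) and `hist`.
#' @export
rg_distribution <- function(ensemble, sel = NULL, breaks = 30,
                            block_lengths = NULL) {
  rg <- vapply(ensemble$frames, frame_rg, numeric(1),
               masses = ensemble$masses, sel = sel)
  w <- ensemble$weights
  mu <- sum(w * rg)
  n <- length(rg)
  if (is.null(block_lengths)) {
    block_lengths <- unique(pmin(2^(0:20), max(1, floor(n / 8))))
  }
  blk <- lapply(block_lengths, function(L) {
    nb <- floor(n / L)
    if (nb < 2) return(NULL)
    idx <- seq_len(nb * L)
    g <- rep(seq_len(nb), each = L)
    bw <- rowsum(w[idx], g)[, 1]
    bm <- rowsum((w * rg)[idx], g)[, 1] / bw
    wn <- bw / sum(bw)
    se <- sqrt(sum(wn^2 * (bm - sum(wn * bm))^2) * nb / (nb - 1))
    data.frame(block_length = L, se = se, n_blocks = nb)
  })
  blk <- do.call(rbind, blk)
  se <- if (is.null(blk) || nrow(blk) == 0) 0 else max(blk$se)
  h <- graphics::hist(rg, breaks = breaks, plot = FALSE)
  dens <- rowsum(w, findInterval(rg, h$breaks, all.inside = TRUE))
  list(rg = rg, mean = mu, se = se, block = blk,
       hist = data.frame(mid = h$mids,
                         weight = as.numeric(dens[match(seq_along(h$mids),
                                                        rownames(dens))])))
}

#' Two-dimensional free-energy surface over collective variables
#'
#' F(s1, s2) = -kB T log(sum of frame weights in the bin), shifted so the
#' minimum is 0; unvisited bins carry `Inf` and are excluded from the
#' shift. Frame weights follow the recorded bias potentials (replica-
#' averaging rule) unless explicit weights are stored.
#'
#' @param ensemble `replica_ensemble`.
#' @param cv1,cv2 `collective_variable`s.
#' @param bins Length-2 number of bins. Default `c(40, 40)`.
#' @param temperature K; defaults to the ensemble temperature.
#' @return Object of class `fes`: list with `s1`, `s2` (bin centers), `F`
#'   (matrix, kB T units), `cv_values` (per-frame data.frame).
#' @export
free_energy_surface <- function(ensemble, cv1, cv2, bins = c(40, 40),
                                temperature = NULL) {
  temperature <- temperature %||% ensemble$temperature
  m <- ensemble$masses
  v1 <- vapply(ensemble$frames, function(fr) cv_value(fr, m, cv1)$value, numeric(1))
  v2 <- vapply(ensemble$frames, function(fr) cv_value(fr, m, cv2)$value, numeric(1))
  b1 <- seq(min(v1), max(v1), length.out = bins[1] + 1)
  b2 <- seq(min(v2), max(v2), length.out = bins[2] + 1)
  i1 <- findInterval(v1, b1, all.inside = TRUE)
  i2 <- findInterval(v2, b2, all.inside = TRUE)
  W <- matrix(0, bins[1], bins[2])
  for (k in seq_along(v1)) W[i1[k], i2[k]] <- W[i1[k], i2[k]] + ensemble$weights[k]
  F <- -log(W)                                     # in kT units
  F[!is.finite(F)] <- Inf
  F <- F - min(F[is.finite(F)])
  structure(list(s1 = (b1[-1] + b1[-length(b1)]) / 2,
                 s2 = (b2[-1] + b2[-length(b2)]) / 2, F = F,
                 cv_values = data.frame(cv1 = v1, cv2 = v2,
                                        weight = ensemble$weights),
                 temperature = temperature),
            class = "fes")
}

#' Weighted mean Debye curve of an ensemble
#'
#' Back-calculates the coarse-grained Debye intensity of every frame and
#' returns the weight-averaged curve — the ensemble forward model used for
#' chi-square comparison against experiment.
#'
#' @param ensemble `replica_ensemble`.
#' @param q Scattering vector grid.
#' @param table `ff_table`; defaults to unit "TOY" constants.
#' @param ff_id Per-particle form-factor ids; default `"TOY"`.
#' @return `saxs_curve`.
#' @export
ensemble_mean_curve <- function(ensemble, q, table = NULL, ff_id = NULL) {
  N <- nrow(ensemble$frames[[1]])
  if (is.null(ff_id)) ff_id <- rep("TOY", N)
  if (is.null(table)) table <- ff_table(NULL, stats::setNames(1, "TOY"))
  Imat <- vapply(ensemble$frames, function(fr) {
    debye_intensity(bead_structure(fr, ff_id), table, q, warn = FALSE)$intensity
  }, numeric(length(q)))
  saxs_curve(q, as.numeric(Imat %*% ensemble$weights))
}

## Kabsch optimal superposition; returns RMSD after best fit
kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Bc, Ac))
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Br <- Bc %*% R
  sqrt(mean(rowSums((Ac - Br)^2)))
}

#' Cluster compact conformations (gromos neighbor-counting scheme)
#'
#' Frames with a (C-alpha-equivalent) selection Rg below `rg_cutoff` form
#' the compact pool; pairwise best-fit RMSD (quaternion-free Kabsch
#' superposition, mass-unweighted) below `rmsd_cutoff` defines neighbors;
#' the frame with the most neighbors (ties broken by lowest frame index)
#' becomes a cluster center, its neighborhood is removed, and the
#' procedure repeats. Populations are reported as weighted fractions of
#' the FULL ensemble, so they sum to the compact fraction.
#'
#' @param ensemble `replica_ensemble`.
#' @param rg_cutoff Compactness threshold (A). Default 20 (2.0 nm).
#' @param rmsd_cutoff Neighbor threshold (A). Default 6.
#' @param sel Optional particle selection for both Rg and RMSD.
#' @return List with `clusters` (data.frame: cluster, center_frame, size,
#'   population), `assignment` (per compact frame), `compact_fraction`,
#'   `compact_frames`.
#' @export
cluster_compact <- function(ensemble, rg_cutoff = 20, rmsd_cutoff = 6,
                            sel = NULL) {
  m <- ensemble$masses
  rg <- vapply(ensemble$frames, frame_rg, numeric(1), masses = m, sel = sel)
  compact <- which(rg < rg_cutoff)
  w <- ensemble$weights
  cf <- sum(w[compact])
  if (length(compact) == 0) {
    message("no compact frames below the Rg cutoff")
    return(list(clusters = data.frame(), assignment = integer(0),
                compact_fraction = 0, compact_frames = integer(0)))
  }
  getxyz <- function(k) {
    fr <- ensemble$frames[[k]]
    if (!is.null(sel)) fr[sel, , drop = FALSE] else fr
  }
  nc <- length(compact)
  D <- matrix(0, nc, nc)
  for (a in seq_len(nc)) for (b in seq_len(a - 1)) {
    D[a, b] <- D[b, a] <- kabsch_rmsd(getxyz(compact[a]), getxyz(compact[b]))
  }
  neigh <- D < rmsd_cutoff
  active <- rep(TRUE, nc)
  assignment <- rep(NA_integer_, nc)
  centers <- integer(); cl <- 0
  while (any(active)) {
    cnt <- rowSums(neigh[, active, drop = FALSE]) * active
    center <- which(cnt == max(cnt))[1]            # lowest index on ties
    members <- which(active & neigh[center, ])
    cl <- cl + 1
    assignment[members] <- cl
    centers <- c(centers, compact[center])
    active[members] <- FALSE
  }
  pops <- vapply(seq_len(cl), function(k) sum(w[compact[assignment == k]]),
                 numeric(1))
  ord <- order(pops, decreasing = TRUE)
  remap <- match(seq_len(cl), ord)
  list(clusters = data.frame(cluster = seq_len(cl),
                             center_frame = centers[ord],
                             size = as.integer(table(assignment)[as.character(ord)]),
                             population = pops[ord]),
       assignment = remap[assignment],
       compact_fraction = cf, compact_frames = compact)
}

#' Interdomain contact-frequency and Coulomb energy maps
#'
#' For two disjoint residue groups: the weighted fraction of frames in
#' which the minimum inter-particle distance of a residue pair is below
#' `contact_cutoff`, and (when charges are given) the ensemble-weighted
#' Coulomb energy E_ab = sum_{i in a, j in b} ke q_i q_j / r_ij for pairs
#' within `coulomb_cutoff`, with per-residue sums over partner residues.
#'
#' @param ensemble `replica_ensemble`.
#' @param domainA,domainB Lists of per-residue particle index vectors (one
#'   entry per residue); the two domains must not share particles.
#' @param charges Optional per-particle charges (e).
#' @param contact_cutoff Contact distance (A). Default 4.5.
#' @param coulomb_cutoff Interaction distance (A). Default 9.
#' @return List with `contact` (matrix |A| x |B|), `coulomb` (matrix or
#'   `NULL`), `per_residue_A`, `per_residue_B` (Coulomb sums, kJ/mol).
#' @export
interdomain_maps <- function(ensemble, domainA, domainB, charges = NULL,
                             contact_cutoff = 4.5, coulomb_cutoff = 9) {
  allA <- unlist(domainA); allB <- unlist(domainB)
  if (length(intersect(allA, allB))) stop("domain selections overlap")
  na <- length(domainA); nb <- length(domainB)
  Cmat <- matrix(0, na, nb)
  Emat <- if (!is.null(charges)) matrix(0, na, nb) else NULL
  w <- ensemble$weights
  for (k in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[k]]
    for (a in seq_len(na)) {
      xa <- fr[domainA[[a]], , drop = FALSE]
      for (b in seq_len(nb)) {
        xb <- fr[domainB[[b]], , drop = FALSE]
        d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
        d <- sqrt(pmax(d2, 0))
        if (min(d) < contact_cutoff) Cmat[a, b] <- Cmat[a, b] + w[k]
        if (!is.null(Emat)) {
          qq <- outer(charges[domainA[[a]]], charges[domainB[[b]]])
          inside <- d < coulomb_cutoff & d > 0
          if (any(inside)) {
            Emat[a, b] <- Emat[a, b] +
              w[k] * COULOMB_KE * sum(qq[inside] / d[inside])
          }
        }
      }
    }
  }
  list(contact = Cmat, coulomb = Emat,
       per_residue_A = if (!is.null(Emat)) rowSums(Emat) else NULL,
       per_residue_B = if (!is.null(Emat)) colSums(Emat) else NULL)
}
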