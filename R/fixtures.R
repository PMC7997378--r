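#' Generate a toy poly-alanine protein structure
#'
#' Builds a self-avoiding C-alpha walk with 3.8 Angstrom virtual bonds and
#' decorates each residue with idealized N, C, O and CB positions in the
#' local frame, giving a poly-alanine structure the shipped bead mapping
#' covers without edge cases. Deterministic given the seed.
#'
#' @param n_residues Number of residues (>= 1).
#' @param fold `"compact"` (walk confined to a globule), `"extended"`
#'   (near-straight), or `"dumbbell"` (two globules joined by an extended
#'   linker, a diubiquitin-like topology).
#' @param seed Integer seed. Default 1.
#' @return `atoms` structure.
#' @export
make_toy_protein <- function(n_residues, fold = c("compact", "extended", "dumbbell"),
                             seed = 1) {
  fold <- match.arg(fold)
  if (n_residues < 1) stop("n_residues must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ca <- .ca_walk(n_residues, fold)
  nm <- character(); el <- character(); rid <- integer(); pos <- list()
  for (i in seq_len(n_residues)) {
    ## local frame from walk direction
    fwd <- if (i < n_residues) ca[i + 1, ] - ca[i, ] else
      if (n_residues > 1) ca[i, ] - ca[i - 1, ] else c(1, 0, 0)
    fwd <- fwd / sqrt(sum(fwd^2))
    up0 <- if (abs(fwd[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    side <- .cross(fwd, up0); side <- side / sqrt(sum(side^2))
    up <- .cross(side, fwd)
    add <- function(name, elem, v) {
      nm <<- c(nm, name); el <<- c(el, elem); rid <<- c(rid, i)
      pos[[length(pos) + 1]] <<- v
    }
    add("N", "N", ca[i, ] - 1.46 * fwd + 0.3 * up)
    add("CA", "C", ca[i, ])
    add("C", "C", ca[i, ] + 1.52 * fwd - 0.3 * up)
    add("O", "O", ca[i, ] + 1.52 * fwd - 1.5 * up)
    add("CB", "C", ca[i, ] + 1.53 * side)
  }
  p <- do.call(rbind, pos)
  atoms(atom_name = nm, element = el, res_name = "ALA", res_id = rid,
        chain = "A", x = p[, 1], y = p[, 2], z = p[, 3])
}

## self-avoiding CA walk (3.8 A steps, 3.5 A clash distance, retries)
.ca_walk <- function(n, fold) {
  step <- 3.8
  if (fold == "extended") {
    t <- seq_len(n)
    return(cbind(step * t * 0.98, 1.5 * sin(t * 0.6), 1.5 * cos(t * 0.6)))
  }
  if (fold == "dumbbell") {
    n1 <- floor((n - 2) / 2); nl <- 2; n2 <- n - n1 - nl
    g1 <- .ca_walk(max(n1, 1), "compact")
    g2 <- .ca_walk(max(n2, 1), "compact")
    sep <- max(12, 1.2 * (max(dist(g1)) + max(dist(g2))) / 2)
    g2 <- sweep(g2, 2, c(sep, 0, 0), "+")
    start <- g1[nrow(g1), ]; end <- g2[1, ]
    link <- t(vapply(seq_len(nl), function(k) {
      start + (end - start) * k / (nl + 1)
    }, numeric(3)))
    return(rbind(g1, link, g2))
  }
  ## compact: confined random walk
  radius <- max(4, 2.2 * n^(1/3) * 1.6)
  xyz <- matrix(0, n, 3)
  if (n == 1) return(xyz)
  for (i in 2:n) {
    for (try in 1:200) {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2)) * step
      cand <- xyz[i - 1, ] + d
      if (sqrt(sum(cand^2)) > radius) next
      if (i > 2) {
        dd <- sqrt(rowSums(sweep(xyz[1:(i - 2), , drop = FALSE], 2, cand)^2))
        if (min(dd) < 3.5) next
      }
      xyz[i, ] <- cand
      break
    }
    if (all(xyz[i, ] == 0) && i > 1) xyz[i, ] <- xyz[i - 1, ] + c(step, 0, 0)
  }
  xyz
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build the two-globule dumbbell toy system
#'
#' Two rigid-ish tetrahedral globules of `n_per` beads each (edge held by
#' stiff harmonic bonds) whose center-of-mass distance moves in a
#' double-well with a compact minimum, an extended minimum and a finite
#' barrier — a desk-scale caricature of a two-domain protein with
#' compact/extended interconversion.
#'
#' @param n_per Beads per globule. Default 4.
#' @param d_compact,d_extended Well minima of the COM distance (A).
#'   Defaults 12 and 24.
#' @param barrier Barrier height (kJ/mol). Default 5.
#' @param k_bond Intra-globule bond constant (kJ/mol/A^2). Default 10.
#' @param mass Per-bead mass (Da). Default 20.
#' @param start `"extended"` or `"compact"` initial state.
#' @return `toy_system`; attributes `groupA`/`groupB` give the globule
#'   index sets.
#' @export
make_dumbbell_system <- function(n_per = 4, d_compact = 12, d_extended = 24,
                                 barrier = 5, k_bond = 10, mass = 20,
                                 start = c("extended", "compact")) {
  start <- match.arg(start)
  edge <- 4
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (edge / (2 * sqrt(2)))
  glob <- tet[seq_len(min(n_per, 4)), , drop = FALSE]
  if (n_per > 4) {
    extra <- matrix(stats::runif(3 * (n_per - 4), -edge / 2, edge / 2),
                    ncol = 3)
    glob <- rbind(glob, extra)
  }
  D0 <- if (start == "extended") d_extended else d_compact
  xA <- sweep(glob, 2, c(-D0 / 2, 0, 0), "+")
  xB <- sweep(glob, 2, c(+D0 / 2, 0, 0), "+")
  x <- rbind(xA, xB)
  N <- nrow(x)
  gA <- seq_len(n_per); gB <- n_per + seq_len(n_per)
  bonds <- do.call(rbind, lapply(list(gA, gB), function(g) {
    pr <- t(utils::combn(g, 2))
    r0 <- sqrt(rowSums((x[pr[, 1], , drop = FALSE] - x[pr[, 2], , drop = FALSE])^2))
    data.frame(i = pr[, 1], j = pr[, 2], k = k_bond, r0 = r0)
  }))
  sys <- toy_system(x, rep(mass, N), bonds = bonds,
                    double_well = list(groupA = gA, groupB = gB,
                                       center = (d_compact + d_extended) / 2,
                                       half_sep = (d_extended - d_compact) / 2,
                                       height = barrier))
  attr(sys, "groupA") <- gA; attr(sys, "groupB") <- gB
  sys
}

#' Two-state synthetic ensemble with known populations
#'
#' Draws frames from a compact and an extended reference geometry with
#' probabilities `p` and `1 - p`, adds isotropic Gaussian coordinate
#' jitter, and keeps the ground-truth state labels for oracle tests.
#'
#' @param compact,extended N x 3 reference coordinate matrices (same N).
#' @param p Population of the compact state, 0 < p < 1 (or exactly 0/1 for
#'   degenerate fixtures).
#' @param n_frames Number of frames.
#' @param jitter Gaussian jitter s.d. (A). Default 0.3.
#' @param masses Per-particle masses. Default 1.
#' @param seed Integer seed. Default 1.
#' @return `replica_ensemble` with `labels` (`"compact"`/`"extended"`).
#' @export
make_two_state_ensemble <- function(compact, extended, p = 0.7, n_frames = 100,
                                    jitter = 0.3, masses = NULL, seed = 1) {
  compact <- as.matrix(compact); extended <- as.matrix(extended)
  if (!all(dim(compact) == dim(extended))) stop("geometries differ in size")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (n_frames < 1) stop("n_frames must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  N <- nrow(compact)
  lab <- ifelse(stats::runif(n_frames) < p, "compact", "extended")
  frames <- lapply(lab, function(l) {
    base <- if (l == "compact") compact else extended
    base + if (jitter > 0) matrix(stats::rnorm(N * 3, sd = jitter), N, 3) else 0
  })
  replica_ensemble(frames, masses = masses %||% rep(1, N), labels = lab)
}

#' Synthetic SAXS curve from a known ensemble
#'
#' Population-weighted mean Debye intensity of the ensemble frames, with
#' multiplicative Gaussian noise of relative standard deviation
#' `noise_rel` (mimicking low-q counting statistics; additive noise
#' available via `noise_model = "additive"`, where `noise_rel` then scales
#' `I(q_min)`). The noise-free truth is returned alongside for
#' parameter-recovery oracles.
#'
#' @param ensemble `replica_ensemble`.
#' @param table `ff_table`.
#' @param ff_id Per-particle form-factor ids (default `"TOY"` constants —
#'   supply the real ids for mapped structures).
#' @param q Scattering vector grid.
#' @param noise_rel Relative noise s.d. Default 0.02.
#' @param noise_model `"multiplicative"` (default) or `"additive"`.
#' @param seed Integer seed. Default 1.
#' @return List with `curve` (noisy `saxs_curve`, errors set to the noise
#'   s.d.) and `true` (noise-free `saxs_curve`).
#' @export
make_synthetic_saxs <- function(ensemble, table = NULL, ff_id = NULL, q,
                                noise_rel = 0.02,
                                noise_model = c("multiplicative", "additive"),
                                seed = 1) {
  noise_model <- match.arg(noise_model)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  N <- nrow(ensemble$frames[[1]])
  if (is.null(ff_id)) ff_id <- rep("TOY", N)
  if (is.null(table)) table <- ff_table(NULL, stats::setNames(1, "TOY"))
  Imat <- vapply(ensemble$frames, function(fr) {
    debye_intensity(bead_structure(fr, ff_id), table, q, warn = FALSE)$intensity
  }, numeric(length(q)))
  Itrue <- as.numeric(Imat %*% ensemble$weights)
  sd_vec <- if (noise_model == "multiplicative") noise_rel * Itrue
            else rep(noise_rel * Itrue[1], length(q))
  Inoisy <- Itrue + stats::rnorm(length(q), sd = sd_vec)
  err <- pmax(sd_vec, 1e-12 * max(Itrue))
  list(curve = saxs_curve(q, Inoisy, err), true = saxs_curve(q, Itrue))
}

#' Interdomain COM distance of dumbbell frames
#'
#' @param ensemble `replica_ensemble` of dumbbell frames.
#' @param groupA,groupB Particle index sets of the two globules.
#' @return Numeric vector of per-frame COM distances (A).
#' @export
dumbbell_distance <- function(ensemble, groupA, groupB) {
  m <- ensemble$masses
  vapply(ensemble$frames, function(fr) {
    cA <- colSums(fr[groupA, , drop = FALSE] * m[groupA]) / sum(m[groupA])
    cB <- colSums(fr[groupB, , drop = FALSE] * m[groupB]) / sum(m[groupB])
    sqrt(sum((cA - cB)^2))
  }, numeric(1))
}

#' Weighted compact-state population of a dumbbell ensemble
#'
#' @inheritParams dumbbell_distance
#' @param threshold COM-distance boundary between compact and extended (A).
#' @return Weighted fraction of frames with distance below `threshold`.
#' @export
compact_fraction <- function(ensemble, groupA, groupB, threshold) {
  d <- dumbbell_distance(ensemble, groupA, groupB)
  sum(ensemble$weights[d < threshold])
}
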