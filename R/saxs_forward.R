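## sinc(x) = sin(x)/x with a series branch below 1e-6 to avoid cancellation;
## dsinc(x) = d/dx sinc(x), likewise guarded (limit 0 at x = 0).
sinc <- function(x) {
  out <- x
  small <- abs(x) < 1e-6
  out[small] <- 1 - x[small]^2 / 6
  xs <- x[!small]
  out[!small] <- sin(xs) / xs
  out
}

dsinc <- function(x) {
  out <- x
  small <- abs(x) < 1e-6
  out[small] <- -x[small] / 3
  xs <- x[!small]
  out[!small] <- (xs * cos(xs) - sin(xs)) / xs^2
  out
}

## Core Debye sum over point scatterers: positions (n x 3), factors
## (n x length(q)), returns I(q) per q. O(n^2) per q, double precision,
## no cutoff (SAXS is a global observable).
debye_sum <- function(positions, factors, q) {
  n <- nrow(positions)
  if (n == 1) return(as.numeric(factors[1, ]^2))
  D <- as.matrix(stats::dist(positions))
  vapply(seq_along(q), function(k) {
    S <- sinc(q[k] * D)
    f <- factors[, k]
    as.numeric(f %*% S %*% f)
  }, numeric(1))
}

#' Coarse-grained Debye scattering intensity
#'
#' Orientationally averaged scattering intensity of a bead structure by the
#' Debye equation, I(q) = sum_ij F_i(q) F_j(q) sinc(q R_ij), where R_ij is
#' the distance between bead centers (the i = j term contributes F_i^2 and
#' sinc(0) = 1). Complexity O(M^2) per q value. Optionally returns the
#' analytical gradient of I(q) with respect to every bead center.
#'
#' @param beads `bead_structure`.
#' @param table `ff_table` covering all bead types present.
#' @param q Scattering vectors (1/Angstrom, >= 0).
#' @param gradient Also compute dI/dr? Default `FALSE`.
#' @param warn Pass the wide-angle warning through (default `TRUE`).
#' @return Object of class `intensity_result`: list with `q`, `intensity`
#'   and, when requested, `gradient` (list over q of M x 3 matrices, units
#'   intensity/Angstrom).
#' @export
debye_intensity <- function(beads, table, q, gradient = FALSE, warn = TRUE) {
  stopifnot(inherits(beads, "bead_structure"))
  if (any(q < 0)) stop("q must be non-negative")
  X <- beads$centers
  M <- nrow(X)
  Fq <- ff_eval(table, beads$ff_id, q, warn = warn)  # M x nq
  I <- debye_sum(X, Fq, q)
  res <- list(q = q, intensity = I)
  if (gradient) {
    D <- as.matrix(stats::dist(X))
    res$gradient <- lapply(seq_along(q), function(k) {
      f <- Fq[, k]
      ## dI/dr_k = sum_{j != k} 2 f_k f_j q sinc'(q R) * (r_k - r_j)/R
      A <- q[k] * dsinc(q[k] * D)           # M x M, zero diagonal by limit
      Rsafe <- D; Rsafe[D == 0] <- 1        # coincident beads contribute 0
      C <- 2 * outer(f, f) * A              # coefficient of unit vector
      diag(C) <- 0
      G <- matrix(0, M, 3)
      for (d in 1:3) {
        dX <- outer(X[, d], X[, d], "-")    # r_k - r_j
        G[, d] <- rowSums(C * dX / Rsafe)
      }
      G
    })
  }
  structure(res, class = "intensity_result")
}

#' Debye intensity with coordinate gradients
#'
#' Convenience wrapper for [debye_intensity()] with `gradient = TRUE`.
#'
#' @inheritParams debye_intensity
#' @return `intensity_result` with a `gradient` element.
#' @export
debye_gradient <- function(beads, table, q, warn = TRUE) {
  debye_intensity(beads, table, q, gradient = TRUE, warn = warn)
}

#' Atomistic Debye reference intensity
#'
#' Full O(N^2) Debye sum over atoms with Cromer-Mann element form factors;
#' the high-resolution oracle against which the coarse-grained model is
#' validated.
#'
#' @param a `atoms` structure.
#' @param q Scattering vectors.
#' @param keep_hydrogens Include hydrogens (if present)? Default `TRUE`.
#' @return `intensity_result`.
#' @export
atomistic_debye <- function(a, q, keep_hydrogens = TRUE) {
  stopifnot(inherits(a, "atoms"))
  if (any(q < 0)) stop("q must be non-negative")
  if (!keep_hydrogens) a <- a[a$element != "H", , drop = FALSE]
  f <- atomic_form_factor(a$element, q)
  structure(list(q = q, intensity = debye_sum(coords(a), f, q)),
            class = "intensity_result")
}

#' Map bead-center gradients to parent atoms
#'
#' Chain rule through the mass-weighted virtual sites: the derivative with
#' respect to atom `a` in bead `k` is (m_a / M_k) times the bead-center
#' derivative.
#'
#' @param beads `bead_structure` with `parents` and `masses` set.
#' @param bead_grad M x 3 matrix of bead-center gradients.
#' @param atom_masses Per-atom masses of the source structure.
#' @return N x 3 matrix of per-atom gradients (zero rows for atoms outside
#'   any bead).
#' @export
bead_gradient_to_atoms <- function(beads, bead_grad, atom_masses) {
  if (is.null(beads$parents)) stop("bead structure carries no parent indices")
  G <- matrix(0, length(atom_masses), 3)
  for (k in seq_along(beads$parents)) {
    sel <- beads$parents[[k]]
    w <- atom_masses[sel] / sum(atom_masses[sel])
    G[sel, ] <- G[sel, ] + outer(w, bead_grad[k, ])
  }
  G
}

#' @export
print.intensity_result <- function(x, ...) {
  cat("Scattering intensity:", length(x$q), "q-points, I(0-most) =",
      signif(x$intensity[1], 6),
      if (!is.null(x$gradient)) "(with gradients)" else "", "\n")
  invisible(x)
}

#' Convert an intensity result to a SAXS curve
#'
#' @param x `intensity_result`.
#' @return `saxs_curve` (no errors).
#' @export
as_saxs_curve <- function(x) {
  stopifnot(inherits(x, "intensity_result"))
  saxs_curve(x$q, x$intensity)
}
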