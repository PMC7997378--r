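#' Read an atomistic structure from a PDB file
#'
#' Parses a (possibly multi-model) PDB file into an atom table with
#' coordinates in Angstrom, element assignments and per-atom masses.
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper selects one
#' model and optionally a subset of chains, and enforces the structural
#' invariants used throughout the package (finite coordinates, positive
#' masses, non-decreasing residue numbering within a chain).
#'
#' @param path Path to a PDB file.
#' @param model Model number to extract (1-based). Default 1.
#' @param chains Optional character vector of chain identifiers to keep.
#' @param keep_hydrogens Keep hydrogen atoms? Default `TRUE` (coarse-grain
#'   mapping excludes them later regardless).
#' @return An object of class `atoms`: a `data.frame` with columns
#'   `atom_name`, `element`, `res_name`, `res_id`, `chain`, `x`, `y`, `z`,
#'   `mass` and `charge` (NA where no charge is known).
#' @export
read_pdb <- function(path, model = 1, chains = NULL, keep_hydrogens = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    stop("requested model ", model, " but file has ", n_models, " model(s)")
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM")
  if (!is.null(chains)) {
    keep <- keep & at$chain %in% chains
    if (!any(keep)) {
      stop("no atoms for requested chain(s) ", paste(chains, collapse = ","),
           "; file has chains ", paste(unique(at$chain), collapse = ","))
    }
  }
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  element <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                    toupper(trimws(at$elesy)),
                    element_from_atom_name(at$elety))
  out <- atoms(
    atom_name = trimws(at$elety), element = element,
    res_name = trimws(at$resid), res_id = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  if (!keep_hydrogens) out <- out[out$element != "H", , drop = FALSE]
  out
}

#' Construct an atom table
#'
#' Low-level constructor for the atomistic structure container used across
#' the package. Masses are assigned from the element unless given.
#'
#' @param atom_name,element,res_name,res_id,chain,x,y,z Per-atom vectors.
#' @param mass Optional masses (Da); derived from `element` if `NULL`.
#' @param charge Optional partial charges (e).
#' @return `atoms` data.frame.
#' @export
atoms <- function(atom_name, element, res_name, res_id, chain = "A",
                  x, y, z, mass = NULL, charge = NA_real_) {
  if (is.null(mass)) mass <- element_mass(element)
  df <- data.frame(
    atom_name = as.character(atom_name), element = as.character(element),
    res_name = as.character(res_name), res_id = as.integer(res_id),
    chain = as.character(chain), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), mass = as.numeric(mass), charge = as.numeric(charge),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(df$x + df$y + df$z))) stop("non-finite coordinates")
  if (any(df$mass <= 0)) stop("non-positive atom mass")
  for (ch in unique(df$chain)) {
    ri <- df$res_id[df$chain == ch]
    if (is.unsorted(ri)) stop("residue indices not non-decreasing in chain ", ch)
  }
  class(df) <- c("atoms", "data.frame")
  df
}

coords <- function(a) cbind(a$x, a$y, a$z)

#' Write an atom table to a PDB file
#'
#' @param a `atoms` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(a, path) {
  stopifnot(inherits(a, "atoms"))
  bio3d::write.pdb(
    file = path, xyz = as.numeric(t(coords(a))), type = "ATOM",
    resno = a$res_id, resid = a$res_name, chain = a$chain,
    elety = a$atom_name, elesy = a$element
  )
  invisible(path)
}

#' Construct a SAXS curve
#'
#' @param q Scattering vector grid, 1/Angstrom, strictly increasing, >= 0.
#' @param intensity Intensities I(q), arbitrary units, finite.
#' @param error Optional experimental errors, > 0 where present.
#' @return Object of class `saxs_curve` (data.frame with columns `q`,
#'   `intensity`, `error`).
#' @export
saxs_curve <- function(q, intensity, error = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(q < 0)) stop("q must be non-negative")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (!all(is.finite(intensity))) stop("non-finite intensity")
  if (is.null(error)) error <- rep(NA_real_, length(q))
  if (length(error) != length(q)) stop("error length mismatch")
  if (any(!is.na(error) & error <= 0)) stop("errors must be positive")
  structure(data.frame(q = q, intensity = intensity, error = as.numeric(error)),
            class = c("saxs_curve", "data.frame"))
}

#' Read a SAXS curve in SASBDB-style .dat format
#'
#' Whitespace-separated columns q, I(q) and optionally sigma(I); lines
#' starting with `#`, blank lines and non-numeric header/footer lines are
#' skipped; extra columns are ignored. q is expected in 1/Angstrom (no unit
#' autodetection; convert externally if the deposition uses 1/nm).
#'
#' @param path Path to the .dat file.
#' @return `saxs_curve`.
#' @export
read_saxs_dat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, "[[:space:]]+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) >= 2 && !anyNA(v[1:2])) v else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no numeric data rows in ", path)
  q <- vapply(rows, `[`, numeric(1), 1)
  i <- vapply(rows, `[`, numeric(1), 2)
  e <- vapply(rows, function(v) if (length(v) >= 3 && !is.na(v[3])) v[3] else NA_real_,
              numeric(1))
  if (all(is.na(e))) e <- NULL
  saxs_curve(q, i, e)
}

#' Write a SAXS curve as 3-column .dat text
#'
#' @param curve `saxs_curve`.
#' @param path Output path.
#' @param digits Significant digits (default 16, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path, digits = 16) {
  stopifnot(inherits(curve, "saxs_curve"))
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  has_err <- !all(is.na(curve$error))
  lines <- c("# q[1/A] I(q) sigma",
             if (has_err) paste(fmt(curve$q), fmt(curve$intensity), fmt(curve$error))
             else paste(fmt(curve$q), fmt(curve$intensity)))
  writeLines(lines, path)
  invisible(path)
}

#' Centered running average of a SAXS curve
#'
#' Smooths the intensity with a centered moving mean of odd window length on
#' the unchanged q grid; near the edges the window truncates symmetrically
#' to the available points. Errors, where present, are averaged with the
#' same window (propagation is not attempted; the smoothed curve is used for
#' restraint-point selection, not for fitting).
#'
#' @param curve `saxs_curve`.
#' @param window Odd integer window length, `<= nrow(curve)`.
#' @return Smoothed `saxs_curve`.
#' @export
running_average <- function(curve, window = 21) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (window %% 2 != 1) stop("window must be odd")
  n <- nrow(curve)
  if (window > n) stop("window longer than curve")
  h <- (window - 1) / 2
  sm <- function(v) vapply(seq_len(n), function(k) {
    idx <- max(1, k - h):min(n, k + h)
    mean(v[idx])
  }, numeric(1))
  err <- if (all(is.na(curve$error))) NULL else sm(curve$error)
  saxs_curve(curve$q, sm(curve$intensity), err)
}

#' Select equally spaced restraint intensities from a smoothed SAXS curve
#'
#' Reproduces the standard restraint preparation: smooth the experimental
#' curve with a running average, then take `n` target intensities at
#' equally spaced q values in `[q_min, q_max]` by linear interpolation of
#' the smoothed curve. The defaults (11 points in 0.06-0.16 1/A, 21-point
#' window) correspond to the low-noise region of a typical protein curve.
#'
#' @param curve Experimental `saxs_curve` (unsmoothed).
#' @param n Number of restraint points (>= 2).
#' @param q_min,q_max Range of scattering vectors, inside the data range.
#' @param window Running-average window (odd); `1` disables smoothing.
#' @return Object of class `restraint_set`: list with `q`, `intensity`,
#'   `error` (interpolated where available) and `window`.
#' @export
select_restraint_points <- function(curve, n = 11, q_min = 0.06, q_max = 0.16,
                                    window = 21) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (n < 2) stop("need n >= 2 restraint points")
  if (q_min >= q_max) stop("q_min must be < q_max")
  if (q_min < min(curve$q) || q_max > max(curve$q)) {
    stop("requested q range [", q_min, ", ", q_max, "] outside data range [",
         min(curve$q), ", ", max(curve$q), "]")
  }
  sm <- running_average(curve, window)
  qs <- seq(q_min, q_max, length.out = n)
  ivals <- stats::approx(sm$q, sm$intensity, xout = qs)$y
  evals <- if (all(is.na(sm$error))) rep(NA_real_, n) else
    stats::approx(sm$q, sm$error, xout = qs)$y
  structure(list(q = qs, intensity = ivals, error = evals,
                 window = as.integer(window)),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("SAXS restraint set:", length(x$q), "points, q in [",
      min(x$q), ",", max(x$q), "] 1/A (window", x$window, ")\n")
  invisible(x)
}
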