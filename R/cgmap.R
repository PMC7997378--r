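#' Load a bead mapping table
#'
#' Reads the atoms-to-beads mapping used for coarse-graining. The shipped
#' default is a Martini 2.2-style protein mapping (one backbone bead of the
#' N, CA, C, O atoms per residue plus 0-4 side-chain beads of roughly four
#' heavy atoms each). The table is a plain-text file users can edit.
#'
#' @param path Mapping file; defaults to the shipped Martini-style table.
#' @return Object of class `bead_mapping`: a named list (by residue name)
#'   of lists with `bead` labels, `atoms` member sets and `ff_id`
#'   form-factor identifiers (`"RES:BEAD"`).
#' @export
read_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "martini22_mapping.txt", package = "metasaxs")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tok <- strsplit(lines, "[[:space:]]+")
  map <- list()
  for (t in tok) {
    if (length(t) != 3) stop("malformed mapping line: ", paste(t, collapse = " "))
    res <- t[1]; bead <- t[2]
    members <- strsplit(t[3], ",")[[1]]
    entry <- list(bead = bead, atoms = members, ff_id = paste0(res, ":", bead))
    map[[res]] <- c(map[[res]], list(entry))
  }
  for (res in names(map)) {
    all_atoms <- unlist(lapply(map[[res]], `[[`, "atoms"))
    if (anyDuplicated(all_atoms)) {
      stop("mapping for ", res, " assigns an atom to more than one bead")
    }
  }
  structure(map, class = "bead_mapping")
}

#' Bead count implied by a residue sequence
#'
#' The bead count is a pure function of sequence under the mapping table:
#' it does not depend on coordinates. Useful for checking a mapped model
#' against the expected coarse-grain size (e.g. the 328 beads of a
#' K63-linked diubiquitin construct).
#'
#' @param res_names Character vector of 3-letter residue names, or a
#'   1-letter amino-acid string.
#' @param mapping `bead_mapping`.
#' @return Integer bead count.
#' @export
count_beads <- function(res_names, mapping = read_mapping()) {
  if (length(res_names) == 1 && !res_names %in% names(mapping) &&
      nchar(res_names) > 3) {
    res_names <- aa1_to_aa3(strsplit(res_names, "")[[1]])
  }
  unknown <- setdiff(unique(res_names), names(mapping))
  if (length(unknown)) stop("no mapping for residue(s): ",
                            paste(unknown, collapse = ", "))
  sum(vapply(res_names, function(r) length(mapping[[r]]), integer(1)))
}

AA_3FROM1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa1_to_aa3 <- function(aa1) {
  out <- AA_3FROM1[toupper(aa1)]
  if (anyNA(out)) stop("unknown 1-letter code(s): ",
                       paste(unique(aa1[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Map an atomistic structure to coarse-grained beads
#'
#' Places one virtual bead per mapping entry at the mass-weighted center of
#' its member heavy atoms. Hydrogens are never bead members; terminal OXT
#' atoms join the backbone bead of their residue so the bead count stays
#' sequence-determined.
#'
#' @param a `atoms` structure.
#' @param mapping `bead_mapping`.
#' @param on_missing What to do when a mapped member atom is absent from a
#'   residue: `"error"` (default) or `"skip"` (warn and place the bead on
#'   the atoms that are present; beads with no present atoms error).
#' @return Object of class `bead_structure`: list with `centers` (M x 3),
#'   `ff_id` (length M), `parents` (list of atom index vectors into `a`),
#'   `masses` (per-bead summed parent mass), `res_id`, `chain`, `bead`.
#' @export
map_to_beads <- function(a, mapping = read_mapping(),
                         on_missing = c("error", "skip")) {
  stopifnot(inherits(a, "atoms"))
  on_missing <- match.arg(on_missing)
  heavy <- a$element != "H"
  key <- paste(a$chain, a$res_id)
  res_order <- !duplicated(key)
  xyz <- coords(a)
  centers <- list(); ff <- character(); parents <- list()
  bmass <- numeric(); rid <- integer(); rch <- character(); blab <- character()
  for (ri in which(res_order)) {
    this <- which(key == key[ri])
    rname <- a$res_name[ri]
    defs <- mapping[[rname]]
    if (is.null(defs)) stop("no bead mapping for residue ", rname,
                            " (", a$chain[ri], a$res_id[ri], ")")
    anames <- a$atom_name[this]
    for (d in defs) {
      members <- d$atoms
      if (d$bead == "BB") members <- c(members, "OXT")
      sel <- this[heavy[this] & anames %in% members]
      wanted <- setdiff(d$atoms, anames)
      if (length(wanted)) {
        msg <- paste0("residue ", rname, " ", a$chain[ri], a$res_id[ri],
                      " missing atom(s) ", paste(wanted, collapse = ","),
                      " for bead ", d$bead)
        if (on_missing == "error") stop(msg) else warning(msg)
      }
      if (!length(sel)) stop("bead ", d$bead, " of residue ", rname, " ",
                             a$chain[ri], a$res_id[ri], " has no atoms present")
      m <- a$mass[sel]
      centers[[length(centers) + 1]] <- colSums(xyz[sel, , drop = FALSE] * m) / sum(m)
      ff <- c(ff, d$ff_id); parents[[length(parents) + 1]] <- sel
      bmass <- c(bmass, sum(m)); rid <- c(rid, a$res_id[ri])
      rch <- c(rch, a$chain[ri]); blab <- c(blab, d$bead)
    }
  }
  bead_structure(do.call(rbind, centers), ff, parents = parents, masses = bmass,
                 res_id = rid, chain = rch, bead = blab)
}

#' Construct a bead structure
#'
#' @param centers M x 3 matrix of bead centers (Angstrom).
#' @param ff_id Per-bead form-factor identifiers.
#' @param parents Optional list of parent-atom index vectors.
#' @param masses Optional per-bead masses (Da).
#' @param res_id,chain,bead Optional per-bead bookkeeping vectors.
#' @return `bead_structure` list.
#' @export
bead_structure <- function(centers, ff_id, parents = NULL, masses = NULL,
                           res_id = NULL, chain = NULL, bead = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("centers must be M x 3")
  if (nrow(centers) != length(ff_id)) stop("ff_id length mismatch")
  if (!all(is.finite(centers))) stop("non-finite bead centers")
  structure(list(centers = unname(centers), ff_id = as.character(ff_id),
                 parents = parents, masses = masses, res_id = res_id,
                 chain = chain, bead = bead),
            class = "bead_structure")
}

#' @export
print.bead_structure <- function(x, ...) {
  cat("Bead structure:", nrow(x$centers), "beads,",
      length(unique(x$ff_id)), "form-factor types\n")
  invisible(x)
}

#' Cromer-Mann atomic form factors
#'
#' X-ray atomic scattering factors in vacuo as four-Gaussian fits
#' f(q) = sum_i a_i exp(-b_i (q / 4 pi)^2) + c, with q = 4 pi sin(theta) /
#' lambda in 1/Angstrom. Coefficients for H, C, N, O, S (f(0) equals the
#' atomic number to < 0.01 e).
#'
#' @param elements Character vector of element symbols.
#' @param q Scattering vectors (1/Angstrom).
#' @return Matrix of factors, `length(elements)` x `length(q)`.
#' @export
atomic_form_factor <- function(elements, q) {
  cm <- CROMER_MANN[toupper(elements)]
  if (any(vapply(cm, is.null, logical(1)))) {
    stop("no Cromer-Mann coefficients for element(s): ",
         paste(unique(elements[vapply(cm, is.null, logical(1))]), collapse = ", "))
  }
  s2 <- (q / (4 * pi))^2
  out <- vapply(cm, function(p) {
    colSums(p$a * exp(-outer(p$b, s2))) + p$c
  }, numeric(length(q)))
  ## elements x q, robust to length-1 q
  if (is.matrix(out)) t(out) else matrix(out, nrow = length(elements))
}

CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

#' Form-factor table
#'
#' Container mapping form-factor identifiers to amplitudes F(q), either as
#' interpolation tables on a q grid or as constants (useful for toy beads).
#'
#' @param q Grid of scattering vectors, or `NULL` for a constant table.
#' @param F Matrix (ids x length(q)) of amplitudes, or named numeric vector
#'   of constants when `q` is `NULL`.
#' @param ids Form-factor identifiers (rownames of `F` if missing).
#' @param q_valid Valid q range, default `c(0, 0.45)` 1/Angstrom.
#' @return Object of class `ff_table`.
#' @export
ff_table <- function(q, F, ids = NULL, q_valid = c(0, 0.45)) {
  if (is.null(q)) {
    if (is.null(ids)) ids <- names(F)
    F <- matrix(F, nrow = length(F), ncol = 1, dimnames = list(ids, NULL))
  } else {
    F <- as.matrix(F)
    if (is.null(ids)) ids <- rownames(F)
    if (length(q) != ncol(F)) stop("F must have one column per q")
  }
  if (is.null(ids)) stop("form-factor ids required")
  if (any(!is.finite(F))) stop("non-finite form factors")
  f0 <- if (is.null(q)) F[, 1] else F[, 1]
  if (any(f0 <= 0)) stop("F(0) must be positive for every bead type")
  structure(list(q = q, F = F, ids = as.character(ids), q_valid = q_valid),
            class = "ff_table")
}

#' Evaluate form factors from a table
#'
#' Linear interpolation on the table grid (constant tables return the
#' constant). Warns past 0.2 1/A where the coarse-grain approximation
#' degrades; errors outside the valid range.
#'
#' @param table `ff_table`.
#' @param ids Identifiers to evaluate (must exist in the table).
#' @param q Scattering vectors.
#' @param warn Emit the wide-angle warning? Default `TRUE`.
#' @return Matrix `length(ids)` x `length(q)`.
#' @export
ff_eval <- function(table, ids, q, warn = TRUE) {
  stopifnot(inherits(table, "ff_table"))
  miss <- setdiff(unique(ids), table$ids)
  if (length(miss)) stop("missing form factor(s): ", paste(miss, collapse = ", "))
  if (any(q < table$q_valid[1] - 1e-12) || any(q > table$q_valid[2] + 1e-12)) {
    stop("q outside valid form-factor range [", table$q_valid[1], ", ",
         table$q_valid[2], "]")
  }
  if (warn && any(q > 0.2)) {
    warning("q > 0.2 1/A: coarse-grain form factors are less accurate at wide angles")
  }
  rows <- match(ids, table$ids)
  if (is.null(table$q)) {
    matrix(table$F[rows, 1], nrow = length(ids), ncol = length(q))
  } else {
    out <- vapply(rows, function(r) {
      stats::approx(table$q, table$F[r, ], xout = q, rule = 2)$y
    }, numeric(length(q)))
    if (is.matrix(out)) t(out) else matrix(out, nrow = length(ids))
  }
}

#' Derive bead form factors by the Single Bead Approximation
#'
#' For each bead type, the effective amplitude is
#' F_bead(q) = sqrt(mean over reference structures of I_bead(q)), where
#' I_bead(q) is the atomistic Debye intensity of the bead's member heavy
#' atoms (computed about the bead center; the Debye sum is origin-free).
#' Averaging over several reference conformers captures the internal
#' geometry of the bead; the result is tabulated on `q_grid`.
#'
#' @param reference_structures List of `atoms` structures (>= 1).
#' @param mapping `bead_mapping`.
#' @param q_grid Grid for the table, default `seq(0, 0.45, by = 0.005)`.
#' @return `ff_table` covering every bead type observed in the references.
#' @export
single_bead_form_factor <- function(reference_structures, mapping = read_mapping(),
                                    q_grid = seq(0, 0.45, by = 0.005)) {
  if (inherits(reference_structures, "atoms")) {
    reference_structures <- list(reference_structures)
  }
  if (length(reference_structures) == 0) stop("need at least one reference structure")
  acc <- list(); cnt <- list()
  for (a in reference_structures) {
    beads <- map_to_beads(a, mapping)
    xyz <- coords(a)
    for (k in seq_along(beads$ff_id)) {
      id <- beads$ff_id[k]
      sel <- beads$parents[[k]]
      f <- atomic_form_factor(a$element[sel], q_grid)
      ib <- debye_sum(xyz[sel, , drop = FALSE], f, q_grid)
      acc[[id]] <- if (is.null(acc[[id]])) ib else acc[[id]] + ib
      cnt[[id]] <- if (is.null(cnt[[id]])) 1L else cnt[[id]] + 1L
    }
  }
  ids <- names(acc)
  Fm <- t(vapply(ids, function(id) sqrt(acc[[id]] / cnt[[id]]),
                 numeric(length(q_grid))))
  ff_table(q_grid, Fm, ids, q_valid = range(q_grid))
}

#' Default bead form factors for the shipped mapping
#'
#' Builds a form-factor table for every bead type in the shipped mapping by
#' the Single Bead Approximation applied to idealized residue geometries
#' (member atoms laid out as a tetrahedral chain with 1.5 Angstrom bonds),
#' using Cromer-Mann atomic factors in vacuo. The result is cached for the
#' session. Users with calibrated bead factors should load their own table.
#'
#' @param q_grid Tabulation grid.
#' @return `ff_table`.
#' @export
default_ff_table <- function(q_grid = seq(0, 0.45, by = 0.005)) {
  key <- paste(range(q_grid), length(q_grid), collapse = "_")
  cached <- .ms_cache$default_ff
  if (!is.null(cached) && identical(cached$key, key)) return(cached$table)
  mapping <- read_mapping()
  refs <- lapply(names(mapping), idealized_residue)
  tab <- single_bead_form_factor(refs, mapping, q_grid)
  .ms_cache$default_ff <- list(key = key, table = tab)
  tab
}

.ms_cache <- new.env(parent = emptyenv())

## Idealized single-residue geometry: member atoms of each bead placed as a
## zig-zag chain with 1.5 A bonds and tetrahedral angles. Captures typical
## intra-bead distances, which is what F_bead(q) is sensitive to below
## 0.45 1/A; not a stereochemically exact residue model.
idealized_residue <- function(res_name, mapping = read_mapping()) {
  defs <- mapping[[res_name]]
  if (is.null(defs)) stop("no mapping for ", res_name)
  nm <- character(); el <- character(); pos <- list()
  offset <- 0
  for (d in defs) {
    members <- d$atoms
    for (i in seq_along(members)) {
      nm <- c(nm, members[i])
      el <- c(el, element_from_atom_name(members[i]))
      ## tetrahedral zig-zag in the xz plane, beads displaced along y
      x <- 1.5 * cos(0.955) * (i - 1)
      z <- 1.5 * sin(0.955) * ((i - 1) %% 2)
      pos[[length(pos) + 1]] <- c(x, offset, z)
    }
    offset <- offset + 3.5
  }
  p <- do.call(rbind, pos)
  atoms(atom_name = nm, element = el, res_name = res_name,
        res_id = 1L, chain = "A", x = p[, 1], y = p[, 2], z = p[, 3])
}
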