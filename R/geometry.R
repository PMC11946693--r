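# Dihedral angles and periodic minimum-image distances.

.SITE_NAMES <- c("H1", "O1", "C1", "C2", "C3", "O2", "H2")

# displacement under the minimum-image convention (orthorhombic box);
# box = NULL means no periodicity
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Dihedral angle of four points
#'
#' Right-handed (IUPAC-sign) dihedral of the bonded quadruple p1-p2-p3-p4,
#' mapped from (-180, 180] to \code{[0, 360)} by adding 360 to negative
#' values. When \code{box} is given, each bond vector is taken under the
#' minimum-image convention, so molecules wrapped across a periodic boundary
#' give the same angle as their unwrapped copies. The angle is invariant
#' under rigid rotation and translation and is negated (mod 360) by
#' coordinate inversion.
#'
#' @param p1,p2,p3,p4 numeric length-3 position vectors in Angstrom.
#' @param box orthorhombic box edge lengths (length 3), or \code{NULL}.
#' @param tol collinearity tolerance: if either bond-plane normal has squared
#'   norm below \code{tol} (Angstrom^4), the geometry is degenerate.
#' @return dihedral angle in degrees on \code{[0, 360)}, or \code{NA} with a
#'   warning for degenerate (collinear) geometry.
#' @export
dihedral <- function(p1, p2, p3, p4, box = NULL, tol = 1e-10) {
  b1 <- .min_image(p2 - p1, box)
  b2 <- .min_image(p3 - p2, box)
  b3 <- .min_image(p4 - p3, box)
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < tol || sum(n2^2) < tol) {
    warning("degenerate (collinear) dihedral geometry; returning NA", call. = FALSE)
    return(NA_real_)
  }
  ang <- atan2(sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  if (ang < 0) ang <- ang + 360
  ang %% 360
}

# extract the 7 x 3 site-coordinate matrix of one molecule from a frame
.site_coords <- function(frame, sites) {
  idx <- match(sites[.SITE_NAMES], frame$ids)
  if (anyNA(idx)) {
    stop("frame is missing atom id(s): ",
         paste(sites[.SITE_NAMES][is.na(idx)], collapse = ", "), call. = FALSE)
  }
  m <- frame$coords[idx, , drop = FALSE]
  rownames(m) <- .SITE_NAMES
  m
}

#' Torsion quadruple of one molecule
#'
#' Measures the four conformation-defining dihedrals of a seven-site 1,3-diol
#' chain H1-O1-C1-C2-C3-O2-H2: H1-O1-C1-C2, O1-C1-C2-C3, C1-C2-C3-O2 and
#' C2-C3-O2-H2, with minimum-image displacements along the bonded chain.
#'
#' @param mol a 7 x 3 coordinate matrix with rows named H1, O1, C1, C2, C3,
#'   O2, H2 (Angstrom).
#' @param box orthorhombic box edge lengths, or \code{NULL}.
#' @return numeric vector of the four torsions in degrees on \code{[0, 360)};
#'   \code{NA} entries flag degenerate geometry.
#' @export
torsion_quad <- function(mol, box = NULL) {
  stopifnot(is.matrix(mol), nrow(mol) == 7L)
  if (!is.null(rownames(mol))) mol <- mol[.SITE_NAMES, , drop = FALSE]
  vapply(1:4, function(k) {
    dihedral(mol[k, ], mol[k + 1L, ], mol[k + 2L, ], mol[k + 3L, ], box = box)
  }, numeric(1L))
}

#' Intramolecular O...O distance
#'
#' Minimum-image distance between the two hydroxyl oxygens O1 and O2 of one
#' molecule. This is the distance whose per-family average tracks the
#' conformational state (short for GG' conformations with an intramolecular
#' hydrogen bond, long for extended TT chains).
#'
#' @inheritParams torsion_quad
#' @return distance in Angstrom.
#' @export
intra_oo <- function(mol, box = NULL) {
  stopifnot(is.matrix(mol), nrow(mol) == 7L)
  if (!is.null(rownames(mol))) {
    d <- .min_image(mol["O2", ] - mol["O1", ], box)
  } else {
    d <- .min_image(mol[6L, ] - mol[2L, ], box)
  }
  sqrt(sum(d^2))
}

#' All hydroxyl-oxygen pair distances in a frame
#'
#' Minimum-image distances between every pair of hydroxyl oxygens (O1 and O2
#' of every target molecule), both intra- and intermolecular: C(2N, 2)
#' distances for N molecules.
#'
#' @param frame a trajectory frame (list with \code{ids}, \code{coords},
#'   \code{box}).
#' @param topology a [topology] object naming the sites of each molecule.
#' @param selection \code{"all"}, \code{"intra"} (only O1-O2 within one
#'   molecule) or \code{"inter"} (only pairs from different molecules).
#' @return numeric vector of distances in Angstrom.
#' @export
pair_distances_oo <- function(frame, topology,
                              selection = c("all", "intra", "inter")) {
  selection <- match.arg(selection)
  oxy <- .oxygen_matrix(frame, topology)
  n_mol <- nrow(oxy) / 2L
  mol_of <- rep(seq_len(n_mol), each = 2L)
  pairs <- utils::combn(nrow(oxy), 2L)
  same <- mol_of[pairs[1L, ]] == mol_of[pairs[2L, ]]
  keep <- switch(selection, all = rep(TRUE, ncol(pairs)), intra = same, inter = !same)
  d <- oxy[pairs[2L, keep], , drop = FALSE] - oxy[pairs[1L, keep], , drop = FALSE]
  for (k in 1:3) d[, k] <- .min_image(d[, k], frame$box[k])
  sqrt(rowSums(d^2))
}

# 2N x 3 matrix of hydroxyl-oxygen coordinates (O1, O2 per molecule)
.oxygen_matrix <- function(frame, topology) {
  ids <- unlist(lapply(topology$molecules, function(s) s[c("O1", "O2")]),
                use.names = FALSE)
  idx <- match(ids, frame$ids)
  if (anyNA(idx)) stop("frame is missing oxygen atom id(s)", call. = FALSE)
  frame$coords[idx, , drop = FALSE]
}
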