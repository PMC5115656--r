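# Geometric descriptors of antioxidant-radical complexes from Cartesian
# coordinates: donor-acceptor O...O separation, O...H...O angle, ring
# plane angle, C-O*...*O-C torsion, and superposed RMSD between structures.

coords_of <- function(atoms, idx = seq_len(nrow(atoms))) {
  as.matrix(atoms[idx, c("x", "y", "z"), drop = FALSE])
}

vnorm <- function(v) sqrt(sum(v^2))

#' Euclidean distance between two atoms
#'
#' @param atoms a `kyn_atoms` table.
#' @param i,j atom indices.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(atoms, i, j) {
  vnorm(coords_of(atoms, i) - coords_of(atoms, j))
}

#' Bond angle at a vertex atom
#'
#' Angle i-vertex-j in degrees, in [0, 180].
#'
#' @param atoms a `kyn_atoms` table.
#' @param i,vertex,j atom indices.
#' @return degrees.
#' @export
bond_angle <- function(atoms, i, vertex, j) {
  a <- coords_of(atoms, i) - coords_of(atoms, vertex)
  b <- coords_of(atoms, j) - coords_of(atoms, vertex)
  if (vnorm(a) < 1e-12 || vnorm(b) < 1e-12) {
    stop("zero-length arm at the angle vertex", call. = FALSE)
  }
  cosang <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

plane_normal <- function(p) {
  n <- crossprod_3(p[2, ] - p[1, ], p[3, ] - p[1, ])
  if (vnorm(n) < 1e-10) stop("collinear atom triple defines no plane", call. = FALSE)
  n / vnorm(n)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two planes defined by atom triples
#'
#' The angle between the plane normals, folded to [0, 90] degrees (a plane
#' has no orientation). Used for the angle between the aromatic-ring
#' planes of an antioxidant and a radical, each plane fixed by the
#' ring carbon bearing O* and the two ring atoms meta to it.
#'
#' @param atoms a `kyn_atoms` table.
#' @param triple1,triple2 integer vectors of three atom indices each.
#' @return degrees in [0, 90].
#' @export
plane_angle <- function(atoms, triple1, triple2) {
  n1 <- plane_normal(coords_of(atoms, triple1))
  n2 <- plane_normal(coords_of(atoms, triple2))
  ang <- acos(pmin(1, pmax(-1, abs(sum(n1 * n2))))) * 180 / pi
  ang
}

#' Dihedral (torsion) angle of four atoms
#'
#' Right-handed IUPAC dihedral of the chain a-b-c-d, mapped to [0, 360)
#' degrees. Used for the torsion between the antioxidant C-O* bond and the
#' radical *O-C bond across the O...O axis.
#'
#' @param atoms a `kyn_atoms` table.
#' @param a,b,c,d atom indices along the chain.
#' @return degrees in [0, 360).
#' @export
torsion <- function(atoms, a, b, c, d) {
  p <- coords_of(atoms, c(a, b, c, d))
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- crossprod_3(b1, b2)
  n2 <- crossprod_3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate (collinear) geometry: torsion undefined", call. = FALSE)
  }
  m1 <- crossprod_3(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  (ang + 360) %% 360
}

#' Geometry report for an antioxidant-radical complex
#'
#' Computes the four tabulated descriptors from a role map: the
#' donor-acceptor oxygen separation ("O...H...O length", implemented as
#' the O1-O2 distance whose ~2.4-2.9 Angstrom magnitudes match the
#' tabulated values; the O1-H + H-O2 path sum is available via
#' `length_mode = "path"`), the O1-H-O2 angle, the ring plane angle, and
#' the C-O*...*O-C torsion.
#'
#' @param atoms a `kyn_atoms` table.
#' @param roles named list of indices: `O1`, `H`, `O2` (scalars), `C1`,
#'   `C2` (carbons bonded to O1/O2, for the torsion), `ring1`, `ring2`
#'   (triples, for the plane angle). `C1`/`C2` or `ring1`/`ring2` may be
#'   omitted, dropping the corresponding descriptor.
#' @param length_mode `"oo"` (O1-O2 distance, default) or `"path"`.
#' @return list with `oho_length`, `oho_angle`, and when available
#'   `plane_angle` and `torsion`.
#' @export
geometry_report <- function(atoms, roles, length_mode = c("oo", "path")) {
  length_mode <- match.arg(length_mode)
  len <- if (length_mode == "oo") {
    atom_distance(atoms, roles$O1, roles$O2)
  } else {
    atom_distance(atoms, roles$O1, roles$H) + atom_distance(atoms, roles$H, roles$O2)
  }
  out <- list(
    oho_length = len,
    oho_angle = bond_angle(atoms, roles$O1, roles$H, roles$O2)
  )
  if (!is.null(roles$ring1) && !is.null(roles$ring2)) {
    out$plane_angle <- plane_angle(atoms, roles$ring1, roles$ring2)
  }
  if (!is.null(roles$C1) && !is.null(roles$C2)) {
    out$torsion <- torsion(atoms, roles$C1, roles$O1, roles$O2, roles$C2)
  }
  out
}

#' RMSD after optimal rigid superposition (Kabsch)
#'
#' Root-mean-square deviation between two conformations of the same
#' molecule after removing the optimal rotation and translation
#' (singular-value decomposition with a reflection guard). Atom order
#' defines the correspondence; element sequences must match. Used to
#' verify that optimized reagent/product complexes coincide with the
#' endpoints of intrinsic-reaction-coordinate paths.
#'
#' @param atoms1,atoms2 `kyn_atoms` tables with identical element order.
#' @param superpose if `FALSE`, return the raw coordinate RMSD without
#'   fitting.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(atoms1, atoms2, superpose = TRUE) {
  if (nrow(atoms1) != nrow(atoms2)) {
    stop("structures have different atom counts", call. = FALSE)
  }
  if (!all(atoms1$element == atoms2$element)) {
    stop("element sequences differ: atom order defines the correspondence",
         call. = FALSE)
  }
  p <- coords_of(atoms1)
  q <- coords_of(atoms2)
  if (superpose) {
    pc <- sweep(p, 2, colMeans(p))
    qc <- sweep(q, 2, colMeans(q))
    s <- svd(t(pc) %*% qc)
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    p <- pc %*% t(rot)
    q <- qc
  }
  sqrt(mean(rowSums((p - q)^2)))
}
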