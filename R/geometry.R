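# ---- angle arithmetic on the circle ------------------------------------

#' Wrap an angle into (-180, 180]
#'
#' All dihedral arithmetic in the package lives on the circle; comparisons
#' between chi angles use wrapped differences so that -179 and +179 degrees
#' are 2 degrees apart, not 358.
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Wrapped absolute difference between two angles (degrees)
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return absolute circular difference in `[0, 180]`.
#' @export
angle_diff <- function(a, b) abs(wrap_angle(a - b))

# ---- basic vector helpers (internal) -----------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("gpcr_geometry_error: zero-length vector", call. = FALSE)
  v / n
}

# ---- distances ---------------------------------------------------------

#' Euclidean distance between two points (Angstrom)
#'
#' @param p,q numeric 3-vectors, Angstrom.
#' @return nonnegative distance in Angstrom.
#' @export
atom_distance <- function(p, q) {
  stopifnot(length(p) == 3, length(q) == 3)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("gpcr_geometry_error: non-finite coordinates", call. = FALSE)
  sqrt(sum((p - q)^2))
}

# ---- Kabsch superposition ----------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets.  The determinant of the rotation is corrected to +1
#' by flipping the singular vector of the smallest singular value, so
#' reflections are never returned.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates, paired row-wise.
#' @return an object of class `rigid_transform`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length-3), and `rmsd` (Angstrom), such
#'   that `mobile %*% t(rotation) + translation` attains `rmsd` against
#'   `reference`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.numeric(mobile) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("gpcr_geometry_error: point sets must be n x 3 matrices", call. = FALSE)
  n <- nrow(mobile)
  if (n != nrow(reference))
    stop("gpcr_geometry_error: point counts differ", call. = FALSE)
  if (n < 3)
    stop("gpcr_geometry_error: need at least 3 paired points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  # degenerate (collinear) sets have rank < 2 covariance
  if (qr(X)$rank < 2 || qr(Y)$rank < 2)
    stop("gpcr_geometry_error: degenerate (collinear) point set", call. = FALSE)
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # maps centered mobile onto centered reference
  moved <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Y)^2)))
  tr <- as.numeric(cr - R %*% cm)
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xf a `rigid_transform` from [superpose()].
#' @param coords n x 3 matrix (or length-3 vector).
#' @return transformed coordinates, same shape as input.
#' @export
apply_transform <- function(xf, coords) {
  stopifnot(inherits(xf, "rigid_transform"))
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, ncol = 3) else as.matrix(coords)
  out <- sweep(m %*% t(xf$rotation), 2, xf$translation, "+")
  if (vec) as.numeric(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

# RMS between paired coordinate sets, no fitting.
.rms <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# ---- dihedrals and chi angles ------------------------------------------

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from `p2` toward `p3`, a clockwise
#' rotation of the far bond relative to the near bond is positive.  The
#' value is reported in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.vnorm(b1) < 1e-9 || .vnorm(b2) < 1e-9 || .vnorm(b3) < 1e-9)
    stop("gpcr_geometry_error: coincident consecutive points in dihedral",
         call. = FALSE)
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# chi2 is defined through the delta atom; which atom that is depends on
# the residue type (ring residues use CD1).
.chi2_atom <- c(TRP = "CD1", PHE = "CD1", TYR = "CD1", HIS = "ND1",
                LEU = "CD1", ILE = "CD1", MET = "SD", ASN = "OD1",
                ASP = "OD1", GLN = "CD", GLU = "CD", LYS = "CD",
                ARG = "CD", PRO = "CD")

.gamma_atom <- c(VAL = "CG1", ILE = "CG1", THR = "OG1", SER = "OG",
                 CYS = "SG")

#' Side-chain chi1/chi2 dihedrals of a residue
#'
#' chi1 is N-CA-CB-(gamma atom); chi2 is CA-CB-(gamma)-(delta atom), with
#' CD1 as the delta atom for Trp/Phe/Tyr ring side chains.  Alanine and
#' glycine have no chi angle; requesting one raises a condition of class
#' `gpcr_no_chi_error`, which downstream code uses to detect toggle-switch
#' alanine mutants.
#'
#' @param res a residue as returned by [get_residue()].
#' @return list with `chi1` and `chi2` (degrees; `chi2` is `NA` when the
#'   residue type defines no chi2).
#' @export
chi_angles <- function(res) {
  rn <- toupper(res$resname)
  if (rn %in% c("ALA", "GLY"))
    stop(structure(class = c("gpcr_no_chi_error", "error", "condition"),
                   list(message = sprintf(
                     "residue %s %s%d has no chi angles (possible toggle-switch mutant)",
                     rn, res$chain, res$resseq), call = NULL)))
  gname <- if (rn %in% names(.gamma_atom)) .gamma_atom[[rn]] else "CG"
  need <- c("N", "CA", "CB", gname)
  pos <- lapply(need, function(a) residue_atom_xyz(res, a))
  chi1 <- dihedral(pos[[1]], pos[[2]], pos[[3]], pos[[4]])
  chi2 <- NA_real_
  if (rn %in% names(.chi2_atom)) {
    dname <- .chi2_atom[[rn]]
    dpos <- residue_atom_xyz(res, dname, required = FALSE)
    if (!is.null(dpos))
      chi2 <- dihedral(pos[[2]], pos[[3]], pos[[4]], dpos)
  }
  list(chi1 = chi1, chi2 = chi2)
}

# ---- ring centroids ----------------------------------------------------

#' Benzene-ring atom names for a residue type
#'
#' Phe/Tyr use the six-membered benzene ring; Trp uses the six-membered
#' (benzene) ring of the indole.
#'
#' @param resname 3-letter residue code.
#' @return character vector of atom names.
#' @export
ring_atom_names <- function(resname) {
  switch(toupper(resname),
         PHE = ,
         TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
         TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
         stop(sprintf("gpcr_geometry_error: no ring definition for residue type '%s'",
                      resname), call. = FALSE))
}

#' Centroid of a residue's ring atoms
#'
#' @param res residue from [get_residue()].
#' @param ring_atoms atom names; default from [ring_atom_names()].
#' @return numeric 3-vector, Angstrom.
#' @export
ring_centroid <- function(res, ring_atoms = ring_atom_names(res$resname)) {
  pos <- vapply(ring_atoms, function(a) {
    p <- residue_atom_xyz(res, a, required = FALSE)
    if (is.null(p))
      stop(structure(class = c("gpcr_incomplete_sidechain_error", "error", "condition"),
                     list(message = sprintf(
                       "residue %s %s%d: missing ring atom %s",
                       res$resname, res$chain, res$resseq, a), call = NULL)))
    p
  }, numeric(3))
  rowMeans(pos)
}

# ---- internal-coordinate atom placement (NeRF) -------------------------

# Place atom D bonded to C, given chain A-B-C, bond length r (C-D), bond
# angle theta (B-C-D, degrees) and dihedral phi (A-B-C-D, degrees, IUPAC).
# Used by the synthetic builder so chi targets are exact by construction.
place_atom_nerf <- function(a, b, c_, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- .unit(c_ - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}
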