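# Internal-coordinate geometry: dihedral measurement, NeRF placement,
# least-squares rigid superposition.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate (zero-length) vector in frame construction")
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric xyz vectors (Angstrom). The dihedral is about
#'   the `p2`-`p3` bond, IUPAC sign convention.
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(cross3(b1, b2)) < 1e-10 || vnorm(cross3(b2, b3)) < 1e-10)
    stop("collinear atoms: dihedral undefined")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

#' Measure a named torsion in a coordinate set
#'
#' @param coords numeric matrix with xyz rows named by atom identifier.
#' @param atoms character vector of four atom identifiers.
#' @return signed dihedral in degrees, (-180, 180].
#' @export
measure_torsion <- function(coords, atoms) {
  stopifnot(length(atoms) == 4L)
  if (!all(atoms %in% rownames(coords)))
    stop("atoms not present: ",
         paste(setdiff(atoms, rownames(coords)), collapse = ", "))
  dihedral_angle(coords[atoms[1], ], coords[atoms[2], ],
                 coords[atoms[3], ], coords[atoms[4], ])
}

# Place one atom from bonded reference A, angle reference B, dihedral
# reference C (the NeRF construction): |new-A| = r, angle(new,A,B) = theta,
# dihedral(new,A,B,C) = phi.
nerf_place <- function(A, B, C, r, theta_deg, phi_deg) {
  th <- deg2rad(theta_deg)
  ph <- deg2rad(phi_deg)
  bc <- unit(A - B)
  n <- cross3(B - C, bc)
  if (vnorm(n) < 1e-10) stop("collinear reference triple: frame undefined")
  n <- unit(n)
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  A + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build Cartesian coordinates from a molecular topology
#'
#' Sequentially places every atom of `topology$tree` with the NeRF
#' construction. The first atom sits at the origin, the second along +x and
#' the third in the xy-plane. Dihedral slots referencing a torsion name are
#' resolved from `torsion_values` (plus the record's fixed offset); slots
#' with no torsion name use the offset alone as a fixed dihedral.
#'
#' @param topology a `glyco_topology` (see [ha_topology()]).
#' @param torsion_values named numeric vector, degrees, one entry per free
#'   torsion named in the tree.
#' @return numeric matrix (atoms x 3) with rownames in tree order. Measured
#'   dihedrals reproduce the supplied values to within 1e-4 degrees.
#' @export
build_cartesian <- function(topology, torsion_values = numeric()) {
  tree <- topology$tree
  n <- nrow(tree)
  xyz <- matrix(NA_real_, n, 3, dimnames = list(tree$atom, NULL))
  need <- unique(tree$torsion[!is.na(tree$torsion)])
  missing <- setdiff(need, names(torsion_values))
  if (length(missing) > 0L)
    stop("unresolved torsion(s): ", paste(missing, collapse = ", "))
  for (i in seq_len(n)) {
    if (i == 1L) {
      xyz[i, ] <- c(0, 0, 0)
    } else if (i == 2L) {
      xyz[i, ] <- c(tree$length[i], 0, 0)
    } else if (i == 3L) {
      # third atom in the xy-plane at the stated bond angle
      th <- deg2rad(tree$angle[i])
      A <- xyz[tree$ref1[i], ]
      B <- xyz[tree$ref2[i], ]
      bc <- unit(A - B)
      perp <- unit(c(-bc[2], bc[1], 0))
      xyz[i, ] <- A - tree$length[i] * cos(th) * bc +
        tree$length[i] * sin(th) * perp
    } else {
      phi <- tree$offset[i]
      if (!is.na(tree$torsion[i]))
        phi <- phi + torsion_values[[tree$torsion[i]]]
      xyz[i, ] <- nerf_place(xyz[tree$ref1[i], ], xyz[tree$ref2[i], ],
                             xyz[tree$ref3[i], ],
                             tree$length[i], tree$angle[i], wrap_angle(phi))
    }
  }
  xyz
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `|| R x + t - y ||` over the paired coordinate sets, with reflection
#' explicitly excluded, and reports the residual RMSD.
#'
#' @param x,y numeric matrices (n x 3) of corresponding points; `x` is
#'   moved onto `y`. Requires n >= 3 non-collinear points.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`,
#'   and `transform(coords)`, a function applying the fit to any m x 3 set.
#' @export
kabsch_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3L, ncol(y) == 3L, nrow(x) == nrow(y))
  if (nrow(x) < 3L) stop("need at least 3 point correspondences")
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  if (min(svd(x0)$d) < 1e-8 * max(svd(x0)$d))
    stop("collinear anchor points: superposition ill-defined")
  H <- t(x0) %*% y0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(x %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fit - y)^2)))
  list(rotation = R, translation = t, rmsd = rmsd,
       transform = function(coords) {
         out <- sweep(as.matrix(coords) %*% t(R), 2, t, "+")
         dimnames(out) <- dimnames(coords)
         out
       })
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b matrices (n x 3) of paired coordinates.
#' @return RMSD in the coordinate units.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

# Signed volume of the tetrahedron formed by a stereocentre and three
# neighbours: its sign is the chirality fingerprint used by the ensemble
# invariance checks.
signed_volume <- function(coords, center, n1, n2, n3) {
  a <- coords[n1, ] - coords[center, ]
  b <- coords[n2, ] - coords[center, ]
  d <- coords[n3, ] - coords[center, ]
  sum(cross3(a, b) * d) / 6
}
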