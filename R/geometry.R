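#' Euclidean distance between two points
#'
#' @param a,b numeric 3-vectors (Angstrom).
#' @return distance in Angstrom.
#' @export
point_distance <- function(a, b) {
  assert_that(length(a) == 3L && length(b) == 3L, "points must be 3-vectors")
  vnorm(as.numeric(a) - as.numeric(b))
}

#' Torsion angle of four points
#'
#' IUPAC sign convention: looking down the p2->p3 axis, a clockwise
#' rotation of the far bond relative to the near bond is positive. The
#' angle is computed with the atan2 form on the two plane normals and
#' returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  assert_that(
    vnorm(n1) > 1e-9 && vnorm(n2) > 1e-9,
    "torsion undefined: three collinear points"
  )
  b2u <- vunit(b2)
  ang <- rad2deg(atan2(sum(vcross(n1, n2) * b2u), sum(n1 * n2)))
  wrap_angle(ang)
}

#' Distance between two named atoms in a frame
#'
#' @param trajectory a `kor_trajectory`.
#' @param frame frame index.
#' @param res_a,atom_a,res_b,atom_b residue numbers and atom names of the
#'   two atoms, resolved against the topology.
#' @param chain_a,chain_b optional chains.
#' @return distance in Angstrom.
#' @export
frame_distance <- function(trajectory, frame, res_a, atom_a, res_b, atom_b,
                           chain_a = NULL, chain_b = NULL) {
  co <- trajectory$frames[[frame]]
  ia <- atom_index(trajectory$topology, res_a, atom_a, chain_a)
  ib <- atom_index(trajectory$topology, res_b, atom_b, chain_b)
  point_distance(co[ia, ], co[ib, ])
}

#' Place a fourth atom from internal coordinates
#'
#' Natural-extension (NeRF) construction: returns the position `D` bonded
#' to `c_pos` with bond length `r`, bond angle `theta` = angle(B, C, D)
#' and torsion `phi` = torsion(A, B, C, D) under the same sign convention
#' as [torsion_angle()]. Used by the trajectory generator to realize
#' prescribed dihedrals exactly.
#'
#' @param a_pos,b_pos,c_pos positions of the three reference atoms.
#' @param r bond length C-D (Angstrom).
#' @param theta bond angle B-C-D (degrees).
#' @param phi torsion A-B-C-D (degrees).
#' @return numeric 3-vector.
#' @export
place_atom <- function(a_pos, b_pos, c_pos, r, theta, phi) {
  assert_that(r > 0, "bond length must be positive")
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  bc <- vunit(as.numeric(c_pos) - as.numeric(b_pos))
  ab <- as.numeric(b_pos) - as.numeric(a_pos)
  n <- vunit(vcross(ab, bc))
  m <- vcross(n, bc)
  d_local <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  as.numeric(c_pos) + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' R3.50 side-chain orientation flag
#'
#' "Facing the intracellular side" is operationalized as a negative
#' projection of the Calpha -> Czeta unit vector on the membrane normal
#' (+z = extracellular by convention); equivalently, the angle between the
#' side-chain vector and the intracellular direction is below `threshold`.
#'
#' @param ca_pos,cz_pos Calpha and Czeta positions of the arginine.
#' @param normal membrane normal unit vector, +z = extracellular.
#' @param threshold angle threshold in degrees (default 90).
#' @return logical: `TRUE` if the side chain points intracellularly.
#' @export
r_orientation <- function(ca_pos, cz_pos, normal = c(0, 0, 1), threshold = 90) {
  v <- vunit(as.numeric(cz_pos) - as.numeric(ca_pos))
  nrm <- vunit(as.numeric(normal))
  ang <- rad2deg(acos(pmin(1, pmax(-1, sum(v * -nrm)))))
  ang < threshold
}
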