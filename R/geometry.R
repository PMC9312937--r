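# Low-level 3D geometry: vector helpers, internal-coordinate atom placement
# (NeRF), and torsion-driven backbone construction used by the synthetic
# generator and by the ideal-segment fixtures.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between two vectors in degrees
#' @noRd
vec_angle <- function(u, v) {
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Dihedral angle a-b-c-d in degrees, IUPAC sign convention
#' @noRd
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom D given positions of A, B, C, the bond length |C-D|, the bond
# angle B-C-D and the dihedral A-B-C-D (both in degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unitv(c - b)
  n  <- unitv(cross3(b - a, bc))
  m  <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Ideal backbone covalent geometry (Engh-Huber-style means, Angstrom/degrees).
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

#' Build a peptide backbone from torsion angles
#'
#' Constructs N, CA, C, O coordinates for a chain of `length(phi)` residues
#' with the given phi/psi/omega torsions and ideal bond lengths and angles.
#' `phi[1]` has no structural effect (there is no preceding carbonyl).
#'
#' @param phi,psi numeric vectors of backbone torsions in degrees, one per
#'   residue.
#' @param omega peptide-bond torsions in degrees (default all trans, 180).
#' @return list of four n x 3 matrices: `N`, `CA`, `C`, `O`.
#' @export
build_backbone <- function(phi, psi, omega = rep(180, length(phi))) {
  n <- length(phi)
  stopifnot(n >= 1L, length(psi) == n, length(omega) == n)
  g <- .bb_geom
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  N[1L, ]  <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1L, ]  <- CA[1L, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  if (n > 1L) {
    for (i in 2:n) {
      N[i, ]  <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                            g$b_c_n, g$a_ca_c_n, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, omega[i - 1L])
      C[i, ]  <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                            g$b_ca_c, g$a_n_ca_c, phi[i])
      # carbonyl O of residue i-1: sp2 carbon, bisecting CA and the next N
      u <- unitv(C[i - 1L, ] - CA[i - 1L, ])
      v <- unitv(C[i - 1L, ] - N[i, ])
      O[i - 1L, ] <- C[i - 1L, ] + g$b_c_o * unitv(u + v)
    }
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ],
                       g$b_c_o, g$a_ca_c_o, psi[n] + 180)
  list(N = N, CA = CA, C = C, O = O)
}
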