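# Internal-coordinate geometry helpers.

vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                           a[3L] * b[1L] - a[1L] * b[3L],
                           a[1L] * b[2L] - a[2L] * b[1L])

# Place atom d given three reference atoms a-b-c, the c-d bond length, the
# b-c-d angle and the a-b-c-d dihedral (degrees). Standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- vunit(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) stop("degenerate frame: reference atoms collinear")
  n <- vunit(n)
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# angle a-b-c in degrees
atom_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# dihedral a-b-c-d in degrees
atom_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# random rotation matrix (uniform via QR of Gaussian matrix), for tests
random_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3L, 3L))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}
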