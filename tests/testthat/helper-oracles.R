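# Independent oracles and tiny fixtures shared across the suite. Every
# oracle here deliberately re-derives its quantity by a different route than
# the package implementation.

# Closed-form dipolar kernel via Fresnel integrals:
#   int_0^1 cos(a (1 - 3 z^2)) dz
#     = [cos(a) C(x) + sin(a) S(x)] / x,  x = sqrt(6 a / pi)
fresnel_kernel <- function(t, r) {
  D <- 52.04
  K <- matrix(0, length(t), length(r))
  for (i in seq_along(t)) for (j in seq_along(r)) {
    a <- 2 * pi * D / r[j]^3 * t[i]
    K[i, j] <- if (a < 1e-12) 1 else {
      x <- sqrt(6 * a / pi)
      (cos(a) * pracma::fresnelC(x) + sin(a) * pracma::fresnelS(x)) / x
    }
  }
  K
}

# NeRF oracle: explicit rotation-matrix construction. Start from the trans
# position in the p1-p2-p3 plane and rotate about the p2->p3 axis by
# (180 - torsion) using the Rodrigues formula.
nerf_oracle <- function(p1, p2, p3, bond, angle, torsion) {
  unit <- function(v) v / sqrt(sum(v^2))
  rodrigues <- function(v, axis, theta) {
    axis <- unit(axis)
    v * cos(theta) + pracma::cross(axis, v) * sin(theta) +
      axis * sum(axis * v) * (1 - cos(theta))
  }
  bc <- unit(p3 - p2)
  n <- unit(pracma::cross(p2 - p1, bc))
  # trans (torsion = 180) position: in the p1-p2-p3 plane, on the side of
  # the p2-p3 axis opposite to p1
  in_plane <- rodrigues(bc, n, -(180 - angle) * pi / 180)
  trans_pt <- p3 + bond * in_plane
  # rotate the trans point about the p2->p3 axis into the requested torsion
  rel <- trans_pt - p3
  p3 + rodrigues(rel, bc, (180 - torsion) * pi / 180)
}

trapz <- function(x, y) sum((diff(x)) * (y[-1] + y[-length(y)]) / 2)

# Earth-mover distance between two densities on a common grid (L1 distance
# of their CDFs).
emd <- function(r, d1, d2) {
  dr <- r[2] - r[1]
  c1 <- cumsum(d1) * dr; c2 <- cumsum(d2) * dr
  sum(abs(c1 / max(c1) - c2 / max(c2))) * dr
}

# Two-atom PDB fixture: CA at the origin and CA at (26, 0, 0) Angstrom.
two_ca_pdb <- function() {
  paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      26.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
}

pdb_atom_line <- function(serial, name, resno, x, y, z, chain = "A",
                          resid = "ALA", elem = "C") {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resid, chain, resno, x, y, z, elem)
}

# A small isolated single-residue structure with backbone only (vacuum
# fixture for the tag model).
vacuum_residue <- function() {
  txt <- paste(
    pdb_atom_line(1, "N", 1, -1.20, 0.80, 0.00, elem = "N"),
    pdb_atom_line(2, "CA", 1, 0.00, 0.00, 0.00),
    pdb_atom_line(3, "C", 1, 1.40, 0.60, 0.10),
    "END", sep = "\n")
  parse_pdb(txt)
}

# Independent clash-scan oracle: rebuilds the ring probe at every grid pair
# and counts clashes with a plain double loop over distances.
scan_oracle <- function(s, site, grid_step = 10, cutoff = 2.5) {
  a <- s$atoms
  env <- a[a$element != "H" &
             !(a$chain_id == site$chain_id & a$res_seq == site$res_seq &
                 !a$het), c("x", "y", "z")]
  vals <- seq(-180 + grid_step, 180, by = grid_step)
  best <- NULL
  for (c1 in vals) for (c2 in vals) {
    pos <- deerscape:::build_ring_atoms(s, site, c1, c2)
    cnt <- 0L
    for (lab in deerscape:::ring_labels) {
      p <- pos[[lab]]
      d2 <- (env$x - p[1])^2 + (env$y - p[2])^2 + (env$z - p[3])^2
      if (length(d2) && any(d2 < cutoff^2)) cnt <- cnt + 1L
    }
    if (is.null(best) || cnt < best$score)
      best <- list(chi1 = c1, chi2 = c2, score = cnt)
  }
  best
}

# Markov stationary distribution by brute-force power iteration (oracle for
# the eigenvector route).
stationary_power <- function(P, iters = 2000L) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.numeric(v %*% P)
  v / sum(v)
}
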