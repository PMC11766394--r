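# Shared fixture builders and small geometry utilities for the test suite.

# Minimal handwritten two-record PDB: one protein CA and one zinc.
minimal_pdb <- function() {
  c("ATOM      1  CA  ALA A   1      11.000  10.000  10.000  1.00  0.00           C",
    "HETATM    2 ZN    ZN A 500      10.000  10.000  10.000  1.00  0.00          ZN")
}

# Build a zb_structure directly from a zinc position and donor offsets, to
# bypass PDB-text coordinate rounding where exact geometry matters.
site_from_offsets <- function(offsets, zn = c(10, 10, 10),
                              elements = NULL, names_ = NULL,
                              resnames = NULL) {
  n <- nrow(offsets)
  if (is.null(elements)) elements <- rep("N", n)
  if (is.null(names_)) names_ <- rep("NE2", n)
  if (is.null(resnames)) resnames <- rep("HIS", n)
  atoms <- data.frame(
    serial = seq_len(n + 1),
    name = c(names_, "ZN"),
    element = c(elements, "Zn"),
    resname = c(resnames, "ZN"),
    resid = c(10L * seq_len(n), 500L),
    chain = "A",
    x = c(zn[1] + offsets[, 1], zn[1]),
    y = c(zn[2] + offsets[, 2], zn[2]),
    z = c(zn[3] + offsets[, 3], zn[3]),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source_id = "test site"),
            class = "zb_structure")
}

first_site <- function(s, ...) find_zinc_sites(s, ...)[[1]]

# Angle between two vectors, degrees.
vec_angle <- function(a, b) {
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, d))) * 180 / pi
}

unit <- function(v) v / sqrt(sum(v^2))

tetrahedral_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid motion (rotation R then translation t) to a zb_structure.
transform_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

# A four-heavy-atom hydroxamate-like ligand with unique atom names, for
# RMSD tests (pairing is by atom name).
toy_ligand <- function() {
  atoms <- data.frame(
    serial = 1:4,
    name = c("C1", "C2", "N1", "O1"),
    element = c("C", "C", "N", "O"),
    resname = "LIG", resid = 1L, chain = "A",
    x = c(0, 1.5, 2.2, 3.5),
    y = c(0, 0.2, 1.3, 1.2),
    z = c(0, 0.1, 0.4, 0.9),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source_id = "toy ligand"),
            class = "zb_structure")
}

# Near-uniform directions on the unit sphere (Fibonacci lattice), for the
# brute-force max-min-angle oracle.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Independent oracle: the direction maximizing the minimum angle to the
# occupied directions, by exhaustive search over a dense direction set.
brute_force_vacant <- function(occ, n_dirs = 1e5) {
  dirs <- fibonacci_sphere(n_dirs)
  cosines <- dirs %*% t(occ)           # n_dirs x n_occ
  min_ang <- apply(acos(pmin(pmax(cosines, -1), 1)), 1, min)
  dirs[which.max(min_ang), ]
}

# Perturb a unit vector by at most max_deg degrees.
perturb_dir <- function(d, max_deg) {
  if (max_deg == 0) return(d)
  repeat {
    cand <- unit(d + stats::rnorm(3, 0, max_deg / 100))
    if (vec_angle(cand, d) <= max_deg) return(cand)
  }
}
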