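# Synthetic zinc-site structures and docking logs with known ground truth,
# and the embedded experimental/calculated pKi reference table.

# Ideal coordination direction sets (unit vectors). Occupied positions are
# taken from the front of each list, so the default 3-ligand tetrahedral
# site leaves the fourth vertex vacant.
.geometry_dirs <- function(geometry) {
  s3 <- 1 / sqrt(3)
  switch(geometry,
    tetrahedral = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                        c(-1, -1, 1)) * s3,
    trigonal_bipyramidal = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                                 c(-0.5, -sqrt(3) / 2, 0),
                                 c(0, 0, 1), c(0, 0, -1)),
    octahedral_vacant = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                              c(0, -1, 0), c(0, 0, 1)),
    stop("unknown geometry '", geometry, "'", call. = FALSE))
}

#' Generate a synthetic zinc coordination site as PDB text
#'
#' Emits a `HETATM` zinc at a stated origin plus `n_ligands` protein donor
#' atoms placed at `bond_length` along ideal coordination directions, each
#' direction optionally perturbed by an independent small-angle jitter
#' (rotation by an angle drawn from `N(0, angular_jitter)` degrees about a
#' random perpendicular axis). The default emulates the catalytic zinc site
#' of an HDAC: two histidine NE2 nitrogens and one aspartate OD1 oxygen on a
#' tetrahedron, leaving one vertex vacant for the ligand zinc-binding group.
#'
#' Output is deterministic for a fixed seed. The manifest records the
#' jitter-free ground truth, in particular the true vacant axis against
#' which [vacant_axis()] recovery can be scored.
#'
#' @param n_ligands Number of occupied coordination positions (2 to one less
#'   than the geometry's vertex count, so a vacancy always remains).
#' @param bond_length Zn--donor distance in Angstrom.
#' @param geometry `"tetrahedral"`, `"trigonal_bipyramidal"` or
#'   `"octahedral_vacant"`.
#' @param angular_jitter Standard deviation of the per-donor angular
#'   perturbation, degrees.
#' @param seed Integer seed for the jitter draws.
#' @return List with `pdb` (PDB text) and `manifest` (list: `vacant_axis`
#'   unit vector of the jitter-free site, `atom_count`, `zinc_xyz`,
#'   `geometry`, `n_ligands`, `bond_length`, `angular_jitter`, `seed`).
#' @examples
#' fix <- make_zinc_site(angular_jitter = 5, seed = 42)
#' fix$manifest$vacant_axis
#' @export
make_zinc_site <- function(n_ligands = 3, bond_length = 2.1,
                           geometry = "tetrahedral", angular_jitter = 0,
                           seed = 1) {
  stopifnot(angular_jitter >= 0, bond_length > 0)
  dirs <- .geometry_dirs(geometry)
  if (n_ligands < 2 || n_ligands > nrow(dirs) - 1)
    stop(sprintf("n_ligands must be in [2, %d] for %s geometry",
                 nrow(dirs) - 1, geometry), call. = FALSE)
  occ <- dirs[seq_len(n_ligands), , drop = FALSE]
  res <- colSums(occ)
  true_axis <- -res / sqrt(sum(res^2))
  placed <- .with_seed(seed, {
    t(apply(occ, 1, .jitter_dir, sd_deg = angular_jitter))
  })
  zn <- c(10, 10, 10)
  # donor identities cycle HIS/HIS/ASP/HIS/ASP: NE2 nitrogens and OD1 oxygens
  resnames <- rep(c("HIS", "HIS", "ASP", "HIS", "ASP"),
                  length.out = n_ligands)
  names_ <- ifelse(resnames == "HIS", "NE2", "OD1")
  elements <- ifelse(resnames == "HIS", "N", "O")
  atoms <- data.frame(
    serial = seq_len(n_ligands),
    name = names_, element = elements, resname = resnames,
    resid = 10L * seq_len(n_ligands), chain = "A",
    x = zn[1] + bond_length * placed[, 1],
    y = zn[2] + bond_length * placed[, 2],
    z = zn[3] + bond_length * placed[, 3],
    stringsAsFactors = FALSE)
  atoms <- rbind(atoms,
                 data.frame(serial = n_ligands + 1L, name = "ZN",
                            element = "Zn", resname = "ZN", resid = 500L,
                            chain = "A", x = zn[1], y = zn[2], z = zn[3],
                            stringsAsFactors = FALSE))
  s <- structure(list(atoms = atoms, source_id = "synthetic zinc site"),
                 class = "zb_structure")
  list(pdb = write_pdb(s),
       manifest = list(vacant_axis = true_axis,
                       atom_count = n_ligands + 1L,
                       zinc_xyz = zn, geometry = geometry,
                       n_ligands = n_ligands, bond_length = bond_length,
                       angular_jitter = angular_jitter, seed = seed))
}

# Rotate unit vector d by an angle ~ N(0, sd_deg) degrees about a uniformly
# random axis (Rodrigues). The component of the axis parallel to d does not
# move d, so the realized angular displacement is |angle|*sin(axis, d).
.jitter_dir <- function(d, sd_deg) {
  if (sd_deg == 0) return(d)
  k <- stats::rnorm(3)
  k <- k / sqrt(sum(k^2))
  ang <- stats::rnorm(1, 0, sd_deg) * pi / 180
  kxd <- c(k[2] * d[3] - k[3] * d[2],
           k[3] * d[1] - k[1] * d[3],
           k[1] * d[2] - k[2] * d[1])
  v <- d * cos(ang) + kxd * sin(ang) + k * sum(k * d) * (1 - cos(ang))
  v / sqrt(sum(v^2))
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic docking log with a known clustering histogram
#'
#' Emits a minimal docking-log dialect whose `CLUSTERING HISTOGRAM` section
#' contains exactly the given clusters, ranks assigned in input order, and is
#' parseable by [parse_dlg()].
#'
#' @param clusters Data.frame with columns `mean_dg`, `lowest_dg` and `size`
#'   (one row per cluster; `lowest_dg <= mean_dg`, `size >= 1`).
#' @param seed Seed for the synthetic run identifiers.
#' @return Docking-log text.
#' @export
make_dlg <- function(clusters, seed = 1) {
  if (!nrow(clusters)) stop("at least one cluster required", call. = FALSE)
  if (any(clusters$size < 1)) stop("cluster sizes must be >= 1", call. = FALSE)
  if (any(clusters$lowest_dg > clusters$mean_dg + 1e-9))
    stop("lowest_dg must not exceed mean_dg", call. = FALSE)
  n <- nrow(clusters)
  runs <- .with_seed(seed, sample.int(100, n))
  bar <- vapply(clusters$size, function(s)
    paste(rep("#", min(s, 40)), collapse = ""), "")
  rows <- sprintf("%4d |%10.2f |%6d |%10.2f |%4d |%s",
                  seq_len(n), clusters$lowest_dg, runs, clusters$mean_dg,
                  clusters$size, bar)
  paste(c(
    "________________________________________________________________________________",
    "",
    "     CLUSTERING HISTOGRAM",
    "     ____________________",
    "",
    "_____|___________|_____|___________|_____|______________________________________",
    "Clus | Lowest    | Run | Mean      | Num | Histogram",
    "-ter | Binding   |     | Binding   | in  |",
    "Rank | Energy    |     | Energy    | Clus|    5    10   15   20   25   30   35",
    "_____|___________|_____|___________|_____|____:____|____:____|____:____|____:___",
    rows,
    "_____|___________|_____|___________|_____|______________________________________"),
    collapse = "\n")
}

#' Embedded reference table of experimental and calculated pKi values
#'
#' Twenty-six ligand--isoform pairs (10 HDAC2, 6 HDAC4, 10 HDAC8) of
#' hydroxamic-acid HDAC inhibitors: experimental Ki (nM) from a single
#' binding-assay source, the corresponding experimental pKi, and
#' docking-derived pKi for the deprotonated (`pki_dps`) and protonated
#' (`pki_ps`) ligand series. Every `pki_exp` equals
#' `round(ki_to_pki(ki_nM), 2)`.
#'
#' @return Data.frame with columns `isoform`, `name`, `ki_nM`, `pki_exp`,
#'   `pki_dps`, `pki_ps`.
#' @examples
#' tab <- load_reference_table()
#' table(tab$isoform)
#' @export
load_reference_table <- function() {
  path <- system.file("extdata", "hdac_pki_reference.tsv",
                      package = "zincbias", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
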