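# Vacant-axis prediction from a zinc coordination sphere and placement of
# ligand-acceptor bias sites, plus bias parameter file (BPF) I/O.
#
# The idea: once the co-crystallized ligand is stripped from a zinc
# metalloenzyme, the protein-side donor atoms occupy only part of the zinc's
# coordination polyhedron. The direction that points away from the mean of the
# occupied coordination positions is the natural place for a ligand
# zinc-binding-group acceptor atom, and a docking bias well placed there
# steers pose generation toward chelation.

#' Build a coordination model from a zinc site
#'
#' @param site A `zb_znsite` from [find_zinc_sites()] with at least two
#'   ligating atoms.
#' @return A `zb_coordmodel`: list with `origin` (zinc position, Angstrom),
#'   `unit_dirs` (n x 3 matrix of unit vectors zinc -> donor, site order) and
#'   `resultant` (their component-wise sum).
#' @export
coordination_model <- function(site) {
  stopifnot(inherits(site, "zb_znsite"))
  la <- site$ligating_atoms
  if (nrow(la) < 2)
    stop("insufficient coordination sphere (need >= 2 ligating atoms)",
         call. = FALSE)
  origin <- as.numeric(site$zinc[1, c("x", "y", "z")])
  v <- as.matrix(la[, c("x", "y", "z")])
  v <- sweep(v, 2, origin)
  nv <- sqrt(rowSums(v^2))
  u <- v / nv
  dimnames(u) <- NULL
  structure(list(origin = origin, unit_dirs = u,
                 resultant = colSums(u)),
            class = "zb_coordmodel")
}

#' Vacant coordination axis of a zinc site
#'
#' Returns the unit vector `-r / |r|` where `r` is the resultant (vector sum)
#' of the occupied coordination unit directions: the direction pointing away
#' from the mean of the occupied positions. For three donors at ideal
#' tetrahedral geometry this is exactly the fourth tetrahedral vertex.
#'
#' @param m A `zb_coordmodel` from [coordination_model()].
#' @param eps Degeneracy threshold on `|r|`; a balanced sphere (for example a
#'   perfect trans pair) has no defined vacancy.
#' @return Unit 3-vector.
#' @export
vacant_axis <- function(m, eps = 1e-6) {
  stopifnot(inherits(m, "zb_coordmodel"))
  r <- m$resultant
  nr <- sqrt(sum(r^2))
  if (nr <= eps)
    stop("degenerate coordination; vacant axis undefined", call. = FALSE)
  -r / nr
}

#' Place zinc-interaction bias sites for a coordination site
#'
#' Places acceptor bias spheres along the vacant coordination axis `v` of the
#' site. `monodentate` puts one site at `zinc + bond_length * v`.
#' `bidentate` puts two sites at
#' `zinc + bond_length * (cos(bite/2) v +/- sin(bite/2) w)`, emulating the
#' two oxygens of a chelating hydroxamate; `w` is the unit vector
#' perpendicular to `v` that bisects the largest angular gap among the
#' occupied donor directions projected onto the plane perpendicular to `v`
#' (ties broken toward the candidate with lexicographically smallest
#' `(x, y, z)`), so the O...O edge leans into the most open region of the
#' first shell. Both placements are exactly `bond_length` from the zinc.
#'
#' @param site A `zb_znsite`.
#' @param mode `"bidentate"` (default) or `"monodentate"`.
#' @param bond_length Zn--acceptor distance in Angstrom (default 2.1, middle
#'   of the usual Zn--O coordination range).
#' @param bite_angle Acceptor--Zn--acceptor angle in degrees for bidentate
#'   placement (default 76, giving an O...O separation of about 2.59 A, the
#'   hydroxamate chelation bite).
#' @param energy Bias well depth Vset in kcal/mol (negative = attractive).
#' @param radius Bias sphere radius in Angstrom.
#' @return A `zb_bias_sites` data.frame with columns `x`, `y`, `z`, `energy`,
#'   `radius`, `kind`.
#' @examples
#' fix <- make_zinc_site(seed = 7)
#' site <- find_zinc_sites(parse_structure(fix$pdb))[[1]]
#' place_bias_sites(site, mode = "monodentate")
#' @export
place_bias_sites <- function(site, mode = c("bidentate", "monodentate"),
                             bond_length = 2.1, bite_angle = 76,
                             energy = -2.00, radius = 0.8) {
  mode <- match.arg(mode)
  stopifnot(bond_length > 0, radius > 0)
  m <- coordination_model(site)
  v <- vacant_axis(m)
  if (mode == "monodentate") {
    p <- matrix(m$origin + bond_length * v, 1, 3, byrow = TRUE)
  } else {
    if (!(bite_angle > 0 && bite_angle < 180))
      stop("bite_angle must lie in (0, 180) degrees", call. = FALSE)
    w <- .gap_bisector(m$unit_dirs, v)
    half <- bite_angle * pi / 360
    p <- rbind(m$origin + bond_length * (cos(half) * v + sin(half) * w),
               m$origin + bond_length * (cos(half) * v - sin(half) * w))
  }
  out <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                    energy = energy, radius = radius,
                    kind = "acceptor", stringsAsFactors = FALSE)
  class(out) <- c("zb_bias_sites", "data.frame")
  out
}

# Unit vector perpendicular to v bisecting the largest angular gap among the
# occupied directions projected onto the plane perpendicular to v.
.gap_bisector <- function(unit_dirs, v) {
  basis <- .plane_basis(v)
  proj <- unit_dirs - tcrossprod(unit_dirs %*% v, v)
  nrm <- sqrt(rowSums(proj^2))
  ok <- nrm > 1e-9
  if (!any(ok)) return(basis$e1)  # donors collinear with v: any w is valid
  th <- atan2(proj[ok, , drop = FALSE] %*% basis$e2,
              proj[ok, , drop = FALSE] %*% basis$e1)[, 1]
  th <- sort(th)
  gaps <- c(diff(th), th[1] + 2 * pi - th[length(th)])
  starts <- th
  big <- which(gaps >= max(gaps) - 1e-9)
  cand <- vapply(big, function(i) {
    b <- starts[i] + gaps[i] / 2
    cos(b) * basis$e1 + sin(b) * basis$e2
  }, numeric(3))
  cand <- t(cand)
  if (nrow(cand) > 1) {
    o <- do.call(order, as.data.frame(round(cand, 9)))
    cand <- cand[o, , drop = FALSE]
  }
  cand[1, ]
}

# Deterministic orthonormal basis of the plane perpendicular to unit vector v.
.plane_basis <- function(v) {
  ref <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) c(1, 0, 0)
         else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Write bias sites to a bias parameter file
#'
#' Emits the whitespace-separated BPF dialect consumed by bias-docking tools:
#' a `#x y z Vset r type` header comment, then one line per site with
#' coordinates to 3 decimals, well depth and radius to 2 decimals, and the
#' interaction type encoded `acc`/`don`/`map`. Output order is input order.
#'
#' @param sites A `zb_bias_sites` data.frame (or any data.frame with the same
#'   columns); an empty set yields the header only.
#' @param path Optional output file.
#' @return The BPF text, invisibly when `path` is given.
#' @export
write_bpf <- function(sites, path = NULL) {
  kinds <- c(acceptor = "acc", donor = "don", map = "map")
  lines <- "#x y z Vset r type"
  if (nrow(sites)) {
    if (!all(is.finite(unlist(sites[, c("x", "y", "z", "energy", "radius")]))))
      stop("non-finite bias site field", call. = FALSE)
    if (!all(sites$kind %in% names(kinds)))
      stop("unknown bias kind: ",
           paste(setdiff(sites$kind, names(kinds)), collapse = ", "),
           call. = FALSE)
    lines <- c(lines, sprintf("%.3f %.3f %.3f %.2f %.2f %s",
                              sites$x, sites$y, sites$z, sites$energy,
                              sites$radius, kinds[sites$kind]))
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a bias parameter file
#'
#' Inverse of [write_bpf()] on its own output. Lines starting with `#` are
#' comments; blank lines are ignored.
#'
#' @param text BPF text (string or character vector of lines) or a file path.
#' @return A `zb_bias_sites` data.frame.
#' @export
read_bpf <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- .split_lines(text)
  kinds <- c(acc = "acceptor", don = "donor", map = "map")
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 6)
      stop(sprintf("line %d: expected 6 fields, got %d", i, length(f)),
           call. = FALSE)
    num <- suppressWarnings(as.numeric(f[1:5]))
    if (anyNA(num))
      stop(sprintf("line %d: unparseable numeric field", i), call. = FALSE)
    if (!f[6] %in% names(kinds))
      stop(sprintf("line %d: unknown type token '%s'", i, f[6]),
           call. = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(x = num[1], y = num[2], z = num[3], energy = num[4],
                 radius = num[5], kind = kinds[[f[6]]],
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               energy = numeric(), radius = numeric(), kind = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("zb_bias_sites", "data.frame")
  out
}
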