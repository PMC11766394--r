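# Fixed-column PDB/PDBQT reading, an atom-table structure model, and geometric
# zinc coordination-site detection.

#' Parse a PDB or PDBQT character stream into a structure
#'
#' Reads fixed-column `ATOM`/`HETATM` records. PDBQT records (which append
#' partial charge and AutoDock atom-type columns) are accepted by ignoring
#' everything past the element columns. All other record types (`TER`,
#' `REMARK`, `CONECT`, ...) are skipped.
#'
#' Coordinates are taken from columns 31--54 (1-based, three 8.3 fixed-point
#' fields). The element symbol is taken from columns 77--78 when present and
#' otherwise inferred from the leading alphabetic characters of the atom name
#' (for `ATOM` records a leading organic-element letter wins, so `"CA"` on a
#' protein record is carbon while a `HETATM` named `"ZN"` is zinc).
#'
#' @param text PDB-format text: a single string or a character vector of lines.
#' @param source_id Free-text label stored on the returned structure.
#' @return An object of class `zb_structure`: a list with `atoms` (a
#'   data.frame with columns `serial`, `name`, `element`, `resname`, `resid`,
#'   `chain`, `x`, `y`, `z`, one row per atom record, file order preserved)
#'   and `source_id`.
#' @examples
#' s <- parse_structure(c(
#'   "ATOM      1  CA  ALA A   1      11.000  10.000  10.000  1.00  0.00           C",
#'   "HETATM    2 ZN    ZN A 500      10.000  10.000  10.000  1.00  0.00          ZN"))
#' s$atoms$element
#' @seealso [find_zinc_sites()], [write_pdb()]
#' @export
parse_structure <- function(text, source_id = "structure") {
  lines <- .split_lines(text)
  rec <- substr(lines, 1, 6)
  is_atom <- grepl("^ATOM ?", rec) | rec == "HETATM"
  if (!any(is_atom)) stop("no atoms in input", call. = FALSE)
  idx <- which(is_atom)
  n <- length(idx)
  serial <- integer(n); name <- character(n); element <- character(n)
  resname <- character(n); resid <- integer(n); chain <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ln <- lines[[idx[k]]]
    lineno <- idx[k]
    # pad so substr() on short PDBQT-ish lines is safe
    ln <- formatC(ln, width = 80, flag = "-")
    serial[k] <- .parse_int_field(substr(ln, 7, 11), lineno, "serial")
    name[k] <- trimws(substr(ln, 13, 16))
    resname[k] <- trimws(substr(ln, 18, 21))
    chain[k] <- trimws(substr(ln, 22, 22))
    resid[k] <- .parse_int_field(substr(ln, 23, 26), lineno, "residue number")
    for (j in 1:3) {
      f <- substr(ln, 31 + 8 * (j - 1), 38 + 8 * (j - 1))
      v <- suppressWarnings(as.numeric(trimws(f)))
      if (is.na(v) || !is.finite(v))
        stop(sprintf("line %d: unparseable %s-coordinate field '%s'",
                     lineno, c("x", "y", "z")[j], trimws(f)), call. = FALSE)
      xyz[k, j] <- v
    }
    el <- trimws(substr(ln, 77, 78))
    if (!grepl("^[A-Za-z]{1,2}$", el))
      el <- .element_from_name(name[k], startsWith(rec[idx[k]], "ATOM"))
    element[k] <- .normalize_element(el)
  }
  atoms <- data.frame(serial = serial, name = name, element = element,
                      resname = resname, resid = resid, chain = chain,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source_id = source_id),
            class = "zb_structure")
}

#' Read a structure from a PDB/PDBQT file
#'
#' @param path Path to a PDB or PDBQT file.
#' @inheritParams parse_structure
#' @return A `zb_structure`; see [parse_structure()].
#' @export
read_structure <- function(path, source_id = basename(path)) {
  parse_structure(readLines(path, warn = FALSE), source_id = source_id)
}

#' Serialize a structure back to PDB records
#'
#' Inverse of [parse_structure()] on its own output: re-parsing the returned
#' text reproduces every atom field exactly.
#'
#' @param s A `zb_structure`.
#' @param path Optional file path; when given the text is also written there.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- .atom_table(s)
  het <- toupper(a$element) %in% c("ZN", "MG", "MN", "FE", "CA", "NI", "CU",
                                   "CO", "NA", "K", "CL") |
    a$resname %in% c("HOH", "WAT")
  rec <- ifelse(het, "HETATM", "ATOM  ")
  # atom names shorter than 4 chars start in column 14 by PDB convention
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf("%s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   rec, a$serial, nm, a$resname,
                   ifelse(a$chain == "", " ", a$chain), a$resid,
                   a$x, a$y, a$z, toupper(a$element))
  txt <- paste(c(lines, "END"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Detect zinc coordination sites in a structure
#'
#' Every atom with element Zn becomes one candidate site. Its ligating atoms
#' are all other atoms whose element is in `donor_elements` and whose distance
#' to the zinc is at most `cutoff`, sorted by distance ascending. Detection is
#' purely geometric: coordinating residue identities are reported, never
#' enforced, because crystallographic zinc sites vary in His/Asp composition.
#'
#' Water oxygens (residue names `HOH`/`WAT`) are excluded unless
#' `include_water = TRUE`. Sites with fewer than two ligating atoms are still
#' returned, flagged with `insufficient_coordination = TRUE`.
#'
#' @param s A `zb_structure`.
#' @param cutoff Detection cutoff in Angstrom (default 2.6; typical first-shell
#'   Zn--N/O bonds are 1.9--2.3 A).
#' @param donor_elements Element symbols eligible to ligate the zinc.
#' @param include_water Include water oxygens as donors?
#' @param chain Optional chain identifier; when given only that chain is
#'   scanned for both zincs and donors.
#' @return A list of `zb_znsite` objects, each with fields `zinc` (one-row
#'   atom data.frame), `ligating_atoms` (atom data.frame sorted by distance),
#'   `distances` (Angstrom, parallel to `ligating_atoms`), `residue_summary`
#'   (data.frame of `resname`, `resid`, `chain`), `insufficient_coordination`
#'   and `cutoff`. Structures without zinc yield an empty list.
#' @examples
#' fix <- make_zinc_site(seed = 1)
#' sites <- find_zinc_sites(parse_structure(fix$pdb))
#' sites[[1]]$residue_summary
#' @export
find_zinc_sites <- function(s, cutoff = 2.6,
                            donor_elements = c("N", "O", "S"),
                            include_water = FALSE, chain = NULL) {
  stopifnot(cutoff > 0)
  a <- .atom_table(s)
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  zn_idx <- which(toupper(a$element) == "ZN")
  donors <- toupper(a$element) %in% toupper(donor_elements)
  donors <- donors & !(toupper(a$element) == "ZN")
  if (!include_water) donors <- donors & !(a$resname %in% c("HOH", "WAT"))
  lapply(zn_idx, function(i) {
    cand <- which(donors)
    cand <- cand[cand != i]
    d <- sqrt((a$x[cand] - a$x[i])^2 + (a$y[cand] - a$y[i])^2 +
                (a$z[cand] - a$z[i])^2)
    keep <- d <= cutoff
    cand <- cand[keep]; d <- d[keep]
    o <- order(d)
    cand <- cand[o]; d <- d[o]
    lig <- a[cand, , drop = FALSE]
    rownames(lig) <- NULL
    structure(list(
      zinc = a[i, , drop = FALSE],
      ligating_atoms = lig,
      distances = d,
      residue_summary = unique(lig[, c("resname", "resid", "chain"),
                                   drop = FALSE]),
      insufficient_coordination = length(d) < 2,
      cutoff = cutoff), class = "zb_znsite")
  })
}

#' @export
print.zb_znsite <- function(x, ...) {
  cat(sprintf("Zinc site: serial %d, chain %s, %d ligating atom(s) within %.2f A%s\n",
              x$zinc$serial, ifelse(x$zinc$chain == "", "-", x$zinc$chain),
              length(x$distances), x$cutoff,
              if (x$insufficient_coordination) " [insufficient coordination]" else ""))
  if (length(x$distances)) {
    la <- x$ligating_atoms
    for (k in seq_along(x$distances))
      cat(sprintf("  %-4s %-4s %s%-4d  %.3f A\n", la$name[k], la$resname[k],
                  la$chain[k], la$resid[k], x$distances[k]))
  }
  invisible(x)
}

#' @export
print.zb_structure <- function(x, ...) {
  cat(sprintf("zb_structure '%s': %d atoms, %d chain(s)\n", x$source_id,
              nrow(x$atoms), length(unique(x$atoms$chain))))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

.split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

.parse_int_field <- function(field, lineno, what) {
  v <- suppressWarnings(as.integer(trimws(field)))
  if (is.na(v))
    stop(sprintf("line %d: unparseable %s field '%s'", lineno, what,
                 trimws(field)), call. = FALSE)
  v
}

.element_from_name <- function(name, is_protein_record) {
  tok <- sub("^[^A-Za-z]*([A-Za-z]+).*$", "\\1", name)
  if (tok == "") stop("atom name '", name, "' has no alphabetic characters",
                      call. = FALSE)
  first <- toupper(substr(tok, 1, 1))
  if (is_protein_record && nchar(tok) > 1 && first %in% c("C", "N", "O", "S", "H", "P"))
    return(first)
  tok
}

.normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

.atom_table <- function(s) {
  if (inherits(s, "zb_structure")) return(s$atoms)
  if (is.data.frame(s)) return(s)
  stop("expected a zb_structure or an atom data.frame", call. = FALSE)
}
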