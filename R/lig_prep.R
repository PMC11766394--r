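# Hydroxamic acid detection and O-deprotonation on SMILES input.
#
# Hydroxamic acids R-C(=O)-N(H)-OH are the canonical zinc-binding group of
# HDAC inhibitors; inside the catalytic site the hydroxyl proton is lost and
# the resulting hydroxamate chelates the zinc as a bidentate anion. This
# module produces that O-deprotonated form by removing the hydroxyl proton
# and setting a -1 formal charge on the oxygen, leaving the rest of the
# molecule untouched. SMILES<->SDF conversion and canonical serialization go
# through OpenBabel (ChemmineOB); the substructure match runs on the SDF
# connection table.

#' Find hydroxamic acid groups in a SMILES string
#'
#' Matches the substructure `C(=O)-N-O(H)`: a carbonyl carbon single-bonded
#' to a nitrogen that bears a hydroxyl. The hydroxyl oxygen must be neutral
#' and bonded only to the nitrogen (so an already deprotonated `N-[O-]`, or
#' an O-substituted N-O, does not match).
#'
#' @param smiles A single SMILES string.
#' @return A data.frame with one row per match and columns `C`, `N`, `O`:
#'   1-based atom indices (SDF atom-block order) of the carbonyl carbon, the
#'   nitrogen, and the hydroxyl oxygen.
#' @examples
#' find_hydroxamic_groups("CC(=O)NO")      # acetohydroxamic acid: 1 match
#' find_hydroxamic_groups("c1ccccc1")      # benzene: none
#' @export
find_hydroxamic_groups <- function(smiles) {
  mol <- .smiles_to_mol(smiles)
  .match_hydroxamic(mol)
}

#' O-deprotonate every hydroxamic acid group
#'
#' For each match found by [find_hydroxamic_groups()], removes the hydroxyl
#' proton and assigns the oxygen a formal charge of -1; the net molecular
#' charge drops by the number of matches and all other atoms are unchanged.
#'
#' @param smiles A single SMILES string containing at least one hydroxamic
#'   acid group.
#' @return The canonical SMILES of the deprotonated (hydroxamate) form.
#' @examples
#' deprotonate_hydroxamic("CC(=O)NO")
#' @export
deprotonate_hydroxamic <- function(smiles) {
  mol <- .smiles_to_mol(smiles)
  hits <- .match_hydroxamic(mol)
  if (nrow(hits) == 0)
    stop("no hydroxamic acid group found", call. = FALSE)
  chg <- mol$charges
  chg[hits$O] <- chg[hits$O] - 1L
  sdf <- .set_sdf_charges(mol$sdf_text, chg)
  .canonical_smiles_of_sdf(sdf)
}

#' Net formal charge of a molecule given as SMILES
#'
#' Sum of atomic formal charges; the bookkeeping quantity that drops by one
#' per deprotonated group.
#'
#' @param smiles A single SMILES string.
#' @return Integer net charge.
#' @export
smiles_net_charge <- function(smiles) {
  sum(.smiles_to_mol(smiles)$charges)
}

#' Heavy-atom count of a molecule given as SMILES
#'
#' @param smiles A single SMILES string.
#' @return Number of non-hydrogen atoms.
#' @export
smiles_heavy_atoms <- function(smiles) {
  mol <- .smiles_to_mol(smiles)
  sum(mol$symbol != "H")
}

#' Read / write .smi ligand lists
#'
#' One record per line: a SMILES string followed by an optional
#' whitespace-separated name. Blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return `read_smi`: a data.frame with columns `smiles` and `name`.
#' @export
read_smi <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  data.frame(smiles = vapply(parts, `[[`, "", 1),
             name = vapply(parts, function(p)
               if (length(p) > 1) paste(p[-1], collapse = " ") else "", ""),
             stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param ligands Data.frame with columns `smiles` and optionally `name`.
#' @export
write_smi <- function(ligands, path) {
  nm <- if ("name" %in% names(ligands)) ligands$name else ""
  writeLines(trimws(paste(ligands$smiles, nm)), path)
  invisible(path)
}

# ---- internal ---------------------------------------------------------------

# Parse SMILES via OpenBabel into an SDF-backed molecule model:
# element symbols, bond table (from, to, order), per-atom formal charges,
# and the raw SDF text used for later charge editing.
.smiles_to_mol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf_text <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) "")
  if (!nzchar(sdf_text) || !grepl("V2000", sdf_text))
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1)
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  at <- lines[5:(4 + n_atoms)]
  symbol <- trimws(substr(at, 32, 34))
  bonds <- if (n_bonds > 0) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    data.frame(from = as.integer(substr(bl, 1, 3)),
               to = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(from = integer(), to = integer(), order = integer())
  charges <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charges[f[2 * j]] <- f[2 * j + 1]
  }
  list(symbol = symbol, bonds = bonds, charges = charges,
       sdf_text = sdf_text, n_atoms = n_atoms)
}

# Graph match of the hydroxamic pattern on the bond table.
.match_hydroxamic <- function(mol) {
  b <- rbind(mol$bonds,
             data.frame(from = mol$bonds$to, to = mol$bonds$from,
                        order = mol$bonds$order))
  degree <- tabulate(b$from, nbins = mol$n_atoms)
  hits <- list()
  for (n_idx in which(mol$symbol == "N")) {
    nb <- b[b$from == n_idx, , drop = FALSE]
    # hydroxyl oxygen: single bond, terminal heavy atom, neutral
    o_ok <- nb$to[mol$symbol[nb$to] == "O" & nb$order == 1 &
                    degree[nb$to] == 1 & mol$charges[nb$to] == 0]
    # carbonyl carbon: single bond to N, and a double-bonded oxygen
    c_ok <- nb$to[mol$symbol[nb$to] == "C" & nb$order == 1]
    c_ok <- c_ok[vapply(c_ok, function(ci) {
      cb <- b[b$from == ci, , drop = FALSE]
      any(mol$symbol[cb$to] == "O" & cb$order == 2)
    }, logical(1))]
    for (ci in c_ok) for (oi in o_ok)
      hits[[length(hits) + 1L]] <- data.frame(C = ci, N = n_idx, O = oi)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(C = integer(), N = integer(), O = integer())
}

# Rewrite the formal-charge block (M  CHG lines) of a V2000 SDF.
.set_sdf_charges <- function(sdf_text, charges) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^M  CHG", lines)]
  nz <- which(charges != 0L)
  if (length(nz)) {
    # at most 8 atom/charge pairs per M CHG line per the V2000 format
    chunks <- split(nz, ceiling(seq_along(nz) / 8))
    chg_lines <- vapply(chunks, function(ix)
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, charges[ix]), collapse = "")),
      "")
    end <- match("M  END", lines)
    lines <- append(lines, chg_lines, after = end - 1L)
  }
  paste(lines, collapse = "\n")
}

.canonical_smiles_of_sdf <- function(sdf_text) {
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = sdf_text)
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}
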