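# Docking-log clustering histogram parsing and representative-energy
# selection.

#' Parse the clustering histogram of a docking log
#'
#' Locates the section whose header contains `CLUSTERING HISTOGRAM` and reads
#' its pipe-separated data rows: `rank | lowest binding energy | run | mean
#' binding energy | count [| histogram bar]`. Decorative header and ruler
#' lines inside the section are skipped; the section ends at the first line
#' that no longer matches the row shape once at least one data row has been
#' read. Trailing histogram bars are ignored.
#'
#' @param text Docking-log text (string or character vector of lines) or a
#'   file path.
#' @return A data.frame of cluster records in file order, with columns
#'   `rank`, `lowest_dg`, `run_id`, `mean_dg` (kcal/mol) and `size`.
#' @examples
#' dlg <- make_dlg(data.frame(mean_dg = c(-8.0, -7.5),
#'                            lowest_dg = c(-8.3, -7.9),
#'                            size = c(60, 30)))
#' parse_dlg(dlg)
#' @export
parse_dlg <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- .split_lines(text)
  start <- grep("CLUSTERING HISTOGRAM", lines, fixed = TRUE)
  if (!length(start)) stop("no clustering histogram", call. = FALSE)
  if (start[1] >= length(lines)) stop("no clustering histogram", call. = FALSE)
  rows <- list()
  for (i in (start[1] + 1L):length(lines)) {
    ln <- lines[[i]]
    f <- trimws(strsplit(ln, "|", fixed = TRUE)[[1]])
    candidate <- length(f) >= 5 && grepl("^\\d+$", f[1])
    if (!candidate) {
      if (length(rows)) break else next
    }
    rank <- as.integer(f[1])
    lowest <- suppressWarnings(as.numeric(f[2]))
    run <- suppressWarnings(as.integer(f[3]))
    mean_dg <- suppressWarnings(as.numeric(f[4]))
    size <- suppressWarnings(as.integer(f[5]))
    if (anyNA(c(lowest, run, mean_dg, size)) || size < 1) {
      if (length(rows)) break
      stop(sprintf("line %d: malformed clustering histogram row", i),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(rank = rank, lowest_dg = lowest, run_id = run,
                 mean_dg = mean_dg, size = size)
    if (i == length(lines)) break
  }
  if (!length(rows))
    stop("no clustering histogram", call. = FALSE)
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$rank))
    stop("duplicate cluster ranks in histogram", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Representative binding free energy of a clustered docking run
#'
#' Implements the reproducible energy-extraction rule: take the mean binding
#' energy of the most populated cluster; when several clusters have similar
#' populations, average the mean binding energies across them. "Similar" is
#' operationalized as a population of at least `similar_frac` times the
#' largest cluster's population, so with the default 0.9 a single dominant
#' cluster reduces the rule to its own mean energy.
#'
#' @param clusters A data.frame from [parse_dlg()] (columns `mean_dg`,
#'   `size`).
#' @param similar_frac Population fraction (0, 1] defining "similar".
#' @return Representative free energy of binding in kcal/mol.
#' @examples
#' cl <- data.frame(mean_dg = c(-8.0, -7.5, -6.0), size = c(45, 44, 10))
#' representative_dg(cl)   # averages the two similar clusters: -7.75
#' @export
representative_dg <- function(clusters, similar_frac = 0.9) {
  if (!nrow(clusters)) stop("no clusters", call. = FALSE)
  stopifnot(similar_frac > 0, similar_frac <= 1)
  top <- max(clusters$size)
  mean(clusters$mean_dg[clusters$size >= similar_frac * top])
}
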