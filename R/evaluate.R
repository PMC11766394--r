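# Thermodynamic conversion of docking energies, correlation with experiment,
# pose-rank statistics, and masked in-place RMSD.

#' Thermodynamic constants for the free energy / Ki relationship
#'
#' @param temperature Absolute temperature in Kelvin; default 310 K
#'   (physiological).
#' @return List with gas constant `R` = 0.0019872036 kcal/(K mol) and `T`.
#' @export
thermo_constants <- function(temperature = 310) {
  stopifnot(temperature > 0)
  list(R = 0.0019872036, T = temperature)
}

#' Convert a binding free energy to an inhibition constant
#'
#' `Ki = exp(dG / (R T))`, in molar, with `dG` in kcal/mol.
#'
#' @param dg Free energy of binding, kcal/mol (negative = favorable).
#' @param const Constants from [thermo_constants()].
#' @return Inhibition constant in molar.
#' @examples
#' dg_to_ki(-12.28)   # ~2.2e-9 M
#' @export
dg_to_ki <- function(dg, const = thermo_constants()) {
  stopifnot(all(is.finite(dg)))
  exp(dg / (const$R * const$T))
}

#' Convert a nanomolar Ki to pKi
#'
#' `pKi = -log10(Ki [M])`, so a 1 nM inhibitor has pKi 9.
#'
#' @param ki_nM Inhibition constant in nanomolar; must be positive.
#' @return pKi (dimensionless).
#' @export
ki_to_pki <- function(ki_nM) {
  if (any(!is.finite(ki_nM)) || any(ki_nM <= 0))
    stop("Ki must be positive and finite", call. = FALSE)
  -log10(ki_nM * 1e-9)
}

#' Convert a binding free energy directly to pKi
#'
#' Composition of [dg_to_ki()] and the molar negative decimal logarithm;
#' strictly decreasing in `dg`.
#'
#' @inheritParams dg_to_ki
#' @return pKi (dimensionless).
#' @examples
#' dg_to_pki(-12.28)  # ~8.66 at 310 K
#' @export
dg_to_pki <- function(dg, const = thermo_constants()) {
  -log10(dg_to_ki(dg, const))
}

#' Least-squares correlation between experimental and calculated pKi
#'
#' Ordinary least squares of `y` on `x`; `r2` is the squared Pearson
#' correlation, identical to the OLS coefficient of determination for a
#' simple linear fit. Summaries round `r2` to 2 decimals.
#'
#' @param x Experimental pKi values.
#' @param y Calculated pKi values, same length, n >= 3.
#' @return A `zb_regression` list: `slope`, `intercept`, `r2`, `n`.
#' @export
pki_regression <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("n < 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = stats::cor(x, y)^2,
                 n = length(x)),
            class = "zb_regression")
}

#' @export
print.zb_regression <- function(x, ...) {
  cat(sprintf("pKi regression (n = %d): y = %.3f x + %.3f, R2 = %.2f\n",
              x$n, x$slope, x$intercept, round(x$r2, 2)))
  invisible(x)
}

#' Mean of a set of R-squared values
#'
#' @param values Non-empty numeric vector of R2 values.
#' @return Arithmetic mean (report to 2 decimals).
#' @export
average_r2 <- function(values) {
  if (!length(values)) stop("no R2 values", call. = FALSE)
  mean(values)
}

#' Pose-rank tally
#'
#' Counts of how often the correctly coordinated pose appeared at each rank
#' position of the docking output (plus `absent` when it never appeared).
#'
#' @param counts Named non-negative integer vector; names from
#'   `"1"`..`"4"`, `"absent"`.
#' @param total Total poses analyzed; defaults to `sum(counts)` and must
#'   equal it.
#' @return A `zb_pose_tally` list with `counts` and `total`.
#' @export
pose_tally <- function(counts, total = sum(counts)) {
  stopifnot(all(counts >= 0), total >= 1)
  if (!all(names(counts) %in% c(as.character(1:4), "absent")))
    stop("tally names must be \"1\"..\"4\" or \"absent\"", call. = FALSE)
  if (sum(counts) != total)
    stop("tally counts must sum to total", call. = FALSE)
  structure(list(counts = counts, total = total), class = "zb_pose_tally")
}

#' Percent pose accuracy
#'
#' The percentage of analyzed cases in which the correctly coordinated pose
#' ranked first.
#'
#' @param tally A `zb_pose_tally` from [pose_tally()].
#' @return Percent, rounded to 1 decimal.
#' @examples
#' pose_accuracy(pose_tally(c(`1` = 25, `2` = 1)))  # 96.2
#' @export
pose_accuracy <- function(tally) {
  stopifnot(inherits(tally, "zb_pose_tally"))
  if (tally$total < 1) stop("empty tally", call. = FALSE)
  first <- if ("1" %in% names(tally$counts)) tally$counts[["1"]] else 0
  round(100 * first / tally$total, 1)
}

#' Relative improvement between two percentages
#'
#' `100 * (a - b) / b`: how much larger `a` is than the baseline `b`, in
#' percent of the baseline.
#'
#' @param a Improved value (percent).
#' @param b Baseline value (percent); must be positive.
#' @return Percent, rounded to 1 decimal.
#' @export
relative_improvement <- function(a, b) {
  if (b <= 0) stop("baseline must be positive", call. = FALSE)
  round(100 * (a - b) / b, 1)
}

#' Masked in-place RMSD between two poses
#'
#' Root-mean-square deviation over heavy atoms paired by atom name, computed
#' in place (no superposition): the convention for docking poses, which share
#' the receptor coordinate frame with the reference. Atoms whose name or
#' serial appears in `exclude` are dropped before pairing, which is how a
#' solvent-exposed ligand portion with no receptor contacts is masked out of
#' the comparison.
#'
#' @param ref,pose `zb_structure` objects or atom data.frames of the same
#'   ligand; after exclusion their heavy-atom names must pair one-to-one.
#' @param exclude Character/integer vector of atom names or serials to drop
#'   from both structures.
#' @param superpose If `TRUE`, optimally superpose `pose` onto `ref`
#'   (Kabsch) before measuring; not the docking convention, off by default.
#' @return RMSD in Angstrom.
#' @export
masked_rmsd <- function(ref, pose, exclude = NULL, superpose = FALSE) {
  pick <- function(s) {
    a <- .atom_table(s)
    a <- a[toupper(a$element) != "H", , drop = FALSE]
    if (length(exclude))
      a <- a[!(a$name %in% as.character(exclude) |
                 a$serial %in% suppressWarnings(as.integer(exclude))), ,
             drop = FALSE]
    if (anyDuplicated(a$name))
      stop("duplicated atom names prevent unambiguous pairing: ",
           paste(unique(a$name[duplicated(a$name)]), collapse = ", "),
           call. = FALSE)
    a
  }
  a <- pick(ref); b <- pick(pose)
  orphans <- c(setdiff(a$name, b$name), setdiff(b$name, a$name))
  if (length(orphans))
    stop("unmatched atoms after exclusion: ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  if (!nrow(a)) stop("no atom pairs left after exclusion", call. = FALSE)
  b <- b[match(a$name, b$name), , drop = FALSE]
  P <- as.matrix(a[, c("x", "y", "z")])
  Q <- as.matrix(b[, c("x", "y", "z")])
  if (superpose) Q <- .kabsch(Q, P)
  sqrt(mean(rowSums((P - Q)^2)))
}

# Optimal rigid superposition of Q onto P (Kabsch, proper rotation).
.kabsch <- function(Q, P) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(Q, 2, cq), sweep(P, 2, cp))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(Q, 2, cq) %*% t(R), 2, cp, `+`)
}
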