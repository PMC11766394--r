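---
title: "Bias-guided docking of zinc metalloproteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-guided docking of zinc metalloproteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincbias)
```

## The problem

Zinc-dependent enzymes such as the histone deacetylases (HDACs) bind their
inhibitors through a zinc-binding group — for the clinically dominant HDAC
inhibitor class, a hydroxamic acid R–C(=O)–N(H)–OH that chelates the
catalytic Zn²⁺. Generic docking scoring functions parameterize zinc as a
bare divalent cation and miss the directional, partly covalent character
of the coordination bond. Two practical consequences follow: generated
poses often fail to chelate the metal the way every co-crystal structure
does, and the computed binding free energies rank ligands poorly against
experimental affinities.

Bias docking mitigates this by adding attractive potential wells ("bias
sites") at chosen coordinates, steering pose generation toward the
coordination geometry. That raises the question this package answers
computationally: *where* should the bias sites go, given only the apo
receptor structure?

## Vacant-axis model

Around a catalytic zinc, the protein contributes a fixed set of donor
atoms (in HDACs, histidine NE2 nitrogens and aspartate carboxylate
oxygens). Writing $\hat{u}_i$ for the unit vectors from the zinc to each
of the $n$ donors, the package models the ligand-accessible vacancy as

$$\hat{v} = -\frac{\sum_{i=1}^n \hat{u}_i}{\left\lVert\sum_{i=1}^n \hat{u}_i\right\rVert},$$

the direction opposite the resultant of the occupied positions. The rule
is parameter-free, deterministic, rotation/translation-equivariant, and
completes ideal polyhedra exactly: for three donors at tetrahedral
geometry $\hat{v}$ is the fourth vertex, at 109.471° from every donor. If
the occupied set is balanced (e.g. a perfect trans pair) the resultant
vanishes and no vacancy is defined; the operation then fails loudly
rather than guessing.

An alternative definition of the vacancy — the direction maximizing the
minimum angle to the occupied donors — coincides with the resultant rule
at ideal tetrahedral geometry in any orientation. The two diverge as the
donor *shape* distorts, at roughly 1.2× the distortion (measured against
a brute-force search over 10⁵ near-uniform sphere directions: maximum
divergence ≈1° at 1° per-donor distortion, ≈2.2° at 2°, ≈7° at 5°). The
test suite therefore checks tight (2°) agreement only for nearly ideal
shapes; away from ideality the resultant rule is the normative
definition, being smooth and unique where the max-min criterion develops
plateaus.

### Bias-site placement

Bias sites are placed at a Zn–acceptor bond length $L$ along $\hat{v}$:

- **monodentate** — one site at $\mathrm{Zn} + L\hat{v}$;
- **bidentate** (default) — two sites at
  $\mathrm{Zn} + L(\cos(\beta/2)\,\hat{v} \pm \sin(\beta/2)\,\hat{w})$,
  emulating the two hydroxamate oxygens.

Both sites are exactly $L$ from the zinc. $\hat{w}$, the in-plane
orientation of the chelating pair, is chosen perpendicular to $\hat{v}$
so as to bisect the largest angular gap among the donor directions
projected onto the plane normal to $\hat{v}$ — the O···O edge leans into
the most open region of the first shell. This selection rule is a package
invention needed to make bidentate placement deterministic; exact angular
ties (measure-zero in practice) are broken toward the candidate with
lexicographically smallest $(x, y, z)$, which sacrifices rotational
equivariance only on the tie set itself.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| detection cutoff | 2.6 | Å | first-shell Zn–N/O bonds run 1.9–2.3 Å; 2.6 adds margin without admitting the second shell |
| bond length $L$ | 2.1 | Å | center of the usual Zn–O coordination range |
| bite angle $\beta$ | 76 | ° | gives O···O = $2L\sin(\beta/2) \approx 2.59$ Å, the hydroxamate chelation bite |
| bias well depth (Vset) | −2.00 | kcal/mol | a moderately strong well; recorded in the output for provenance, tune per engine |
| bias radius | 0.8 | Å | localizes the well to the acceptor position |
| similar-population fraction | 0.9 | — | see energy extraction below |

All are exposed as function arguments and CLI flags; none is fitted to
data in this package.

Donor detection is purely geometric (element ∈ {N, O, S} within the
cutoff). HDAC zinc sites are variously described with two histidines and
one aspartate or one histidine and two aspartates; rather than arbitrate,
the detector reports the residues it finds and enforces nothing. Water
oxygens are excluded by default (receptors are prepared with waters
stripped), and a chain filter is available since multi-chain entries
usually get docked one chain at a time.

## Ligand preparation

In the active site the hydroxamic acid is deprotonated at the *hydroxyl
oxygen*, and the anionic hydroxamate is the species that chelates. The
package matches the substructure C(=O)–N–O(H) on the molecular graph (the
hydroxyl oxygen must be neutral and terminal, so an already deprotonated
N–[O⁻] no longer matches — re-application fails instead of silently
double-charging) and emits the canonical SMILES with the oxygen's proton
removed and formal charge −1. The N–H tautomer question from the
quantum-chemistry literature is deliberately not modeled: the O-anion is
the form used throughout. Multiple hydroxamic groups, if present, are all
deprotonated. Conformer generation, protonation of other groups at pH
7.4, and PDBQT conversion belong to the external docking pipeline and are
out of scope.

## Energy extraction and evaluation

A docking engine run with ~100 GA runs clusters its poses; re-running the
search does not reproduce individual poses, but the population structure
is stable. For reproducibility the representative binding free energy is
therefore the **mean binding energy of the most populated cluster**; when
several clusters have similar populations the means are averaged across
them. "Similar" is operationalized as a population ≥ 90% of the largest
cluster (exposed as `similar_frac`) — an exact-tie rule would almost
never trigger the averaging branch, while 90% captures genuinely
ambiguous clusterings. The average is unweighted.

Conversions use $K_i = e^{\Delta G/RT}$ with
R = 0.0019872036 kcal K⁻¹ mol⁻¹ and T = 310 K, yielding $K_i$ in molar
when ΔG is in kcal/mol; the nanomolar scale appears only at reporting.
This unit convention is forced by the embedded reference table, whose Ki
(nM) and pKi columns are mutually consistent under
$\mathrm{p}K_i = -\log_{10}(K_i\,[\mathrm{M}])$ for all 26 rows.

R² is the squared Pearson correlation (identical to the OLS coefficient
of determination for a simple linear fit), rounded to two decimals in
summaries. The series averages are taken over the per-isoform
two-decimal values, matching how such summaries are conventionally
quoted.

Masked RMSD is computed **in place** — poses and reference share the
receptor frame, so superposition would hide exactly the displacement
being measured (an optional Kabsch superposition exists behind a flag for
conformational comparisons). Pairing is by atom name over heavy atoms;
orphans are an error, which forces masks to be explicit. The mask
(`exclude`) is how a ligand portion dangling out of the catalytic site,
with no protein contacts, is omitted from a re-docking comparison. No
symmetry correction over equivalent-atom permutations is attempted.

## Embedded reference data and pose tallies

The package ships a 26-row table (10 HDAC2, 6 HDAC4, 10 HDAC8
ligand–isoform pairs) of experimental Ki with docking-derived pKi for
both protonation series, all activity values drawn from a single binding
assay so the correlations are biologically commensurable.
`reproduce_reference_stats()` recomputes from it the six per-isoform R²
values (deprotonated: 0.76/0.82/0.81; protonated: 0.58/0.69/0.75), the
series averages (0.80 vs 0.67), and — from the embedded pose tallies —
rank-1 accuracies of 96.2% vs 76.9% and a 25.1% relative improvement.
The tallies store the rank-1 counts (25/26 and 20/26, the only integer
counts consistent with those accuracies); the full rank distribution
beyond rank 1 is not published, so non-first poses are pooled at rank 2
and only the rank-1 fraction should be interpreted.

## Synthetic data: what it does and does not emulate

`make_zinc_site()` builds a zinc plus 2–5 donors on ideal tetrahedral,
trigonal-bipyramidal or vacancy-bearing octahedral frames, with donor
identities cycling His-NE2/His-NE2/Asp-OD1 and an optional angular jitter:
each donor direction is rotated by an angle drawn from N(0, σ) about a
uniformly random axis (Rodrigues), with σ the `angular_jitter` in
degrees. Because the axis component parallel to the donor direction is
inert, the realized displacement is |angle|·sin(axis, donor) — a mild,
isotropic perturbation under which the vacant-axis error over 100 seeds
at σ = 5° averages ≈4.2°, comfortably inside the ≤5° recovery tolerance
the generator is tested against. The manifest records the jitter-free
vacant axis as ground truth.

These fixtures exercise parsing, detection, geometry and round-trip
invariants. They do **not** emulate crystallographic reality: no
anisotropic coordinate error, no second-shell atoms, no alternate
conformations, no distorted five-coordinate sites with a bound water.
Passing tests on them demonstrates correctness of the geometric
machinery, not accuracy on real receptors. Likewise `make_dlg()` emits
only the clustering-histogram section of a docking log, enough to
validate the parser's column contract against real-dialect rows.

Problem sizes used by the test and acceptance runs — 10⁵ oracle
directions, 100 jittered fixtures, 26-row correlations — were chosen so
the whole suite completes in well under a minute while keeping
Monte-Carlo standard errors an order of magnitude below the tested
margins.

## Known limitations

- The vacant-axis rule presumes a single coherent vacancy; severely
  distorted or five-coordinate sites with near-balanced donors approach
  the degenerate error case.
- Bias well depth and radius defaults are engine-agnostic conventions,
  not fitted values; they should be tuned against re-docking RMSD for a
  new target class, which requires the external docking engine and is
  out of scope here.
- The reference-table correlations validate the *evaluation* pipeline;
  regenerating the underlying ΔG values, or re-docking RMSD tables,
  requires the full AutoDock toolchain and receptor structures and is
  not reproducible inside this package.
- PDB parsing is fixed-column PDB/PDBQT only (no mmCIF), matching the
  file formats the surrounding docking toolchain actually consumes.
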