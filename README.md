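# zincbias

Docking against zinc metalloenzymes — above all the histone deacetylases
(HDACs) — is notoriously unreliable with generic scoring functions: the
catalytic Zn²⁺ is treated as a bare divalent cation, so the coordination
bond between the metal and the ligand's zinc-binding group (ZBG) is scored
poorly, poses drift away from the chelating geometry seen in co-crystal
structures, and computed binding free energies correlate weakly with
experiment. `zincbias` supports a *bias-docking* workflow around this
problem, for computational chemists running AutoDock-style virtual screens
against HDACs and related zinc enzymes:

1. **Zinc-site detection.** Parse a receptor PDB/PDBQT and find each Zn
   with its protein coordination sphere (donor atoms N/O/S within a 2.6 Å
   cutoff, purely geometric — residue identities are reported, not
   assumed).
2. **Vacant-axis prediction and bias placement.** With the co-crystallized
   ligand removed, the occupied coordination unit vectors
   $\hat{u}_1,\dots,\hat{u}_n$ around the zinc leave a vacancy along

   $$\hat{v} \;=\; -\,\frac{\sum_i \hat{u}_i}{\lVert \sum_i \hat{u}_i \rVert},$$

   the direction pointing away from the mean of the occupied positions —
   for three donors at ideal tetrahedral geometry, exactly the fourth
   vertex (109.47° from each donor). Acceptor bias sites are placed at
   bond length 2.1 Å along $\hat{v}$ (monodentate) or as a symmetric pair
   at a 76° bite angle (bidentate, emulating hydroxamate O,O-chelation),
   and written as a bias parameter file (`x y z Vset r type`) for
   bias-capable docking engines.
3. **Ligand preparation.** Hydroxamic acids R–C(=O)–N(H)–OH are detected
   in SMILES input and O-deprotonated to the hydroxamate anion
   (N–O⁻), the form that chelates the zinc in the active site.
4. **Evaluation.** Docking-log clustering histograms are parsed and the
   *mean binding energy of the most populated cluster* is taken as the
   representative ΔG (averaging across clusters of similar population);
   ΔG is converted via $K_i = e^{\Delta G / RT}$
   (R = 0.0019872036 kcal K⁻¹ mol⁻¹, T = 310 K) and
   $\mathrm{p}K_i = -\log_{10} K_i$; calculated and experimental pKi are
   compared by least-squares regression (R²); pose-rank accuracy and
   masked in-place RMSD (no superposition, the docking-pose convention)
   complete the validation toolkit.

The package embeds a reference table of 26 ligand–isoform measurements
(hydroxamate inhibitors of HDAC2/4/8: experimental Ki plus docking-derived
pKi for the protonated and deprotonated ligand series) and synthetic
zinc-site / docking-log generators with known ground truth, so the entire
evaluation pipeline is testable offline.

## Worked example

```r
library(zincbias)

# a synthetic HDAC-like zinc site: 2 His NE2 + 1 Asp OD1 on a tetrahedron
fix <- make_zinc_site(seed = 1)
site <- find_zinc_sites(parse_structure(fix$pdb))[[1]]
site
#> Zinc site: serial 4, chain A, 3 ligating atom(s) within 2.60 A
#>   NE2  HIS  A10    2.099 A
#>   NE2  HIS  A20    2.099 A
#>   OD1  ASP  A30    2.099 A

cat(write_bpf(place_bias_sites(site)))
#> #x y z Vset r type
#> 8.517 8.517 9.900 -2.00 0.80 acc
#> 9.572 9.572 12.011 -2.00 0.80 acc

deprotonate_hydroxamic("CC(=O)NO")   # acetohydroxamic acid
#> [1] "[O-]NC(=O)C"

reproduce_reference_stats()
#> Embedded-table evaluation
#> -------------------------
#>   HDAC2  deprotonated R2 = 0.76  (n = 10)
#>   HDAC2  protonated   R2 = 0.58  (n = 10)
#>   HDAC4  deprotonated R2 = 0.82  (n = 6)
#>   HDAC4  protonated   R2 = 0.69  (n = 6)
#>   HDAC8  deprotonated R2 = 0.81  (n = 10)
#>   HDAC8  protonated   R2 = 0.75  (n = 10)
#>   average R2: deprotonated 0.80, protonated 0.67
#>   pose accuracy: deprotonated 96.2%, protonated 76.9%
#>   relative improvement: 25.1%
#>   reference table self-consistent: yes
```

The two bias-site lines are the acceptor positions a bias-docking engine
will reward, each exactly 2.1 Å from the zinc at a 76° mutual bite angle.
The final report shows that across all three isoforms the deprotonated
(hydroxamate) ligand series correlates better with experimental affinities
than the protonated series, and places the correctly zinc-coordinated pose
first far more often.

A command-line interface covering the same operations is installed as
`exec/zincbias` (`zincbias find-sites`, `predict-bias`, `deprotonate`,
`analyze-dlg`, `correlate`, `pose-stats`, `rmsd`, `synth`, `table`,
`reproduce`); run it without arguments for usage.

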