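Package: zincbias
Title: Bias-Guided Docking Toolkit for Zinc Metalloproteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for setting up and evaluating bias-guided docking against
    zinc metalloproteins such as histone deacetylases (HDACs). Detects zinc
    coordination sites in PDB/PDBQT structures, predicts the vacant
    coordination direction and places zinc-interaction bias sites written as
    bias parameter files, prepares O-deprotonated hydroxamate ligands from
    SMILES, parses docking-log clustering histograms and extracts a
    representative binding free energy, converts binding free energies to
    inhibition constants and pKi, and computes correlation, pose-rank and
    masked in-place RMSD statistics. Ships an embedded reference table of
    experimental and docking-derived pKi values for hydroxamate HDAC
    inhibitors, plus synthetic zinc-site and docking-log generators with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
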