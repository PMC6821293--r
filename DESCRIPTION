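Package: dzfit
Title: Geometric Catalytic-Strategy Analysis of RNA-Cleaving DNAzyme Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-frame geometric analysis of molecular-dynamics coordinate
    ensembles of small nucleolytic enzymes, developed around the 8-17 DNAzyme.
    Evaluates the four fundamental catalytic strategies for RNA cleavage by
    2'-O-transphosphorylation (in-line fitness alpha, phosphate charge
    stabilization beta, nucleophile activation gamma, leaving-group
    stabilization delta) as per-frame pass flags and graded 0-1 fitness
    scores, classifies the active state, clusters frames by active-site metal
    binding mode (sodium-only, lead-only, bridging-sodium plus lead), detects
    water- and sodium-mediated bridges and their occupancies, computes radial
    distribution functions with peak and coordination-number extraction, and
    bins ion densities on voxel grids. Includes a seeded synthetic
    active-site ensemble generator that plants known geometry, binding modes
    and occupancy fractions so every analysis stage is testable without
    trajectory data, plus readers for multi-model PDB files and a plain-text
    trajectory table format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
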