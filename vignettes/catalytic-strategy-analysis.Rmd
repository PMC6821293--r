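---
title: "Geometric catalytic-strategy analysis of DNAzyme ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric catalytic-strategy analysis of DNAzyme ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dzfit)
```

## The problem

The 8–17 DNAzyme cleaves an RNA substrate by 2′-*O*-transphosphorylation: the
2′-oxygen of the residue upstream of the scissile phosphate (numbered G–1
here) attacks the adjacent phosphorus, expelling the O5′ leaving group of
G+1. Whether a given conformational snapshot is *catalytically competent* is,
to a good approximation, a geometric question, conventionally decomposed into
four fundamental strategies:

* **α (in-line fitness)** — the nucleophile, scissile phosphorus and leaving
  group approach the near-linear arrangement required for associative attack;
* **β (phosphate charge stabilization)** — cationic charge neutralizes the
  non-bridging phosphoryl oxygens (NPOs, stereochemically pro-R~P~ and
  pro-S~P~);
* **γ (nucleophile activation)** — the 2′-OH proton is positioned for
  abstraction by the general base, the N1 of a conserved guanine (G13);
* **δ (leaving-group stabilization)** — developing negative charge on O5′ is
  stabilized by a metal ion directly, through its second solvation shell, or
  through a metal-bound water donating a hydrogen bond.

`dzfit` evaluates these strategies frame by frame over a coordinate ensemble
(multi-model PDB or the package's plain-text trajectory table), classifies
each frame's active-site metal binding mode, measures bridge occupancies and
radial distribution functions, and — because the microsecond trajectories
such analyses are normally run on are rarely shareable — ships a synthetic
ensemble generator that plants all of these observables with known ground
truth.

## Per-frame criteria and graded scores

Each strategy has a binary pass criterion and a graded score in [0, 1]. The
binary thresholds carry the quantitative weight (populations, occupancies);
the graded scores reproduce the darker-tone-is-fitter visual convention of
per-frame strategy plots and are deliberately simple linear ramps.

| quantity | pass threshold (inclusive) | score ramp (0 → 1) |
|---|---|---|
| α: d(O2′···P) | ≤ 3.5 Å | 3.5 Å → 3.0 Å |
| α: ∠O2′–P–O5′ | ≥ 140° | 140° → 180° |
| γ: d(HO2′···G13:N1) | ≤ 2.2 Å | 2.2 Å → 1.8 Å |
| β: ion–NPO contact | ≤ inner-shell cutoff | cutoff → 2.0 Å |
| δ: ion–O5′ | first shell ≤ cutoff; second ≤ 5.6 Å | step: 1 / 0.5 |
| δ: Pb-water H···O5′ | ≤ 2.2 Å | step: 0.75 |

The two α ramps multiply. A frame is **active** when α and γ pass
simultaneously; activity is undefined for deprotonated-nucleophile ensembles
(no HO2′ atom), which is why `build_site_map()` accepts `gamma = FALSE` and
the pipeline then skips the population summary rather than guessing.

Notes on the choices embedded here:

* Thresholds are *inclusive* and ramps are zero at the threshold, so a frame
  exactly at 3.5 Å / 140° / 2.2 Å passes with score 0. This is the one place
  where "pass" and "score > 0" disagree, and it is intentional: populations
  must count boundary frames, while the visual gradation should not reward
  them.
* Hydrogen bonds are distance-only criteria on the H···acceptor distance, no
  angle term. The γ criterion is printed that way, and we keep one H-bond
  convention everywhere rather than mixing conventions across analyses.
* Inner-sphere cutoffs default to Na–O 3.1 Å and Pb–O 3.0 Å — the
  conventional first-minimum positions of these ion–oxygen RDFs — and the
  second shell ends at 5.6 Å. These are `fitness_params()` arguments, not
  constants, because first-minimum positions drift with force field and
  water model.
* The δ score weights (1 / 0.75 / 0.5) are presentation-layer only; no
  statistic in the package depends on them.

## Binding modes and bridges

Frames are clustered by the metal content of the active site:

* `NA_ONLY` — the system contains no Pb²⁺ at all (a separate simulation
  condition, and therefore a separate topology);
* `PB_ONLY` — Pb²⁺ in the site, no bridging Na⁺;
* `NA_BRIDGE_PB` — Pb²⁺ in the site plus a Na⁺ making simultaneous
  inner-sphere contact with O2′ and pro-R~P~ (the bridging ion that couples
  nucleophile positioning to in-line geometry);
* `OTHER` — Pb²⁺ present but outside the site.

"In the site" has no printed definition, so we define it explicitly: within
`second_shell_max` of any role in `site_roles` (default pro-R~P~, pro-S~P~,
O5′, G6:O6). When several Na⁺ qualify as bridging, the one minimizing the
larger of its two contact distances wins, ties broken by atom index — a
deterministic rule so reruns agree bit for bit.

`detect_bridge()` finds water- or Na⁺-mediated bridges between two named
sites (default G13:O6 and pro-S~P~). A water bridge requires a hydrogen
within the H-bond cutoff of each endpoint (donor geometry on both sides); a
Na bridge requires the ion inner-sphere to both. When both exist the ion is
reported, since an inner-sphere ion contact is the stronger interaction.
`occupancy()` is the plain event fraction over frames.

## Radial distribution functions

`compute_rdf()` histograms minimum-image reference–target distances in
uniform bins (default 0.05 Å) and normalizes by the ideal-gas expectation:

$$g_k = \frac{C_k}{n_\mathrm{frames}\, n_\mathrm{ref}\, \rho\, V_k},
\qquad V_k = \tfrac{4}{3}\pi\,(r_k^3 - r_{k-1}^3),$$

with ρ the per-frame target density n/V averaged over frames, so
constant-pressure ensembles with fluctuating volume are handled; the density
is per selection (per reference set), not global. `r_max` may not exceed
half the smallest perpendicular cell width — beyond that the minimum-image
convention is ill-defined. Peaks are reported at bin centres
(`first_peak()`, first local maximum above `min_g = 1`, requiring a strict
rise into the bin so flat curves have no peak); bin-centre precision is
finer than the 0.1 Å at which shell positions are conventionally quoted.
`coordination_number()` integrates ρ g(r) dV up to a cutoff.
`residue_averaged_rdf()` implements the background-vs-specific-site split:
rank per-residue curves by their global maximum, set the top `n_exclude`
aside (those are the specific binding pockets, reported by id), and average
the rest.

## The synthetic generator

The generator exists because the analyses' natural inputs — microsecond MD
ensembles — are not reproducible at desk scale. It emulates exactly the
observables the analyses measure, with ground truth:

* a fixed 10-atom active-site scaffold holding every named role (scissile
  phosphate with tetrahedral P–O geometry at 1.48/1.60 Å, nucleophile pair,
  G13 N1/O6, G6 O6/N7), centred in an orthorhombic box (30 Å default);
* per-frame scalar draws (truncated normals) for the α/γ geometry and every
  planted contact distance, realized *exactly* in 3D: the nucleophile is
  placed at the drawn distance and in-line angle, the bridging Na⁺ on the
  two-sphere intersection satisfying both of its drawn contacts, the Pb²⁺
  radially off pro-R~P~ or on a two-sphere locus when a Pb–O5′ distance is
  also specified, bridge and Pb-bound waters likewise;
* mixtures of such states with largest-remainder allocation of frame counts,
  so a noise-free mixture planted at 56% active is recovered at exactly 56%
  at any n;
* ground-truth labels computed from the scalar draws against the default
  thresholds — *not* from the realized coordinates. Agreement between the
  two is precisely what the fidelity tests quantify.

The default study conditions (`gb_minus_specs()`, `na_only_specs()`) encode
the deprotonated-general-base system: binding-mode shares proportional to
the reported trajectory durations (bridged cluster 1.5 µs vs 0.49 µs
Pb-only, with a 1 µs Na-only companion), active fractions of 56%, ~1% and
0.5% within the bridged, Pb-only and Na-only modes, inner-sphere contacts at
2.4–2.5 Å, and the G13:O6/pro-S~P~ solvent bridge at 70% occupancy in the
bridged states. Active-state geometry draws sit several σ inside the
thresholds (3.15 ± 0.08 Å, 162 ± 6°, 1.95 ± 0.08 Å) and inactive draws are
truncated outside them, so planted labels are crossed only with ~10⁻³ tail
probability.

What the generator does **not** emulate — and therefore what passing tests
do and do not show: there is no force field, no dynamics (frames are i.i.d.,
so no autocorrelation, residence times or exchange kinetics), no solvent
structure beyond the planted motifs (bulk waters and territorial ions are
uniform with a 4 Å clearance from the site), and no conformational coupling
beyond what is planted. Tests passing on this generator demonstrate that the
*measurement machinery* is correct — that planted geometry, modes and
occupancies are recovered at the planted rates — not that any real ensemble
has those properties.

## Numerical choices

* Threshold comparisons carry a 10⁻⁹ guard so frames constructed exactly at
  a printed threshold classify inclusively despite trigonometric round-off;
  RDF binning uses the same epsilon so a pair at an exact bin edge lands in
  the upper bin.
* The nucleophile's azimuth about the P–O5′ axis is a free nuisance
  parameter; it is re-drawn jointly with the bridging-Na placement until the
  two-sphere intersection is feasible (bounded retries, then an error naming
  the constraint). Planted motifs keep a 2 Å steric clearance from
  scaffold atoms they do not coordinate; without it the random azimuth
  occasionally parked the bridging ion on top of pro-S~P~, an unphysical
  overlap visible as a spurious g(r) spike at 0.2 Å.
* All tabular output is fixed-precision text (4 decimals for Ångström and
  scores, 0.1% for percentages, 4 decimals in the trajectory table), so
  reruns under one seed are byte-identical and diffs are meaningful.
* Degenerate inputs fail loudly and early: inconsistent model sizes name the
  model, malformed atom rows name the line or frame, unresolved or ambiguous
  roles name the role, zero-volume cells and oversized `r_max` are errors,
  and `run_analyze()` validates every input's site map before computing
  anything, removing partial outputs on failure.

## Problem sizes

The bundled drivers (`analysis/01_simulate.R` … `03_rdf.R`) use 4,000 +
2,000 frames, enough to resolve the planted percentages to a few tenths of a
point; the recovery tests and the acceptance script use 10,000 + 5,000
frames, where the 99% binomial interval around a planted 56% is about
±1.3 points. Pooling across ensembles is frame-weighted, with per-source
rows retained so any other weighting is recoverable.

## Known limitations

* The atom-naming dialect for the NPOs (OP1/OP2 vs O1P/O2P, and which is
  pro-R) must be stated in the site-naming config; the package never infers
  stereochemistry from coordinates.
* Hydrogen-bond criteria are distance-only by design; systems where angular
  criteria matter need stricter cutoffs.
* The δ "second shell" uses a single global cutoff rather than an
  RDF-derived per-state cutoff.
* The PDB writer is a pass-through for synthetic ensembles (orthorhombic
  cells only); binary MD formats are out of scope — convert upstream to
  multi-model PDB or the trajectory table.
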