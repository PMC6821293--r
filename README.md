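# dzfit — geometric catalytic-strategy analysis of DNAzyme ensembles

`dzfit` is an R package for per-frame geometric analysis of molecular-dynamics
coordinate ensembles of small nucleolytic enzymes, built around the
RNA-cleaving 8–17 DNAzyme. For every frame of an ensemble it scores the four
fundamental catalytic strategies of 2′-*O*-transphosphorylation:

- **α, in-line fitness** — pass iff d(O2′···P) ≤ 3.5 Å and ∠O2′–P–O5′ ≥ 140°;
- **β, NPO charge stabilization** — pass iff a metal ion (Na⁺/Pb²⁺) makes an
  inner-sphere contact (Na–O ≤ 3.1 Å, Pb–O ≤ 3.0 Å) with a non-bridging
  phosphoryl oxygen;
- **γ, nucleophile activation** — pass iff d(HO2′···G13:N1) ≤ 2.2 Å;
- **δ, leaving-group stabilization** — first/second solvation-shell metal
  coordination of O5′ (≤ inner shell / ≤ 5.6 Å), or a Pb-bound water donating
  a hydrogen bond to O5′ (H···O5′ ≤ 2.2 Å);

each with a graded 0–1 fitness score (linear ramps from threshold to an ideal
value). A frame is **active** when α and γ hold simultaneously. On top of the
per-frame flags the package provides:

- binding-mode clustering of frames into `NA_ONLY` / `PB_ONLY` /
  `NA_BRIDGE_PB` (Pb²⁺ plus a Na⁺ bridging O2′ and pro-R_P) / `OTHER`, with
  active-state populations per mode;
- water/Na⁺ bridge detection between named sites (default G13:O6 ↔ pro-S_P)
  and occupancy statistics;
- radial distribution functions g(r) (0.05 Å bins, minimum-image, periodic
  triclinic cells), first-peak and coordination-number extraction, and
  residue-averaged curves with the dominant binding sites excluded;
- ion density grids around the active site;
- readers for multi-model PDB and a plain-text trajectory table, and a
  deterministic TSV report set (`run_analyze()`);
- a seeded **synthetic active-site ensemble generator** (`generate_ensemble()`
  and the `gb_minus_specs()` / `na_only_specs()` study conditions) that plants
  known in-line geometry, binding modes, shell distances and occupancy
  fractions, so the whole pipeline is testable without trajectory data.

## Worked example

```r
library(dzfit)

# two study-condition ensembles: deprotonated general base with the
# active-site Pb2+, and the sodium-only companion system
run_simulate(gb_minus_specs(), 4000, seed = 2026, out_dir = "results/ensembles/gb_pb")
run_simulate(na_only_specs(), 2000, seed = 2027, out_dir = "results/ensembles/na_only")

res <- run_analyze(list(
  inputs  = c("results/ensembles/gb_pb", "results/ensembles/na_only"),
  out_dir = "results/analysis"))
read_tsv(res$population_summary)
```

```
        label n_frames n_active active_fraction_pct
 NA_BRIDGE_PB     3015     1686                55.9
      NA_ONLY     2000       10                 0.5
      PB_ONLY      985       10                 1.0
          ALL     6000     1706                28.4
```

The population summary reads: of the 3015 frames in which a Na⁺ ion bridges
the O2′ nucleophile and the pro-R_P oxygen alongside the site-bound Pb²⁺,
55.9% are in the active state; frames with Pb²⁺ but no bridging ion are
active 1.0% of the time, and frames of the Pb-free system 0.5% — the
generator's planted fractions (56% / 1% / 0.5%), recovered by the full
file-based pipeline. The occupancy table from the same run reports the
G13:O6 ↔ pro-S_P solvent bridge in 57.5% of all with-Pb frames (the planted
mixture of 70% occupancy in the bridged states and 20% elsewhere), and the
Na⁺ g(r) around both O2′ and pro-R_P peaks at 2.375 Å (bin centre; planted
contact 2.4 Å) with an inner-sphere coordination number of 1.0:

```
Na+ g(r) first peaks (bridged frames), bin 0.05 A:
  O2p    r = 2.375 A (g = 301.2), N(3.1 A) = 1.00
  proRP  r = 2.375 A (g = 291.1), N(3.1 A) = 1.00
```

The numbered scripts under `analysis/` run this workflow end to end
(`01_simulate.R`, `02_analyze.R`, `03_rdf.R`), writing their tables under
`results/`.

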