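---
title: "Quantifying hydrophobic gating: methods and design notes"
author: "hydrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hydrophobic gating: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrogate)
```

## Scope

hydrogate implements the quantitative layer of a hydrophobic-gating study
of a hexameric ion channel (the CRAC channel subunit Orai1 is the model
system; residue numbers and helix ranges follow human Orai1 numbering).
It covers five analysis families — pore geometry, pore and back-pore
hydration, side-chain/helix conformation descriptors, sequence hydropathy,
and microscopy quantification (three-cube FRET, NFAT translocation) — plus
seeded synthetic-data generators that plant known ground truth for every
stage. Molecular-dynamics production, homology modelling and image
segmentation are out of scope: trajectory frames, sequences and region
masks are inputs.

Throughout, the membrane plane is xy, the pore axis is z, and "projected
in the plane of the membrane" means dropping the z component. Residue
ranges are inclusive; the helix presets are TM1 = 80–110, TM2 = 120–150,
TM3 = 170–195 and TM4 = 235–262, with a narrower TM3 fitting preset
(`TM3_FIT` = 179–185) kept separately because display selections and
RMSD-fit selections use different TM3 ranges; both are preserved as named
presets rather than reconciled.

## Pore centre and pore-radius profile

The pore centre is the arithmetic mean of the Cα atoms of residues 80–110
(the pore-lining TM1 ring of all six subunits). The pore-radius profile
follows the HOLE idea: in each 1 Å slice along z, the radius is that of
the largest sphere centred in the slice that touches no atom's van der
Waals surface,

$$ r(z_k) \;=\; \max_{c \in \mathbb{R}^2} \; \min_i \;
   \big( \lVert (c, z_k) - x_i \rVert - r^{\mathrm{vdw}}_i \big), $$

with atoms considered for a slice when $|z_i - z_k| \le r^{\mathrm{vdw}}_i
+ 3$ Å. Van der Waals radii come from a Bondi-type element table
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å), overridable in
`read_structure()`.

Two deliberate departures from the original HOLE implementation:

* **Deterministic optimisation.** HOLE's Monte Carlo annealing is replaced
  by Nelder–Mead ascent on the maximin objective, seeded per slice from
  the previous slice's centre (the first slice from the pore-centre xy).
  The search is run over the *displacement* from the seed so the initial
  simplex has a fixed absolute size; a single restart from the first
  optimum guards against premature simplex collapse. The objective is
  piecewise smooth and concave inside a ring of atoms, so a local
  optimiser suffices; tests verify it against an exhaustive 0.05 Å grid
  search. Determinism and testability motivated the substitution; exact
  numerical agreement with published HOLE curves is not a target since
  HOLE's probe parameters and axis definition for the original figures
  are unstated.
* **Reported as-is.** Sterically blocked slices yield negative radii and
  are reported unchanged; slices with no nearby atoms are `NA` (flagged
  missing), not errors.

With `optimize_center = FALSE` the probe stays on the pore axis; the fixed
centre radius is then a lower bound on the optimised one (a property the
tests assert). Replica aggregation time-averages per replica and reports
the cross-replica mean with the standard deviation of the mean
(sample SD across replica means divided by $\sqrt{n_\text{replicas}}$),
the error bar convention used for all replica-aggregated quantities here.

## Hydration

Waters are recognised by residue name (HOH, SOL, TIP3, WAT) and oxygen
atom name (O, OW, OH2); hydrogens are never required. Two observables:

* **Axial histograms** count water oxygens inside a vertical cylinder
  through the per-frame pore centre — radius 10 Å for the conducting
  pore, 30 Å when the back pores (the hydrated crevices at the TM
  interfaces outside the conducting pathway) are included — binned by z
  relative to the pore-centre z.
* **Shell counts** are the number of water oxygens within 6 Å of the Cα
  of a chosen residue (default 181, the TM3/TM4-interface position),
  per frame and subunit. The per-channel figure is the sum over the six
  subunit shells per frame; a water lying in two shells is counted in
  both, which the source analysis does not address — at 20 Å between
  neighbouring shell centres overlap is geometrically impossible anyway.

Distance and ratio boundaries are inclusive (`<=`), fixed for determinism
where the verbal description ("around 6 Å") leaves it open. The histogram
is exactly conservative: its bin sum equals `count_waters_in_cylinder()`
for the same cylinder and z extent, per frame. The analysis window
defaults to all frames; the study convention of using the final 50 ns is
expressed as `last_ns = 50`. Whether pooled-subunit or per-channel
reductions were used for the published count distributions is unstated,
so both are reported (`frequency` pools subunits; `per_channel_mean`
sums them).

## Conformation descriptors

* **Rotation angle** — the angle between two xy-projected vectors, both
  anchored at the residue's Cα: Cα→Cγ (side chain) and Cα→pore-centre.
  The verbal definition is directionally ambiguous about which atom the
  pore vector starts from; anchoring both at Cα makes 0° mean "side chain
  points at the pore", consistent with reading distributions shifted to
  low angles as reorientation toward the pore. Values are in [0°, 180°];
  degenerate projections (vector length < 1e-6 Å) are flagged `NA`.
* **Moiety distance** — xy-plane distance from the pore centre to the
  geometric centre of a residue's charge-carrying group. The chemical
  groups are named in the field's terms; the atom-name presets are our
  choice: Lys NZ; Arg guanidinium CZ/NH1/NH2/NE; Glu CD/OE1/OE2 (and Asp
  CG/OD1/OD2 by analogy). Explicit atom sets override the presets.
* **Triangle area** — full 3-D area of the Cα triangle of residues
  143/177/253 (TM2/TM3/TM4 packing at the peripheral interface),
  $\tfrac12\lVert (B-A)\times(C-A)\rVert$.
* **Torsions** — IUPAC-signed dihedrals in (−180°, 180°], cis = 0;
  cross-checked against bio3d's torsion implementation.
* **Kabsch RMSD** — optimal rigid superposition (SVD, reflections
  excluded) of a fit selection, RMSD measured over a possibly different
  selection after applying the transform. Fitted RMSD never exceeds
  unfitted RMSD and the operation is symmetric; both are asserted in
  tests, along with agreement with a direct numerical optimiser over
  rigid motions.

No periodic-boundary imaging is applied: frames are assumed whole-molecule
imaged, as produced by standard trajectory post-processing.

## Hydropathy profiles

`hydropathy_profile()` computes a centred, unweighted sliding-window mean
of per-residue hydropathy values; window lengths of 9–25 residues are the
intended range (odd, window 1 allowed as an explicit per-residue lookup).
Termini shorter than half a window carry no score — no padding, since the
edge handling of the original profiles is unspecified and padding would
fabricate values. The bundled scale is Roseman's (1988) side-chain
hydrophobicity scale as distributed in ProtScale; the original analysis
cites the scale without reprinting values, so tests of the profile
arithmetic use a toy scale and are independent of the bundled numbers.
The profile is linear in the scale, and a single substitution perturbs
exactly `window` consecutive outputs by (Δscale)/window — both are
asserted as properties.

## Imaging quantification

The apparent sensitized-emission FRET efficiency is computed pixel-wise as

$$ E_\text{app} = \frac{I_\text{FRET} - a\,I_\text{YFP} - b\,I_\text{CFP}}
   {I_\text{FRET} - a\,I_\text{YFP} + (G - b)\,I_\text{CFP}}, $$

where $a$ (YFP cross-excitation) and $b$ (CFP crosstalk) are
per-measurement-day calibration factors from single-fluorophore samples
and $G$ is the dimensionless instrument constant, default 2.75.
Analysis is restricted to pixels whose CFP:YFP ratio lies between 0.1:10
and 10:0.1, i.e. $I_\text{CFP}/I_\text{YFP} \in [0.01, 100]$; the bounds
are taken inclusive since "between" is ambiguous. Background subtraction
clamps at zero; pixels with a negative numerator keep their negative
$E_\text{app}$ in the map as a diagnostic but are excluded from summary
means. Zero denominators are flagged invalid, never errors. Whether
published per-cell summaries were pixel means or medians is unstated, so
both are exposed with mean as the default.

NFAT translocation is scored from background-subtracted nucleus/cytosol
mean-intensity ratios with three populations: inactive (< 0.85),
homogeneous (0.85–1.15, boundaries included, matching the printed closed
range) and active (> 1.15). The categories partition the positive ratios;
the headline statistic is the active fraction.

## Synthetic ground truth

The generators define the conditions every recovery test runs under; they
are parameters of record, not tuning knobs.

* `build_channel()` emulates the hexamer as four concentric rings of Cα
  pseudo-atoms (radii 8/14/20/26 Å, spanning z = ±15 Å) carrying the
  TM1–TM4 residue numbering, so all named selections resolve and the
  pore centre sits at the origin by symmetry. The Cγ of residue 181 is
  placed 1.5 Å from its Cα in the xy-plane at a von Mises-distributed
  angle from the pore direction (sampled per frame, subunit and replica
  with a built-in Best–Fisher sampler); defaults μ = 60°, κ = 8. Waters
  are homogeneous Poisson point processes per region: bulk-like
  0.0334 Å⁻³ in the 10 Å pore cylinder and 0.00332 Å⁻³ in the 6 Å shells
  around the Cα of residue 181 (≈18 waters per channel, the
  hydrated-state figure). Three replicas of 25 frames spanning 50 ns
  mirror the replica/window conventions. Because a trajectory requires a
  constant atom count, per-frame Poisson draws are padded up to the
  replica maximum with reservoir waters parked 100 Å above the channel,
  outside every analysis region. Poisson placement is the weakest
  assumption that still validates the counting and binning machinery;
  real trajectory waters are correlated in space and time, so passing
  recovery tests validates the measurement code, not any claim about
  water structure.
* `make_fret_images()` inverts the efficiency equation: inside cell $i$,
  $I_\text{CFP} = D(1 - E_i)$ (donor quenching), $I_\text{YFP} = A$, and
  $I_\text{FRET} = a I_\text{YFP} + b I_\text{CFP} + G E_i/(1-E_i)\,
  I_\text{CFP}$, plus background and optional Poisson shot noise, so the
  analysis pipeline recovers the planted $E_i$ exactly when noise-free
  and within ±0.02 at the 1,000-count level. No optics model (PSF,
  vignetting) is simulated.
* `make_nfat_population()` plants nucleus/cytosol ratios on disk cells
  with inner-disk nuclei; noise-free recovery is exact.

Every generator returns its ground truth alongside the data; recovery
tests compare against the returned truth, never against values re-derived
from the generated artifact. Identical spec and seed give bit-identical
output.

## Numerical choices and problem sizes

Slice thickness and bin width default to 1 Å; angle histograms default to
5° bins and count histograms to 1-unit bins (the original binning is
unstated). The slice optimiser uses a relative tolerance of 1e-10 with a
restart, giving centre recovery to ~1e-9 Å on analytic geometry — well
inside the 1e-3 Å contract. The test and acceptance workloads use sizes
chosen to make stochastic checks sharp but cheap: 50 random frames of up
to 2,000 waters for the neighbour-count oracle, 100 frames for
Poisson-density recovery (3σ bin-wise), 540 samples for von Mises
orientation recovery (circular mean within 2°), 100 random perturbations
for Kabsch properties, and 100-cell populations for category-fraction
recovery. PDB I/O goes through bio3d and is exact to the format's fixed
width (1e-3 Å).

## Worked example

```{r example}
ch <- build_channel(channel_spec(n_frames = 10, n_replicas = 3, seed = 1))
sh <- shell_count_distribution(ch$trajectories, residue = 181, cutoff = 6)
sh

ring <- md_frame(ring_atoms(12, 8.0), time = 0)
pore_radius_profile(ring, z_range = c(-0.5, 0.5), dz = 1)$radius
```

## Known limitations

* No GROMACS binary formats (XTC/TRR); frames enter as multi-MODEL PDB or
  XYZ. No topology or bond perception.
* The pore axis is the vertical line through the per-frame pore centre,
  not a fitted curvilinear axis; strongly tilted pores would need the
  latter.
* No water-dipole, hydrogen-bond or free-energy analyses; no cation–π
  detection beyond generic group distances; no cell segmentation (masks
  are inputs).
* The recognised water-name set is a superset of common conventions; an
  exotic water model would need an explicit rename.
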