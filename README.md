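# hydrogate

Quantitative analysis of hydrophobic gating in hexameric ion channels.

Ca²⁺ release-activated Ca²⁺ (CRAC) channels built from Orai1 hexamers can
be locked open or shut by single mutations at the TM3/TM4 helix interface.
Deciding *why* requires a battery of measurements on simulation frames and
microscopy images: how wide is the pore along its axis, how wet is the
conducting pathway and the peripheral "back pores", which way do the
mutated side chains point, how hydrophobic is the helix sequence, does the
channel couple to its activator (FRET) and does downstream signalling fire
(NFAT translocation)? hydrogate packages those measurements — with a
synthetic ground-truth generator for every stage — for structural
biologists and channel physiologists who want the analysis layer without
the original one-off scripts.

## What it computes

* **Pore-radius profile** (HOLE-style): per 1 Å slice along the pore axis,
  the largest probe sphere not overlapping any van der Waals surface,
  `r(z) = max_c min_i (||(c, z) − x_i|| − r_vdw,i)`, with a deterministic
  per-slice centre optimiser instead of Monte Carlo annealing. The pore
  centre is the geometric centre of the Cα atoms of residues 80–110.
* **Hydration**: axial water-oxygen histograms inside pore-centred
  cylinders (10 Å conducting pore, 30 Å including back pores) and water
  counts within 6 Å shells around a residue's Cα (default 181), with
  replica aggregation (mean ± SD of the mean over replicas).
* **Conformation**: xy-projected side-chain rotation angle (Cα→Cγ vs
  Cα→pore-centre; 0° = pointing at the pore), in-plane charged-moiety
  distance from the pore centre, Cα triangle areas (143/177/253), IUPAC
  torsions, and Kabsch-superposed per-helix RMSD (TM presets included).
* **Hydropathy**: centred sliding-window profiles on the bundled Roseman
  scale (windows 9–25) and mutant-minus-wild-type deltas.
* **Imaging**: pixel-wise three-cube FRET efficiency
  `E_app = (I_FRET − a·I_YFP − b·I_CFP) / (I_FRET − a·I_YFP + (G − b)·I_CFP)`
  with ratio gating (CFP:YFP between 0.1:10 and 10:0.1) and background
  subtraction, plus NFAT nucleus/cytosol scoring (inactive < 0.85,
  homogeneous 0.85–1.15, active > 1.15).
* **Synthetic data**: seeded generators for pseudo-hexameric channels
  (planted water densities, planted von Mises side-chain orientations)
  and microscopy images (planted efficiencies, bleed-through and
  translocation ratios), each returning its ground truth.

Inputs are multi-MODEL PDB or XYZ frames, FASTA sequences and grayscale
TIFF rasters; outputs are CSV/JSON tables plus base-graphics plot methods.
A command-line launcher (`inst/exec/hydrogate`) exposes everything as
subcommands (`pore-profile`, `hydration`, `geometry`, `hydropathy`,
`fret`, `nfat`, `simulate`) and writes a JSON run manifest with input
digests and the seed next to every output.

## Worked example

```r
library(hydrogate)

# a synthetic hexamer: 3 replicas x 10 frames, default (hydrated-state)
# water densities, planted side-chain orientations at 60 degrees
ch <- build_channel(channel_spec(n_frames = 10, n_replicas = 3, seed = 1))

shell_count_distribution(ch$trajectories, residue = 181, cutoff = 6)
#> <shell_count_distribution> CA of residue 181, cutoff 6 A: 180 samples,
#>   mean 2.91 waters/shell, 17.47 waters/channel

# analytic ring channel: 12 carbons at 8.0 A -> slice radius 8.0 - 1.7
ring <- md_frame(ring_atoms(12, 8.0), time = 0)
pore_radius_profile(ring, z_range = c(-0.5, 0.5), dz = 1)$radius
#> [1] 6.3

series_over_trajectory(ch$trajectories[[1]], "rotation_angle", residue = 181)
#> <descriptor_series> rotation_angle [deg]: 1 replicas, 60 pooled values, mean 62.07

fret_eapp(300, 500, 200, fret_calibration(a = 0.1, b = 0.5, G = 2.75))
#> [1] 0.2142857

nfat_summarize(c(0.5, 0.9, 1.0, 1.5))
#> <nfat_summary> 4 cells: inactive 25.0%, homogeneous 50.0%, active 25.0%
```

The shell summary says the planted back-pore hydration (~18 waters per
channel summed over the six subunit shells) is recovered; the ring radius
matches the analytic value `8.0 − 1.7 = 6.3` Å; the rotation-angle series
recovers the planted 60° orientation; the FRET example evaluates the
efficiency equation at `G = 2.75`; and the NFAT summary counts one
inactive, two homogeneous and one active cell.

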