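---
title: "Methods: hydrophobicity, shift analytics and interface ranking for TM helix dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrophobicity, shift analytics and interface ranking for TM helix dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixdimer)
```

helixdimer analyses the transmembrane (TM) and membrane-proximal parts of
single-pass receptors studied by solution NMR in membrane mimetics
(micelles, bicelles). Its running example is the human TLR4 TM helix and
its juxtamembrane hydrophobic region (HR), but every function takes plain
sequences, shift tables and coordinates. This vignette records the models
implemented, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## Whole-residue hydrophobicity

Segment hydrophobicity is the sum of Wimley–White whole-residue
water-to-octanol transfer free energies (kcal/mol). The default charge
convention — histidine neutral (0.11 kcal/mol), Asp/Glu/Lys/Arg charged —
is the one that reproduces the published juxtamembrane table shipped as
`tlr_jm_segments()`; `hydro_scale()` exposes charged His and neutral
Asp/Glu as alternatives. Internal arithmetic is kept at full precision and
only printing rounds to two decimals. Two reference rows (TLR1, TLR9)
disagree with the scale sum by 0.02 and 0.30 kcal/mol under every charge
convention we tried; they are kept in the table, flagged
`scale_consistent = FALSE`, and treated as probable typographic errors.
The reference table also spells the TLR4 HR segment `KFYFHLMLLAGCI` while
the expression construct reads `...KFYFHLLMLAGCI...`; the two are
composition-identical permutations, so all hydrophobicity sums agree, and
we record the discrepancy without resolving it.

`extract_post_tm_segment()` implements the "first 11–16 residues after the
TM domain, until the first polar residue" rule. Applied literally the
polar stop contradicts the segments it is meant to produce (they contain
internal K, D and G), so the stop is only applied beyond `min_len`
(default 11) and the segment is capped at `max_len` (default 16); the
polar set and both lengths are arguments, and explicit ranges always
override.

## Chemical-shift analytics

*Generalized methyl CSP.* `generalized_csp()` combines proton and carbon
changes as `sqrt(ddH^2 + ddC^2/16)` (ppm). Classification uses strict
inequalities — perturbations *exceeding* 0.02 ppm are `strong` (interface
candidates), values in (0.01, 0.02] are `weak`, a value exactly at a
threshold falls in the lower class. A residue's class is the maximum over
its methyl groups. Missing carbon shifts give a proton-only perturbation
with an explicit `h_only` flag, never silently.

*Secondary shifts and helix calling.* Secondary Cα shifts are observed
minus random-coil reference (Wishart-compilation values shipped as
`random_coil_ca()`); no sequence-neighbour or temperature corrections are
applied, which is adequate for helix/coil discrimination but not for
quantitative structure work. The helix caller reports maximal runs with
ΔδCα > 0.7 ppm of at least 4 residues, bridging single unobserved
residues. These three thresholds are not experimental constants; they were
chosen once so that a clean 33-residue helical stretch is called stably,
and all are arguments.

*Titration.* The pH dependence of a titrating group's shift follows the
Hill model `delta(pH) = (delta_a + delta_b 10^(n(pKa-pH))) / (1 +
10^(n(pKa-pH)))`. Note the algebra: `delta_b` is the limiting shift at low
pH (protonated side chain) and `delta_a` at high pH, and the value at
`pH = pKa` is their mean for any `n`. Fitting is nonlinear least squares
(Levenberg–Marquardt) with a deterministic initialization: for each pKa on
a coarse grid (4–9, step 0.5, plus the data midpoint) with `n = 1` the two
plateaus are solved by linear least squares (the model is linear in them),
and the best grid point seeds the full fit. Standard errors come from the
fit covariance. Fits with plateau separation below three times the noise
estimate are rejected as degenerate rather than returned with meaningless
parameters; at least 5 points spanning 1.5 pH units are required.

*Exchange and intensity ratios.* CLEANEX/reference intensity ratios
measure amide solvent exchange; ratios below 0.02 are called protected.
HNCO cross-peak intensities are normalized to a maximum of 1 and residues
below 0.25 are flagged as exchange-broadened. Neither cutoff is a
published constant — both are package choices exposed as arguments.

*Dimerization energetics.* Monomer/dimer populations at a
detergent-to-protein mole ratio (LPR) give the mole-fraction equilibrium
constant `K_x = (f_D/2) · LPR / f_M^2` and `dG = -RT ln K_x`
(R = 1.987e-3 kcal/(mol K), default T = 318.15 K, the 45 °C of the
experiments). The factor 1/2 converts peptide fraction to dimer particles;
LPR converts to mole fractions in the detergent phase. This is a
documented standard convention, validated against its algebraic
identities (LPR doubling shifts dG by −RT ln 2; inversion flips the sign)
and by exact round-trip with `make_population_series()` — not against any
published free energy, whose underlying populations and conventions are
not available.

## Helix axes and dimer geometry

`fit_helix_axis()` uses the classic bisector construction: for interior
Cα atoms, `H_i = Ca_{i-1} - 2 Ca_i + Ca_{i+1}` points radially at the
axis, so consecutive cross products `H_i × H_{i+1}` are parallel to the
axis; their sign-aligned average gives the direction, and the axis
position is the least-squares circle centre of the Cα projections on the
normal plane. Both steps are exact on ideal helices (machine-precision
recovery of direction, radius and rise), which a midpoint-smoothing +
total-least-squares line is not: any linear smoother leaves a residual
helix whose fitted line is biased by ~1e-3 rad whenever the trace spans a
non-integer number of turns. Perfectly collinear traces (degenerate helix
of radius zero) fall back to the total-least-squares line. At least 7 Cα
atoms are required; kinked or curved helices are out of scope.

`dimer_geometry()` reports the acute crossing angle Ω ∈ [0°, 90°] between
the axis lines (N→C polarity only sets the `antiparallel` flag), the
minimal distance between the finite axial segments (so parallel axes stay
well-defined), and the packing handedness from the torsion sign: with `w`
the common perpendicular at closest approach, negative
`det[dir_A, dir_B, w]` is right-handed, positive left-handed. Pairs
within 2° of parallel are labelled `parallel`. The convention is fixed by
construction in `make_symmetric_dimer()` and unit-tested by round-trip
over a grid of known geometries (5–45°, 6–12 Å, both handednesses,
recovered within 0.5° and 0.1 Å). Helix length is reported as the axial
span between the projections of the first and last Cα, so an ideal
n-residue helix measures (n−1) × 1.5 Å — an explicit convention; published
helix lengths quoted per residue count can differ by one rise depending on
whether termini are padded.

## Solvent-accessible surface and interface ranking

`sasa()` is a Shrake–Rupley implementation: each atom's sphere of radius
r_vdw + probe (probe 1.4 Å) is sampled on a deterministic golden-spiral
lattice and the accessible fraction is the share of points outside all
neighbouring expanded spheres. Radii: C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å; hydrogens (1.20 Å) are excluded by default. Per-atom accuracy
was validated against the analytic two-sphere cap formula (0.1–0.5%
error). The default of 3840 points per atom was set by a convergence
criterion — doubling the point count must change per-residue areas of an
isolated helix by less than 1% — which 960 points narrowly fail (1.04% on
the TM-helix fixture) and 3840 meet with margin (0.69%). Residues that are
almost completely buried in a tight complex have areas of a few Å², and
their *relative* convergence is intrinsically poor at any practical
lattice size; absolute burial values are unaffected.

`burial_profile()` defines buried area per residue as SASA of the chain
alone minus SASA in the complex, computed with the same point lattice, so
burial is non-negative by construction and the per-residue burials sum
exactly to SASA_A + SASA_B − SASA_complex. `rank_models()` scores each
candidate dimer by the summed burial of the CSP-flagged residues, averaged
over the two chains (identical up to sampling noise for C2 models), sorts
descending with ties broken by total interface area then model id, and
marks a model `inconsistent` whenever an unperturbed reporter residue
(e.g. a lysine side-chain CεH2 whose shift does not move on dimerization)
buries more than 15 Å². The aggregation (sum of whole-residue burial) and
the reporter cutoff are package choices: the cutoff was calibrated on
synthetic fixtures so that clearly interfacial side chains fail it and
clearly exposed ones pass, and whole-residue burial can be switched to
side-chain-only via `side_chain_only`.

`enumerate_symmetric_dimers()` is a deliberately simple geometric
enumerator standing in for an external docking program, so the pipeline is
end-to-end runnable: C2-symmetric placements on a grid of crossing angle,
distance, self-rotation and handedness, discarding grid points with
interchain backbone contacts below 2.2 Å. The pseudo-atom side chains of
generated helices (below) are excluded from the clash test: they are
centroids, and two facing side chains in van der Waals contact
legitimately bring their centroids within ~2 Å — counting them would
reject exactly the interface-forming candidates the enumerator exists to
produce. For full-atom structures every heavy atom counts.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with recorded
ground truth and bit-identical output for a fixed seed:

- `make_ideal_helix()`: straight ideal α-helix (rise 1.5 Å/residue, twist
  100°/residue, Cα radius 2.3 Å) with idealized cylindrical backbone N, C,
  O placement and one pseudo-atom side chain per residue at a
  residue-type-specific radial distance. No rotamers, no kinks, no
  termini effects.
- `make_symmetric_dimer()`: exact C2 dimers with prescribed crossing
  angle, handedness, distance, self-rotation and axial shift; clashing
  geometries are still emitted (with a warning) because tests need them.
- `make_shift_tables()`: monomer shifts from random-coil values plus a
  +2.8 ppm helical Cα offset inside the helical range and residue-type
  methyl baselines; dimer shifts add a fixed (ΔδH, ΔδC) perturbation
  (default ≈ 0.032 ppm generalized) on the interface residues and
  i.i.d. Gaussian noise (defaults σH 0.003, σC 0.012 ppm — the carbon sd
  is four times the proton sd so both contribute comparably after the
  1/16 carbon weighting). The recoverable truth is the interface residues
  that carry methyls.
- `make_titration()`: Hill-model curves (default pKa 6.16, n 0.98,
  plateaus 8.60/7.70 ppm, 25 points over pH 4.5–8.5, σ 0.005 ppm).
- `make_population_series()`: exact inverse of the mole-fraction
  equilibrium, no oligomer fraction.

Passing tests on these inputs shows the estimators are correct and
well-conditioned under the stated noise; it does not show robustness to
what real spectra add — peak overlap and misassignment, correlated
chemical-shift noise, ring-current and neighbour effects on random-coil
references, curved or kinked helices, rotamer-dependent burial, or
higher-order oligomers competing with the dimer equilibrium.

## Problem sizes

The shipped tests and the acceptance checks run at desk scale by design:
48-residue constructs, 100 replicates for titration recovery and for
flagged-set recovery (F1 computed per seed), a 40-point geometry
round-trip grid, candidate ensembles of 4–8 dimers ranked at 960 sphere
points, and SASA convergence checks at the 3840-point default. The full
suite completes in well under a minute.
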