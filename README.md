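# helixdimer

Analysis toolkit for single-pass transmembrane (TM) helix dimers studied
by solution NMR in membrane mimetics. It is written for structural
biologists who have (or simulate) the typical observables of such a study
— sequence segments, chemical-shift tables for monomeric and dimeric
states, pH-titration series, peak-intensity ratios, and candidate dimer
coordinates — and want the downstream analyses as reproducible, testable
code. The running example is the human TLR4 TM helix and its
juxtamembrane hydrophobic region, whose dimerization interface can be
inferred from methyl chemical-shift perturbations.

The package implements five connected analyses:

1. **Whole-residue hydrophobicity.** Segment free energy of transfer
   water → octanol, ΔG = Σᵢ ΔG(aaᵢ), on the Wimley–White whole-residue
   scale (His neutral, Asp/Glu/Lys/Arg charged by default), with sliding
   windows and an extractor for the post-TM hydrophobic segment.
2. **Chemical-shift analytics.** Secondary Cα shifts Δδ = δ_obs − δ_rc and
   helix-stretch calling; generalized methyl perturbations
   δ = √(ΔδH² + ΔδC²/16) with strong/weak classification (> 0.02 ppm /
   0.01–0.02 ppm); Hill titration fits
   δ(pH) = (δₐ + δᵦ·10^{n(pKa−pH)}) / (1 + 10^{n(pKa−pH)});
   CLEANEX exchange and HNCO intensity ratios; mole-fraction dimerization
   energetics K_x = (f_D/2)·LPR/f_M², ΔG° = −RT ln K_x.
3. **Helix-dimer geometry.** Bisector-based helix-axis fits (exact on
   ideal helices) and dimer descriptors: crossing angle Ω, packing
   handedness from the inter-axis torsion sign, minimal inter-axis
   distance between finite segments.
4. **Interface ranking.** Shrake–Rupley SASA, per-residue buried surface
   on dimerization, and CSP-guided ranking of candidate dimers: score =
   buried area of perturbation-flagged residues, with an
   unperturbed-reporter consistency test that rejects models burying
   groups whose shifts did not move.
5. **Synthetic data.** Deterministic generators (ideal helices, exact C2
   dimers with prescribed geometry, shift tables with a known interface,
   titration curves, population series) so every stage is testable with
   known ground truth.

## Worked example

```r
library(helixdimer)

# hydrophobicity of the TLR4 post-TM hydrophobic region
tmicl <- tlr4_constructs()$TMICL
hr <- extract_post_tm_segment(tmicl, tm_end = 652)
score_segment(hr)
#> <segment_score> n = 13, total = -5.13 kcal/mol, per residue = -0.39

# build a C2 dimer with known geometry and measure it back
dim <- make_symmetric_dimer(strrep("V", 25), omega = 28,
                            handedness = "right", d = 7.9)
measure_dimer(dim)
#> <dimer_geometry> omega = 28.0 deg (right), closest distance 7.90 A

# fit a pH titration
curve <- make_titration(pKa = 6.16, n = 0.98, sigma = 0.005, seed = 1)
fit_titration(curve$pH, curve$delta)
#> <titration_fit> pKa = 6.158 +/- 0.006, Hill n = 0.969 +/- 0.013
#>   plateaus: 8.602 (high pH) / 7.698 (low pH) ppm, residual rms 0.0046 ppm
```

The total of −5.13 kcal/mol (−0.39 per residue) says the 13 juxtamembrane
residues after the annotated TM domain are, on average, as hydrophobic as
the TM helix itself — the basis for treating them as part of one long TM
helix. The dimer descriptors recover the construction geometry within
0.5° and 0.1 Å, and the titration fit recovers the generating pKa within
its standard error.

The `analysis/` directory holds three narrative drivers that run the full
workflow and write tables under `results/`:

```sh
Rscript analysis/01_hydrophobicity.R   # segment scores vs published table
Rscript analysis/02_shift_analysis.R   # helix call, CSP flags, titration, dG
Rscript analysis/03_dimer_models.R     # candidate geometries + ranking
```

`run_pipeline(pipeline_config(out_dir = "results/run"))` executes the same
stages end to end from one configuration object.

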