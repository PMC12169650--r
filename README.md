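# duplexform

Tools for quantifying how DNA duplexes adapt their structure when a
minor-groove binding protein engages them — written for structural
biophysicists analyzing protein–DNA ensembles (molecular-dynamics
snapshots, multi-model PDB structures) alongside fluorescence binding
data.

The scientific motivation is the sequence-dependent recognition of DNA by
the bacterial nucleoid-structuring protein H-NS: its DNA-binding domain
inserts a conserved Gln-Gly-Arg (QGR) loop into the minor groove, binds
AT-rich repeats far more strongly than GC-rich ones, and the AT-rich DNA
responds with A-like local features — North (C3′-endo) sugar repuckering,
an anti shift of the glycosidic torsion χ, minor-groove widening,
increased curvature and undertwisting of the central base step.
`duplexform` implements the complete analysis chain for that kind of
study, plus synthetic-data generators with known ground truth so every
stage is testable without microsecond trajectories.

## What it computes

- **Rigid-base parameters.** Base frames by Kabsch superposition of
  embedded standard bases; the six pair parameters (buckle, propeller,
  opening; shear, stretch, stagger) and six step parameters (tilt, roll,
  twist; shift, slide, rise) via the 3DNA-style mid-frame (hinge-axis)
  decomposition, with an exact closed-form inverse used by the duplex
  builder, so build → extract is an identity to numerical precision.
- **Backbone conformation.** Sugar pseudorotation
  (tan P from the five endocyclic torsions ν₀…ν₄, ν_max amplitude),
  North/South and anti/high-anti classification, per-position fraction
  profiles over ensembles.
- **Helix geometry.** Minor/major groove widths (cross-strand P–P
  distances − 5.8 Å), local helical axis, total bend and bend direction
  relative to the minor groove.
- **Protein–DNA contacts.** Heavy-atom contact counts, the
  *C*<sub>minor–QGR</sub> and *C*<sub>sugar–Trp</sub> coordinates, the
  bound-state rule (*C*<sub>minor–QGR</sub> > 25 with ≥ 2 Trp–sugar
  contacts), and exact 2D contact densities.
- **Metadynamics free energies.** PLUMED-HILLS-dialect I/O,
  F(s) = −Σ h·exp(−(s−s_k)²/2σ²) reconstruction over the twist interval
  [10°, 60°], sub-profiles every 2 ns min-aligned and averaged over a
  10–50 ns window with pointwise SDs, free-diffusion diagnostics, and the
  pruning rule for runs with unrecovered base-pair opening.
- **Binding spectroscopy.** Inner-filter correction
  F·exp((A_ex+A_em)/2), Hill-isotherm fits θ = cⁿ/(Kⁿ+cⁿ) on θ vs log₁₀ c,
  ΔG = −RT ln(1/K_D) at 298 K, and IRF-reconvolution multi-exponential
  TCSPC lifetime fits I(t) = Σ αᵢ e^(−t/τᵢ).
- **Generators.** Ideal/perturbed A-/B-form duplex ensembles built from
  rigid-base parameters and sugar templates (with controlled fluctuation
  SDs and adjacent-twist coupling ρ), geometric protein probes with
  brute-force-checkable contact counts, Langevin-walker hill deposits,
  Hill titrations, and Poisson TCSPC decays.

See the methods vignette (`vignettes/dna-structural-adaptation.Rmd`) for
the model details, parameter defaults, and design decisions.

## Worked example

```r
library(duplexform)

# build the AT-rich 12-mer in ideal B-form and extract its parameters
d <- build_form_duplex("GCATATATATGC", "B")
rb <- rigid_base_parameters(d)
round(head(rb$step, 3), 3)
#>   position tilt roll twist shift slide rise
#> 1        1    0    0    36     0     0 3.38
#> 2        2    0    0    36     0     0 3.38
#> 3        3    0    0    36     0     0 3.38
```

The extractor returns exactly the canonical B-form values the builder was
given (twist 36°, rise 3.38 Å) — the round-trip identity that anchors the
whole rigid-base layer.

```r
# perturbed ensemble with anticorrelated neighbour twists
ens <- sample_ensemble(list(sequence = "GCATATATATGC"),
                       ensemble_spec(n_frames = 200, seed = 1, rho = -0.5))
adjacent_step_correlation(attr(ens, "truth")$step[, , "twist"])
#> [1] -0.4857692

# sugar pucker / glycosidic classification of an A-form duplex
da <- build_form_duplex("GCATATATATGC", "A")
p <- pseudorotation(residue_xyz(da, "A", 6))
c(P = unname(round(p["P"], 2)), pucker = classify_pucker(p["P"]),
  chi_class = classify_chi(chi_angle(da, chain = "A", resno = 6)))
#>         P  pucker.P chi_class
#>      "18"   "North"    "anti"
```

A 200-frame ensemble generated with twist coupling ρ = −0.5 measures a
pooled adjacent-twist correlation of −0.49, and the A-form duplex shows
the expected C3′-endo (P = 18°, North) sugar with an anti glycosidic
torsion.

```r
# metadynamics: double-well twist landscape, windowed averaging
gen <- generate_hills(make_potential("double_well", minima = c(25, 45),
                                     barrier = 5), duration_ns = 52, seed = 1)
prof <- windowed_profiles(gen$hills, every_ns = 2, window = c(10, 50))
prof
#> fes_profile: 201 points, window 10-50 ns (21 sub-profiles)
#>   minimum at 25.25 deg, valley width 7.68 deg at kT
fes_local_minima(prof)[1:2, ]
#>     twist_deg   F_kJmol
#> 62      25.25 0.0000000
#> 142     45.25 0.1281456
```

The windowed average of the accumulated bias locates both wells of the
generating potential (truth: 25° and 45°) to within a quarter degree.

```r
# Hill fit of a synthetic quenching titration and its free energy
tt <- generate_titration(K = 1.57e4, n = 1.38,
                         concentrations = 10^seq(2.5, 6.5, length.out = 12),
                         noise_sd = 0.5, seed = 1)
hill_fit(tt)
#> hill_fit: K = 1.568e+04 nM (se 184), n = 1.405 (se 0.0207)
#>   delta G (298 K, 1 M standard state) = -6.55 kcal/mol
delta_g(3.35e5 * 1e-9)   # the weaker GC-rich site, for comparison
#> [1] -4.738302
```

A noisy titration generated with K = 1.57×10⁴ nM and n = 1.38 is fitted
back to K = 1.568×10⁴ nM, n = 1.405; the corresponding dissociation free
energies are −6.55 kcal/mol for the high-affinity (AT-rich) site and
−4.74 kcal/mol at the GC-rich site's K_D.

An end-to-end run (simulate → analyze → report, with a manifest and
byte-reproducible outputs) is available as
`run_pipeline(system.file("extdata", "demo-config.yaml",
package = "duplexform"))`, or from a shell via
`inst/scripts/run_pipeline.R`.

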