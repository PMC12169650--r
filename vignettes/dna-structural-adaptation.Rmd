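---
title: "Quantifying sequence-dependent DNA structural adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sequence-dependent DNA structural adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexform)
```

## The problem

Minor-groove binding proteins such as the bacterial nucleoid-structuring
protein H-NS engage AT-rich DNA with much higher affinity than GC-rich
DNA, and the DNA itself responds: sugars repucker from the B-like South
(C2'-endo) region toward the A-like North (C3'-endo) region, the glycosidic
torsion shifts from high-anti toward anti, the minor groove widens, the
helical axis bends, and the central base step undertwists. `duplexform`
implements the full analysis chain needed to quantify these effects — from
atomic coordinates to rigid-base parameters, backbone classification,
groove/bend descriptors, contact statistics, metadynamics free-energy
profiles and binding isotherms — together with synthetic-data generators
that produce every input with known ground truth, so that each analysis is
testable end to end without microsecond molecular-dynamics trajectories.

## Rigid-base parameters and the builder/extractor pair

Each base is treated as a rigid body. A base frame is obtained by
least-squares (Kabsch) superposition of an embedded standard base
(Tsukuba-convention reference geometries for A, T, G, C) onto the observed
base ring atoms; reflection solutions are corrected to proper rotations.
Two frames are related by six descriptors via the mid-frame (hinge-axis)
construction used by the 3DNA family: the z-axes are symmetrically rotated
onto their bisector plane about the hinge `z1 x z2`, twist (or opening) is
the angle between the corrected x-axes, the bend angle is distributed onto
roll/tilt (propeller/buckle) by the phase angle between the hinge and the
mid-frame y-axis, and translations are expressed in the mid-frame. The
Crick frame is flipped 180 degrees about its own x-axis before pairing, so
two coincident ideal bases give identically zero pair parameters.

The decomposition has an exact closed-form inverse (`compose_frames()`,
and `split_mid_frame()` internally), and the duplex builder places bases
*only* through this inverse. Correctness is therefore enforced by
round-trip identities rather than by digit-matching any external program:
`compose -> decompose` is the identity to 1e-9 over |angles| <= 45 deg and
|translations| <= 3 A, and a full 12-mer build/extract round trip agrees
to 1e-6. Angles are degrees externally and radians internally.

## Sugar construction and pseudorotation

The five endocyclic torsions of the deoxyribose ring follow
`nu_j = nu_max * cos(P + 144 (j - 2))`; the analysis direction
(`pseudorotation()`) uses the standard phase formula with the quadrant
resolved by `atan2`, and recovers the amplitude through `nu0` when
`cos P ~ 0`. North/South classification splits the phase circle at 90/270
degrees with half-open intervals (P = 90 is South); no East/West classes
are used, since the hemispheres are what the A/B distinction needs.

The build direction has no unique answer (many Cartesian rings realize one
(P, nu_max)), so the package constructs a puckered pentagon whose
out-of-plane displacement phase and amplitude are calibrated by direct
optimization against the package's own `pseudorotation()` until the
realized phase matches the request; the acceptance band is +/-5 degrees
but the optimizer lands within ~1e-4 degrees in practice. Bond lengths are
near 1.5 A by construction. The ring is grafted onto the base through the
free tetrahedral slot at C1', and the glycosidic torsion chi
(O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines) is set exactly
by a final rotation about the glycosidic bond. The facial choices for the
base, C5' and O3' substituents reproduce the beta-D arrangement; they were
fixed, once, by requiring a continuous backbone (short O3'(i)-O5'(i+1)
bridges) and the B-DNA cross-strand phosphate pattern (narrow minor / wide
major groove) on ideal fibers. Phosphates are placed midway along the
C3'(i)-C5'(i+1) bridge; backbone torsions are otherwise unconstrained,
because only sugar, base and phosphate positions feed the analyses.

Chi classes use half-open boundaries anti `[-180, -120)`, high-anti
`[-120, -60)`, syn `[0, 90)`, other elsewhere, chosen so canonical A-DNA
(chi ~ -160) is anti and canonical B-DNA (chi ~ -100) is high-anti; they
are configurable in `classify_chi()`. Per-position North/anti fractions
pool the two paired residues by default (one value per base pair), with a
flag for per-strand profiles; fractions are exact ratios of integer
counts.

## Canonical forms and the ensemble generator

The canonical fixtures are textbook fiber constants: B-form twist 36 deg,
rise 3.38 A, slide 0, roll 0, P 162 deg, chi -100 deg; A-form twist
32.7 deg, rise 2.56 A, slide -1.5 A, roll 8 deg, P 18 deg, chi -160 deg.
`sample_ensemble()` draws per-frame step and pair parameters as Gaussians
about the spec means. Default fluctuation SDs (3-4 deg for step angles,
~6 deg for buckle/propeller, 0.2-0.4 A for translations) are of the order
seen in thermal ensembles of B-DNA; they matter only as generator targets.
Adjacent step twists share a multivariate normal whose tridiagonal
correlation rho models the nearest-neighbour twist coupling that minor
groove binding amplifies; a non-positive-definite request errors rather
than being silently repaired. Because frames are rebuilt from the sampled
parameters exactly, extraction recovers the sampled values to numerical
precision — the generator validates the extractor, not the reverse.

What the generator does *not* emulate: sequence-specific equilibrium
values, anharmonic or bimodal parameter distributions, BI/BII backbone
substates, ions and hydration, and correlations beyond adjacent twists. A
green test suite therefore certifies the analysis machinery, not any
biophysical claim about real trajectories.

## Helix geometry

Groove widths are refined cross-strand P-P distances minus the
conventional 5.8 A phosphate-radius correction; the minor width at step i
takes the minimum over Crick phosphates of pairs i-2 and i-3 (major:
i+2, i+3), with NA — never zero — where phosphates are missing near
termini. Absolute widths differ between conventions by a constant; only
relative changes are interpreted.

The local helical axis at step i is the normalized average of the
base-pair z-axes over a sliding window (default 3 steps). An alternative
definition — the rotation axis of the step transform — was considered and
rejected: for any uniform parameter set the step rotation axis is a
constant vector (each frame is the previous one times a fixed rotation,
which fixes its own axis), so uniform-roll fixtures would show zero
curvature and no closed-form oracle would exist. With the z-average
definition, an ideal straight fiber gives parallel axes, and uniform roll
without twist turns the axis by exactly the roll angle per step, matching
direct rotation composition. Total bend is the angle between the axes of
the first and last window; bend direction is the signed angle from the
central pair's minor-groove vector (its -y axis) to the axis change
projected into the central pair plane.

## Protein-DNA contacts

Contacts are strict `<` heavy-atom pair counts. The two coordinates
mirror the minor-groove binding geometry: all heavy atoms of the
Gln112-Gly113-Arg114 motif against the minor-groove acceptors (purine N3,
pyrimidine O2, sugar O4'), and the Trp109 NE1 atom against the
deoxyribose atoms C1'-C5', O4'. The 4.5 A cutoff is the community default
for heavy-atom contacts and is configurable; every downstream statement is
a threshold on counts (bound when `C_minor-QGR > 25` and
`C_sugar-Trp >= 2`), not an absolute count. Probe complexes built by
`build_probe_complex()` place pseudo-atoms at exact distances from named
DNA atoms (direction chosen to maximize clearance from all other atoms,
deterministically), so fixtures have brute-force-checkable counts; the
O(n^2) oracle ships as `brute_force_contacts()`. 2D contact histograms
use integer bins and sum to one exactly.

## Metadynamics free-energy reconstruction

Hill deposits follow the standard twist-metadynamics setup: Gaussian
width 0.04 rad, height 0.1 kJ/mol, deposited every 4 ps, bias confined to
[10, 60] degrees with zero bias force outside. The free-energy estimate is
the negative accumulated bias,
`F(s) = -sum_k h_k exp(-(s - s_k)^2 / 2 sigma_k^2)`, min-aligned to zero;
reconstruction is tested against direct summation to 1e-12. The averaging
protocol reconstructs one sub-profile every 2 ns, min-aligns each
(declared explicitly so the pointwise SDs are interpretable), and averages
over the 10-50 ns window; 21 sub-profiles on a 0.25 degree grid. Grid
spacing is fine enough to resolve minimum shifts an order of magnitude
smaller than the ~5 degree scale of interest. Well-tempered rescaling is
not supported: a biasfactor column is parsed but triggers a warning and
heights are used as deposited.

The generator's walker is overdamped Langevin (Euler-Maruyama, kT =
2.494 kJ/mol) on the model potential plus its own accumulated bias, with
reflective walls at the boundaries. The walker is a calibration device,
not a molecular model: its diffusion coefficient (default 1e4 deg^2/ns,
time step 0.1 ps, per-step drift capped at 2 degrees so the steep outer
walls of confining potentials cannot destabilize the integrator) was
chosen when the generator was designed so that its documented contracts
hold — free diffusion across the interval well before 10 ns on a flat
potential, and a windowed accumulated bias flat to within three hill
heights in the interior on long runs. Two unavoidable artifacts are
documented rather than hidden: deposits near a wall spill half their mass
outside, so profiles taper within ~3-4 Gaussian widths of the boundaries
(flatness is assessed on [20, 50] degrees), and single-profile roughness
scales like `sqrt(h kT sigma S / (D tau))`, which is why the windowed
average, not any single profile, is the estimator.

Convergence diagnostics report interval coverage and
boundary-to-boundary traversals (within 2.5 degrees of a wall, about one
hill width); a run passes with at least one traversal before 10 ns.
Pruning treats a base pair as open in a frame when every Watson-Crick
donor-acceptor heavy-atom distance exceeds 3.5 A, as unrecovered when it
is open from its first opening to the end of the run, and excludes a run
when more than one monitored pair is unrecovered; the decision is a pure
function of the pairing time series.

## Binding and time-resolved spectroscopy

Observed intensities are inner-filter corrected by
`exp((A_ex + A_em)/2)`. The bound fraction is defined from quenching as
`theta = (F0 - F)/(F0 - F_inf)` with the endpoints co-fitted by default
(they are rarely measured exactly); the Hill isotherm
`theta = c^n/(K^n + c^n)` is fitted unweighted on theta versus log10
concentration — the surface on which such titrations are plotted — via
Levenberg-Marquardt on log10 K, with standard errors from the fit
covariance (delta method for K) and optional seeded residual-bootstrap
CIs. Free energies use `delta G = -RT ln(1/K_D)` at 298 K with R =
1.98720e-3 kcal/(mol K) on the 1 M standard state.

Decay fits reconvolve `sum alpha_i exp(-t/tau_i)` with the instrument
response function by discrete causal convolution on the channel grid
(Gaussian IRF, default FWHM 1 ns — a typical TCSPC instrument width);
weighted least squares with Poisson weights `1/max(counts, 1)`, positivity
enforced by log-transformed parameters, at most three components (more are
not identifiable from single decays), reduced chi-square reported.
Generator and fitter share one model function, so noiseless round trips
are exact by construction; Poisson-noise recovery is checked at 1e6 total
counts under fixed seeds.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 500 random parameter
sets for the frame round trip; 12-mer duplexes throughout; 2000-frame
ensembles for fluctuation/coupling recovery (with extraction identity
spot-checked on a 20-frame slice, since extraction is exact by
construction); 10^4 random hills for the reconstruction oracle; one 52 ns
double-well run and one 160 ns flat run for the metadynamics contracts;
200 seeded titration replicates for CI coverage; and 1024-channel decays
at 10^6 counts. These sizes make every stochastic check stable across
seeds. All generators are bit-reproducible under a fixed seed, and
`run_pipeline()` writes byte-identical outputs for identical config and
seed.

## Known limitations

The builder's backbone is idealized (midpoint phosphates, unconstrained
backbone torsions), so epsilon/zeta or BI/BII analyses are out of scope.
Groove widths and curvature use transparent fixed definitions rather than
curvilinear-axis fits, so absolute values are convention-dependent. The
hill generator's walker dynamics are not molecular kinetics; only the
deposition bookkeeping and reconstruction mathematics carry over to real
HILLS files. The Hill fit treats titration points as independent and
assumes a single binding class; the decay fit assumes a stationary IRF
and no scattered-light component.
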