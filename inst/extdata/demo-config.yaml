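# Demo pipeline configuration: build the AT-rich 12-mer in B-form, sample
# a thermally perturbed ensemble with coupled neighbour twists, and run
# every analysis stage. All angles in degrees, distances in Angstrom,
# concentrations in nM, times in ns.
seed: 1
sequence: GCATATATATGC
ensemble:
  n_frames: 50
  rho: -0.3
stages: [simulate, conformation, rigid_base, grooves, bend, contacts, fes, binding]
contacts:
  cutoff: 4.5
fes:
  duration_ns: 12
  every_ns: 2
  window: [4.0, 10.0]
  potential:
    type: harmonic
    s0: 35.0
    k: 0.05
binding:
  K: 15700.0
  n: 1.38
  concentrations: [316.0, 1000.0, 3160.0, 10000.0, 31600.0, 100000.0,
                   316000.0, 1000000.0, 3160000.0]
  noise_sd: 0.5
  decay:
    amplitudes: [0.7, 0.3]
    lifetimes: [1.0, 4.0]
    total_counts: 100000.0
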