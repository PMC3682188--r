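# enthcg

Coarse-grained modeling of how epsin N-terminal homology (ENTH) domains
bind membranes and self-organize into ordered coats on membrane tubules,
together with the CW-EPR analysis chain that constrains that organization
experimentally.

ENTH domains drive membrane remodeling by inserting an N-terminal
amphipathic helix (H0, residues 1-15, `MSTSSLRRQMKNIVH`) into the outer
leaflet and binding PIP2. Spin-label EPR on singly labeled domains bound to
preformed membrane tubules reveals short, symmetric interlabel distances
(residue 6 and 10 near 13 Å, residue 5 at 9 Å, residue 4 broad around
21 Å) diagnostic of an antiparallel H0 dimer, plus shorter cross-dimer
distances (residue 13 near 15 Å, residue 14 near 10 Å) pointing at an
offset dimer-of-dimers lattice. `enthcg` turns those observations into a
working computational pipeline:

* **Membrane simulator** — single-site Gay–Berne lipids (3:1 aspect ratio,
  broken head–tail symmetry) with analytic forces and torques; builders
  for flat bilayers, periodic/capped tubes and vesicles; constant-NVT
  velocity-Verlet dynamics with a Nosé–Hoover thermostat
  (300 K, dt = 0.001 ps).
* **16-site ENTH model** — essential-dynamics coarse-graining
  (`edcg_partition()`, exact dynamic programming), fluctuation-matched
  elastic networks (`heteroenm_fit()`), role-annotated topology
  (H0 sites 1–2, patch site 5, R114 loop site 10, PIP2 pocket) and
  Boltzmann-inversion PMFs (`pmf_from_rdf()`).
* **EPR-restrained lattices** — `build_h0_dimer()`, `build_tetramer()`,
  helical tubule coats (`coat_tube()`) and random vesicle monolayers
  (`scatter_vesicle()`), all verified by an independent distance routine.
* **Coat order analysis** — the local orientational order parameter
  S_i = mean over neighbors within 5 nm of |u_i · u_j| between H0 axes,
  convergence traces, segment heterogeneity, defect lists and H0
  insertion-depth profiles.
* **EPR pipeline** — accessibility contrast Φ = ln(Π_O2/Π_NiEDDA), depth
  calibration d = aΦ + b, helical periodicity and face assignment, and
  spin-dilution interspin distance estimation by Gaussian
  dipolar-broadening fits.
* **Interfacial partitioning** — Wimley–White transfer free energies for
  partially helical amphipathic sequences.
* **Synthetic data** — seeded generators for every input (ENM reference
  trajectories, spectrum pairs, accessibility profiles, calibration
  points), so the full pipeline runs and tests offline.

## A worked example

Build the EPR-restrained dimer and check it against the measured
distances with the independent measurement routine:

```r
library(enthcg)

dimer <- build_h0_dimer()
dimer$residuals
#> # A tibble: 4 × 4
#>   residue target measured  residual
#>     <int>  <dbl>    <dbl>     <dbl>
#> 1       6     13    13.0  -0.000291
#> 2      10     13    13.0   0.000509
#> 3       5      9     9.00  0.000497
#> 4       4     21    21.0  -0.000225

tet <- build_tetramer(dimer)
measure_anchor_distance(tet, 13, "inter_dimer")  # 15.0 (Angstrom)
measure_anchor_distance(tet, 14, "inter_dimer")  # 10.0
```

All four intra-dimer anchors land on their restraint centers (13/13/9/21 Å,
residuals below 0.001 Å), and the offset tetramer reproduces the 15 Å /
10 Å cross-dimer distances with the site-5 hydrophobic patches in contact
(0.95 nm).

Partitioning the H0 helix into the bilayer interface:

```r
interfacial_dg(enth_h0_sequence(), helicity = 1)
#> Interfacial partitioning of MSTSSLRRQMKNIVH (NH3+/CONH2), helicity 100%:
#>   dG(unfolded) = +1.70, dG(folding) = -6.00, dG(total) = -4.30 kcal/mol
```

A favorable −4.3 kcal/mol at full helicity (−3.4 at 85%): folding and
interfacial partitioning pay for the unfavorable transfer of the unfolded
chain.

Recover an interspin distance from a synthetic spin-dilution pair in the
partially interacting regime:

```r
estimate_distance(gen_pair_spectrum(13, 2, 0.15, seed = 42))
#> Distance estimate: r = 13.00 A (width 2.00 A), interacting fraction 0.150
```

And a small simulated tubule coat:

```r
tube <- build_tube(16, 7 * 1.647407, periodic = TRUE, seed = 7)
coat <- coat_tube(tube)                   # seamless helical lattice
tr   <- run_nvt(coat, 16000, snap_stride = 2000, seed = 1)
converged_order(order_trace(tr))          # ~0.85-0.89: the coat holds
```

The same coat run with the inter-domain H0–H0 attraction removed
(`default_interactions(h0_h0_on = FALSE)`) relaxes to ~0.55–0.6, and
monomers scattered on a vesicle to ~0.5 — the ordered lattice needs both
the anisotropic tube geometry and the specific contacts.

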