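# ionbridge

Tools for studying protein–RNA recognition with **reduced amino-acid
alphabets** — for molecular evolution and RNA–protein biochemistry groups
who design combinatorial libraries, run in vitro selections, measure
binding by SPR, and interrogate interfaces in structural ensembles.

The scientific setting: modern protein–RNA interfaces lean on cationic and
aromatic side chains, yet those residues were scarce on the early Earth. A
protein restricted to a prebiotically plausible alphabet
(G, A, D, E, V, S, I, L, P, T) can still bind RNA if acidic side chains
recruit K⁺/Mg²⁺ ions as bridges to the phosphate backbone. `ionbridge`
implements the full computational workflow around that question:

- **Library design** — per-position substitution pools from a family
  alignment restricted to a design alphabet, encoded as optimal degenerate
  codons by exhaustive search over all 15³ = 3,375 IUPAC codons
  (objective, in priority order: off-target species, stop codons,
  degeneracy, lexicographic), with exact diversity accounting.
- **Selection analysis** — peptide counting from flanked reads, abundance
  ranking, position frequency matrices, information-content logos
  (`IC = log₂20 − H` bits), enrichment trajectories, consensus motifs.
- **Binding kinetics** — simulation and global fitting of the 1:1 Langmuir
  model for two-phase SPR sensorgrams:
  `R(t) = R_eq(1 − e^{−(k_on·C + k_off)t})` during association,
  `R(t_s)·e^{−k_off(t−t_s)}` during dissociation, `K_D = k_off/k_on`;
  one shared `(k_on, k_off, R_max)` across a concentration series,
  Levenberg–Marquardt on the log scale.
- **Interface analysis** — direct H-bonds (≤ 3.0 Å donor–acceptor, ≥ 135°
  D–H–A when hydrogens exist), water bridges, per-element metal-ion bridges
  (Mg 3.0 Å, K 3.5 Å), per-frame occupancies, VOLMAP-style occupancy grids
  with OpenDX export, and Kabsch-superposed backbone RMSD restricted to
  secondary-structure elements.
- **Synthetic data** — library samples, multi-round selections under a
  motif-fitness model, noisy sensorgrams, and toy protein–RNA ensembles
  with interactions planted at known occupancies, so every stage is
  validated against ground truth.

## Worked example

Design a degenerate codon and account for a small library:

```r
library(ionbridge)

design_codon(c("A", "D", "E", "G", "V"))
#> <degenerate codon GNK: 8 expansions, encodes {A,D,E,G,V}>

sch <- library_scheme(list(
  position_pool(1, "K", c("D", "E")),
  position_pool(2, "R", c("A", "D", "E", "G", "V")),
  position_pool(3, "G", "G")), name = "demo")
sch
#> <library scheme 'demo': 3 positions (2 randomized)>
#>   protein variants 10, DNA variants 16
```

GNK is the minimal exact cover of {A,D,E,G,V}: 8 DNA expansions, no
off-target residues, no stops. The demo scheme encodes 2 × 5 × 1 = 10
protein variants from 16 DNA variants, with 2/3 of positions randomized.

Simulate an SPR concentration series at published wild-type rate constants
(k_on = 1.2×10⁴ M⁻¹s⁻¹, k_off = 3.0×10⁻⁴ s⁻¹) with noise, then refit:

```r
p <- kinetic_params(1.2e4, 3.0e-4, 100)
curves <- lapply(c(525, 262.5, 131.25) * 1e-9, function(cc)
  simulate_sensorgram(p, cc, seq(0, 900), t_switch = 300, noise_sd = 2, seed = 1))
fit <- fit_one_to_one(curves)
summary(fit)
#> Global 1:1 binding fit
#>
#> Coefficients:
#>       estimate std.error
#> k_on  1.20e+04  5.50e+01
#> k_off 3.05e-04  3.83e-06
#> R_max 1.00e+02  2.88e-01
#> K_D   2.55e-08  3.56e-10
#>
#> Residual standard error: 2.067 on 2700 degrees of freedom (5 iterations)
```

The fitted `K_D` of 2.55×10⁻⁸ M recovers the generating 2.5×10⁻⁸ M within
the noise-limited uncertainty.

Detect planted interface interactions in a synthetic ensemble:

```r
pe <- build_planted_ensemble(planted_ensemble_spec(
  n_frames = 1000, hbonds = 0.63, water_bridges = 0.6, ion_bridges = 0.4,
  seed = 77))
detect_ion_bridges(pe$ensemble, frames = 1:1000)
#>   bridge_kind bridging_species protein_partner rna_partner occupancy
#> 1         ion       I/MG601/MG       A/SER3/OG    C/U3/OP1     0.407
```

Occupancy is the fraction of analyzed frames in which the Mg²⁺ ion
coordinates a protein oxygen and an RNA phosphate oxygen simultaneously —
here recovering the planted 0.40 within binomial sampling error.

See the methods vignette (`vignettes/ionbridge-methods.Rmd`) for the
models, defaults, and the reasoning behind every numerical choice.

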