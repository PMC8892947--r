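---
title: "Methods: reduced-alphabet library design, selection analysis, binding kinetics, and interface characterization"
author: "ionbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-alphabet library design, selection analysis, binding kinetics, and interface characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbridge)
```

# Scope

`ionbridge` implements the computational side of a reduced-alphabet
protein–RNA interaction study: (i) designing combinatorial protein libraries
restricted to a reduced amino-acid alphabet and encoding them as degenerate
codons, (ii) analysing multi-round in vitro selection (mRNA-display-style)
sequencing output, (iii) simulating and fitting 1:1 surface plasmon
resonance (SPR) binding kinetics, and (iv) characterizing protein–RNA
interfaces — direct hydrogen bonds, water bridges, and metal-ion bridges —
across structural ensembles such as molecular-dynamics trajectories. A
synthetic-data module generates every input with known ground truth, which
is how the package validates itself.

The motivating scientific question is whether a protein deprived of
cationic and aromatic residues (the residues modern protein–RNA interfaces
lean on) can still bind RNA, with acidic side chains recruiting K⁺/Mg²⁺
ions as electrostatic bridges to the RNA phosphate backbone. Every module
here serves some stage of that workflow, but each is general-purpose.

# Library design

## Substitution pools

`pools_from_alignment()` turns a family alignment into per-position
substitution pools: a residue enters a position's pool when its column
frequency reaches `min_column_freq` (default 0.1) *and* it belongs to the
design alphabet (for the "early" alphabet: G, A, D, E, V, S, I, L, P, T).
When the intersection is empty the position is fixed at the alphabet member
most similar to the wild-type residue under a 20×20 substitution score
table (BLOSUM62 by default; any table with residue dimnames can be
supplied). Ties resolve alphabetically so the output is deterministic.

## Degenerate codon optimization

`design_codon()` is an exhaustive search over all 15³ = 3,375 IUPAC
degenerate codons. A codon is feasible when its expansion covers the
required residue set, introduces no off-target residue (unless allowed) and
no stop codon (unless allowed). Among feasible codons the optimum minimizes,
in strict priority order:

1. number of off-target amino-acid species,
2. number of stop codons in the expansion,
3. degeneracy (expansion size),
4. the IUPAC string, lexicographically.

The priority order reflects the design goal of *defined* reduced alphabets:
a library advertised as "early residues only" must not leak other
chemistries, so off-target species dominate the objective; stop codons are
next (truncations waste library); degeneracy last (DNA-level redundancy is
cheap but dilutes sampling). The lexicographic tie-break only makes results
reproducible; e.g. `{D,E}` is encoded by GAK, GAM and GAS at equal cost and
GAK is reported. With 3,375 candidates, exhaustive search is exact and
instantaneous, so nothing heuristic is involved. Integer-programming
multi-codon designs under a library-size budget (as in dedicated
codon-design servers) are deliberately out of scope.

`library_diversity()` does exact accounting: protein variants are the
product over positions of the number of distinct encoded residues inside
the pool, DNA variants the product of degeneracies, and the randomized
fraction the share of non-fixed positions. Products are returned as doubles
because realistic schemes (19 randomized positions with pools of 3–4)
reach 10⁹–10¹⁰ variants, far beyond integer range.

# Selection analysis

`count_peptides()` excises the insert between exact 5′/3′ flank matches,
translates it in frame 0, and discards reads missing either flank or whose
translation contains an internal stop (a single trailing stop is stripped).
No quality trimming or read merging is attempted — reads are assumed
pre-processed. The default abundance floor is `min_count = 1`, i.e. none.

`peptide_logo()` computes a position frequency matrix and an
information-content logo over equal-length peptides. Information content
per position is

$$IC_j = \log_2 20 - H_j, \qquad
  H_j = -\sum_a f_{aj}\log_2 f_{aj},$$

with letter heights $f_{aj} \cdot IC_j$. No small-sample correction is
applied: the convention here is logos over the top-100 most abundant
sequences of a round, where the correction is small and its omission keeps
closed-form expectations exact in tests. Both uniform and count-weighted
logos are supported because selection-literature figures often do not state
which is used; uniform over the top-100 is the default. Peptides containing
ambiguous `X` residues are excluded from logos.

`consensus_sequence()` reports the modal residue per position when its
frequency reaches the threshold (default 0.5), otherwise `x`; modal ties
resolve alphabetically. `enrichment_trajectory()` reports per-round
fractions and round-over-round ratios, with the ratio undefined (NA)
whenever the previous round's fraction is zero.

# Binding kinetics

The 1:1 Langmuir interaction model for a two-phase sensorgram at analyte
concentration $C$:

association ($t \le t_s$):
$$R(t) = R_{eq}\left(1 - e^{-(k_{on}C + k_{off})\,t}\right),\qquad
R_{eq} = \frac{R_{max}\,C}{C + K_D},$$

dissociation ($t > t_s$):
$$R(t) = R(t_s)\,e^{-k_{off}(t - t_s)},\qquad K_D = k_{off}/k_{on}.$$

`fit_one_to_one()` fits all curves of a concentration series jointly with a
single global $(k_{on}, k_{off}, R_{max})$ — the standard global-analysis
practice for 1:1 SPR data, and the natural reading of a "one-to-one" model
when the sharing scheme is not otherwise specified. Parameters are
optimized on the log scale (enforcing positivity) by Levenberg–Marquardt
(`minpack.lm`), with tight tolerances (`ftol = ptol = 1e-14`) so noise-free
synthetic data is recovered to optimizer precision. Starting values come
from curve features: $R_{max}$ as 1.2× the largest response, $k_{off}$ from
a log-linear fit of the highest-concentration dissociation tail, $k_{on}$
from observed association rates. Standard errors derive from the
residual-variance-scaled covariance on the log scale, delta-propagated to
the natural scale; the $K_D$ error propagates the log-scale covariance of
$k_{off}$ and $k_{on}$.

Mass-transport limitation, baseline drift, bulk refractive-index jumps and
heterogeneous-ligand models are out of scope. When fitted values are
*displayed* at a table's 2-significant-figure precision, optimizer-level
floating-point noise (relative $\sim 10^{-15}$) is stripped first by
pre-rounding to 10 significant figures; stored values are never rounded.
This matters when the true value sits exactly on a rounding tie, e.g.
$3.6\times10^{-6} / 1.6\times10^{3} = 2.25\times10^{-9}$ M, displayed as
$2.2\times10^{-9}$ under round-half-to-even.

# Interface analysis

## Criteria

The geometric criteria are common trajectory-analysis defaults, all
configurable:

| quantity | default | unit |
|---|---|---|
| H-bond donor–acceptor heavy-atom distance | ≤ 3.0 | Å |
| H-bond donor–H–acceptor angle (when H present) | ≥ 135 | ° |
| Mg²⁺ coordination distance | ≤ 3.0 | Å |
| K⁺ coordination distance | ≤ 3.5 | Å |
| reported-record occupancy floor | 0.10 | — |
| analysis window | final 25% of frames | — |

When the ensemble carries no explicit hydrogens (crystal structures, many
deposited trajectories) the angle test is skipped with a warning and the
distance criterion alone decides — the behaviour is announced rather than
silently degraded. Donor/acceptor heavy atoms are tabulated for the 20
amino acids, the 4 ribonucleotides and water.

The tail-window default mirrors standard MD practice of analysing only the
equilibrated end of a trajectory; every detector takes an explicit frame
range. Published interaction counts from trajectory studies are sensitive
to exactly these settings (criteria and occupancy floor are rarely printed),
so counts should be compared across settings, not read as absolutes.

## Bridges

A water bridges when its oxygen simultaneously satisfies the H-bond
distance criterion to ≥ 1 polar protein atom and ≥ 1 polar RNA atom in the
same frame; an ion bridges when it is within its element's cutoff of ≥ 1
protein N/O and ≥ 1 RNA N/O simultaneously. Water bridges are aggregated by
(protein atom, RNA atom) partner pair across exchanging waters by default —
the conserved *site* view, which is what matters when individual waters
exchange with bulk solvent — with a per-water mode available. Ion bridges
are aggregated per (ion, protein partner, RNA partner) triple, with
per-partner coordination occupancies attached, because persistent ions are
individually identifiable.

## Grids and RMSD

`occupancy_grid()` voxelizes a species selection: a voxel's value is the
fraction of analyzed frames in which ≥ 1 selected atom falls inside it, so
values are exact frame fractions (value × n_frames is integral). Frames
should be superposed first (`superpose_ensemble()`); grids export to
OpenDX for isosurface rendering, conventionally contoured at 0.25
(water) and 0.20 (ion) occupancy.

`superpose_rmsd()` performs Kabsch superposition (SVD with reflection
guard) on the backbone atoms (N, CA, C, O) of the residues named in a
secondary-structure element set, then reports the RMSD over those same
atoms per frame and its mean. The default reference is frame 1; an external
single-frame ensemble may be supplied and is matched by (chain, residue
number, atom name).

# Synthetic data and what validation does (not) show

`sample_library()` draws each position's codon uniformly from its
degenerate expansion — the idealization of mixed-base synthesis.
`simulate_selection()` models a selection round as frequency-proportional
multinomial resampling with static per-motif retention weights (regular
expressions, so motifs can be anchored): the simplest model consistent with
enrichment dynamics. An optional uniform per-base substitution error
emulates polymerase errors in the RT-PCR steps; there is no PCR
amplification-bias or chimera model. One observed consequence worth noting:
weakly weighted motifs can transiently lose ground to genetic hitchhiking
on the back of strongly weighted clones before selection asserts itself —
visible in the package's own tests, and a reminder that consensus recovery
depends on effect size, round count and sequencing depth together. The
end-to-end recovery checks run at 10,000 reads/round over ≥ 8 rounds.

`build_planted_ensemble()` places a serine-rich toy protein chain and a
uridine-phosphate RNA chain on a 30 Å lattice so only planted contacts can
satisfy any criterion, then realizes each planted interaction as an
independent Bernoulli(occupancy) frame mask: present frames sit at bonded
geometry (2.7 Å pairs; 2.2 Å ion coordination), absent frames displace the
mobile species 6 Å sideways, and Gaussian jitter (default 0.02 Å) is added
everywhere. Detectors are scored against the realized masks — exact ground
truth — and against targets within binomial sampling error (3 SE at 1,000
frames in the acceptance checks).

These generators validate *bookkeeping and statistics*, not structural
realism: real trajectories have correlated frames, competing near-threshold
contacts, solvent exchange and force-field physics that the toy ensembles
deliberately lack. Passing tests show the detectors count what the criteria
define, on inputs where the right answer is known.

# Numerical and design choices

- **Indexing.** Residue and sequence numbering is 1-based (PDB convention);
  frame indices are also 1-based, as is natural in R — a single indexing
  convention throughout beats a mixed one.
- **Ambiguity in translation.** A degenerate codon translates to a residue
  only when *all* expansions agree (GGN → G); otherwise `X`. Nothing is
  silently invented.
- **Multi-model PDB** is the canonical ensemble format: self-contained,
  text, diffable, and sufficient at the tested scales. Coordinates
  round-trip to the format's 0.001 Å precision.
- **Determinism.** Every stochastic generator takes an explicit seed; all
  optimizer tie-breaks are lexicographic.
- **Degenerate inputs.** Empty FASTA/FASTQ files, empty alignments,
  no-surviving-read rounds, waterless ensembles and flat sensorgrams warn
  (or error, where no sensible value exists) with specific messages.
- **Problem sizes.** The test suite works at desk scale chosen to keep the
  full run in minutes while leaving comfortable statistical margins:
  10,000 reads/round selections, 1,000-frame planted ensembles,
  three-curve kinetic series at 1 s sampling, and 500 random required-sets
  for the codon-optimizer/oracle equivalence check.

# Known limitations

- Exact-cover degenerate codons do not exist for every residue set (e.g.
  {A, I, L, V}); the designer reports the best near-miss and can relax to
  minimal off-target designs on request, but pool choice upstream is the
  real lever.
- The 1:1 fitter assumes the model it fits; it will converge happily on
  data generated by richer mechanisms (mass transport, heterogeneity) and
  report biased constants, as any 1:1 analysis does.
- Interface detectors use fixed atom-name tables (standard PDB naming for
  amino acids, ribonucleotides, water); nonstandard residues classify as
  "other" and are ignored by the detectors.
- Published interaction counts from microsecond trajectory studies depend
  on unstated criteria and thresholds; reproducing such counts requires the
  original trajectories and sensitivity analysis over the criteria, neither
  of which ships with the package.
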