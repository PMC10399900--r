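---
title: "Coarse-grained modelling of Nanog micelle-like condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of Nanog micelle-like condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nanogmicelle)
```

## The scientific problem

Human Nanog is a master transcription factor of embryonic stem cells that
phase-separates in vitro at micromolar concentrations.  Its 305 residues fall
into three domains: a charged, disordered N-terminal domain (NTD), a folded
three-helix DNA-binding homeodomain (DBD), and a hydrophobic disordered
C-terminal domain (CTD) whose hallmark is the tryptophan-repeat (WR) region —
a block of five-residue repeats each beginning with Trp.  This package
implements a residue-level coarse-grained model of Nanog (and simple DNA and
crowder co-solutes), a Langevin dynamics engine for periodic slab boxes, and
the condensate analyses needed to characterise the internal structure of the
resulting droplets: Nanog condensates are not homogeneous liquids but
collections of *micelle-like clusters* — WR-driven hydrophobic cores wearing
charged NTD/DBD shells — that are bridged electrostatically into a larger
condensate.

## The model

**Beads and units.**  One bead per residue at the Cα position; three beads
per DNA nucleotide (phosphate, sugar, base, with the 5′-terminal nucleotide
of each strand lacking its phosphate); crowders are single repulsive
spheres.  Energies are in kcal/mol, lengths in Å, masses in amu; the derived
time unit is √(amu·Å²/(kcal/mol)) ≈ 48.9 fs.  Step counts, not physical
times, are the time axis of every analysis, since coarse-grained friction
makes the mapping to wall-clock time conventional.

**Hydrophobicity-scale (HPS) potential.**  Disordered-region bead pairs
interact through the Ashbaugh–Hatch form

$$
U_{\mathrm{HPS}}(r)=\begin{cases}
U_{\mathrm{LJ}}(r)+(1-\lambda_{ij})\,\epsilon, & r\le 2^{1/6}\sigma_{ij}\\[2pt]
\lambda_{ij}\,U_{\mathrm{LJ}}(r), & r> 2^{1/6}\sigma_{ij}
\end{cases}
$$

with $U_{\mathrm{LJ}}$ the 12-6 potential, $\sigma_{ij}$ and $\lambda_{ij}$
arithmetic means of per-residue diameters and stickiness values, and
$\epsilon = 0.2$ kcal/mol.  The λ table shipped in
`inst/extdata/hps_params.tsv` is a Tesei-et-al-derived calibration of the
hydrophobicity scale (λ ∈ [0,1]; Trp 0.99, Tyr 0.98, Ala 0.27, Glu ≈ 0).
The table is versioned and swappable (`hps_params(path = ...)`).  The
microscopic driver of every result in this package is that λ(Trp) ≫ λ(Ala),
which makes WR–WR contacts the stickiest interactions in the system and is
why the W8A mutation abolishes micelle cores.

**Electrostatics.**  Charged beads (Asp/Glu −1, Lys/Arg +1, His 0,
phosphoserine −1 by default, DNA phosphates −0.6) interact by Debye–Hückel
screened Coulomb energies with relative permittivity 78 and the Debye length
of the configured monovalent ionic strength (8.6 Å at 125 mM, 300 K).  The
no-electrostatics control is a flag that zeroes these terms; it is *not*
implemented as a large ionic strength.

**Excluded volume.**  All remaining pairs (crowders, DNA, folded-domain
pairs outside the HPS scope) repel through the WCA form — the 12-6 potential
shifted up by ε and truncated at its minimum — which is zero at and beyond
$2^{1/6}\sigma_{ij}$ and equals ε at $r=\sigma_{ij}$.

**Folded DBD.**  The homeodomain is held near a native-like shape by an
elastic network (harmonic restraints, k = 2 kcal/mol/Å², cutoff 9 Å) built
on a synthetic idealized three-helix bundle generated in code
(`dbd_reference_coords()`).  The choice is deliberate: the micelle
architecture is insensitive to the DBD interaction treatment (the
all-residue HPS control reproduces it), so a geometry-preserving network is
sufficient and keeps the package self-contained.  By default DBD beads feel
no HPS attraction (`hps_scope = "disordered_only"`); `"all_residues"` and
`"disordered_any"` expose the control setup and the second reading of the
ambiguous mixed-pair case.

**DNA.**  A geometry-preserving three-site duplex: ideal B-form-like helix
(rise 3.4 Å, 10.5 bp/turn), backbone bonds at reference distances, and an
intra-duplex elastic network (k = 5, cutoff 12 Å) standing in for base
pairing and stacking — the duplex is never meant to melt.  Nanog–DNA
interactions are excluded volume plus electrostatics only: binding is
sequence-nonspecific by construction (the poly-CG fragment is far from the
Nanog consensus site).

**Bonded terms.**  Harmonic bonds, b₀ = 3.8 Å, k = 5 kcal/mol/Å², and no
angle terms in disordered regions: the conclusions rest on the nonbonded
HPS/DH balance, and softer local terms permit the 0.5 time-unit step below.

**Cutoffs.**  Debye–Hückel terms use a 50 Å cutoff by default — the same
length scale used to define molecular "interaction" in the cluster analyses.
HPS and WCA use 25 Å (≈ 4σ).  Both are truncated *and shifted* so the
potential vanishes continuously at its cutoff; absolute energies therefore
carry a uniform shift relative to unshifted conventions, which cancels in
every force and every comparison made here.  The desk-scale studies below
shorten the DH cutoff to 35 Å (≈ 4 Debye lengths at 125 mM), which changes
screened interactions by under 2 % of ε at the cut.

## Dynamics

The engine integrates underdamped Langevin dynamics with the BAOAB
splitting, a deterministic counter-based RNG (bit-identical trajectories
under a seed), minimum-image periodicity in all three axes, and a two-level
Verlet/cell pair list (short-range list for HPS/WCA; a charged-pairs-only
list for electrostatics).  Coordinates are integrated unwrapped — mean-square
displacements need no unwrapping bookkeeping — and wrapped views are derived
on demand (`wrap_coords()`, bead-wise; `wrap_molecules()`, contiguity
preserving).

Defaults: timestep 0.5 time units (≈ 24 fs), chosen so the stiffest term
(bonds at k = 5 on glycine's mass) is integrated at ≈ 0.1 of its period;
friction 0.01–0.05 per time unit.  Friction in a coarse-grained model sets
sampling speed, not physics: the equilibrium ensemble is friction-independent,
and the package's validation suite checks equipartition (kinetic temperature
within 2 %) and free diffusion and harmonic-well sampling against closed
forms (within 5 %).

**Slab geometry.**  The production box is 300 × 300 × 3000 Å: a condensate
spans the short x–y cross-section, removing curved interfaces and their
finite-size costs; the long z axis carries the dilute phase.  The 300 Å
cross-section exceeds the largest intra-chain distance a single Nanog chain
samples (≈ 220 Å), so chains never touch their periodic images.

**Initialization protocols.**  `random_placement()` scatters rotated chain
conformations without steric overlap (the homogeneous start);
`shrink_protocol()` implements the condensed start — the box's z side
decreases by a fixed amount every fixed number of steps (0.1 Å / 100 steps
in the reference protocol) while the system relaxes, after which the dense
configuration is re-embedded in the full slab with `wrap_molecules()`.
`micelle_seed_placement()` constructs a micelle-like arrangement directly —
chains on a sphere with WR regions pointing inward — which is how the
desk-scale variant comparisons below are initialized.

## Analyses

All observables take a trajectory (engine output or synthetic fixture —
the two are interchangeable):

* `density_profile_z()` — z histograms of bead counts (optionally centred on
  the slab to remove drift before averaging).
* `molecule_clusters()` — single-linkage components of the 50 Å
  minimum-bead-distance interaction graph.  The dilute phase is every
  molecule outside clusters of five or more (`dilute_phase_stats()`), its
  concentration computed over the box volume minus the condensed slab
  (`condensate_extent()`: the largest contiguous, periodic-aware run of
  z bins above a density threshold; by default half the profile maximum,
  configurable absolutely).
* `wr_micelle_clusters()` — components of the WR-contact graph (any WR-bead
  pair within 6.5 Å); the operational definition of a micelle-like cluster.
* `intermolecular_contact_map()` — mean 6.5 Å residue–residue contact counts
  per frame per ordered molecule pair (alternative normalisation exposed).
* `domain_radial_profile()` — distances of per-molecule domain centroids
  from the periodic-aware (circular-mean), mass-weighted cluster centroid;
  geometric centroids are an option.
* `cluster_size_distribution()` — per-period normalised size histograms with
  an L1 convergence diagnostic.
* `msd_diffusion()` — time-origin-averaged centroid MSD with phase
  classification at the origin (molecules keep their origin label within a
  window), D from the MSD = 6Dt regression over a stated lag window.
* `tracked_set_variance()` — FRAP-like z-window tracking and
  micelle-membership tracking, reporting the z-centroid variance versus lag
  and, for micelles, how many original members still share a cluster (the
  cluster containing the largest number of original members).
* `dna_distance_distribution()` — minimum-image DNA centroid distance
  histograms.

## Synthetic fixtures

Every analysis is testable without dynamics through generators with planted
ground truth: two-phase slabs of known extent and dilute count
(`make_two_phase()`), micelles with prescribed CTD/DBD/NTD shell radii and a
WR core guaranteed inside the contact cutoff (`make_planted_micelle()`),
Brownian walkers of known D (`make_brownian_walkers()`), pinned DNA pairs
(`make_pinned_dna_pair()`), and a slow-micelle/fast-gas mixture
(`make_slow_micelle_fast_gas()`).  Fixture noise scales are fixed small
relative to the analysis cutoffs so the planted truth is unambiguous, and
every generator is deterministic under its seed.  Fixtures emulate geometry
and statistics only — none of the force-field physics — so a passing fixture
suite certifies the *measurement* machinery, not the model.

## Desk-scale study conditions

The reference experiments (200 chains, 5 × 10⁷ steps, eight trajectories)
are cluster-scale.  The package's own test suite and analysis scripts
reproduce the qualitative phenomenology on reduced systems whose sizes were
fixed in advance as a compromise between signal and runtime:

* 8 chains in a 140 × 140 × 560 Å slab (the cross-section still exceeds the
  ≈ 100 Å scale of one micelle), HPS cutoff 25 Å, DH cutoff 35 Å,
  timestep 0.5, friction 0.005–0.01, runs of 3–6 × 10⁴ steps.
* Variant comparisons start from a common micelle-seeded configuration
  (WR cores inward, seed radius 18 Å) built by `micelle_seed_placement()`
  from a collapsed single-chain conformation.  This mirrors the reference
  design, where the mutant run starts from the wild-type phase-separated
  configuration and the readout is retention versus dissolution; de novo
  micelle assembly from dispersed chains is a nucleation process outside
  desk-scale reach.  The retention statistic (`wr_retention()`) is the
  fraction of final-third frames whose largest WR cluster holds at least
  five molecules: near 1 for the wild type, and decaying toward zero for
  W8A over runs of 5–6 × 10⁴ steps.
* Density contrasts compare systems at matched total residue count: the
  Only-CTD comparison uses sixteen 151-residue chains against eight
  305-residue wild-type chains, so peak z-profile bead counts are directly
  comparable (with eight chains of each, the bead totals would differ
  two-fold and "denser" would be ill-posed).
* The single-chain expansion statistic (largest intra-chain residue–residue
  distance) uses one chain in a 700 Å cube for 5 × 10⁵ steps.

What desk scale can and cannot show: stability of a seeded WT micelle, its
CTD < DBD < NTD shell ordering, W8A's weaker core, density contrasts
(Only-CTD denser than WT; 50 mM denser than 125 mM), slower condensed-phase
diffusion, and DNA surface binding are all observable.  Coexistence
quantities — the 7.64 μM dilute-phase concentration, the ≈ 1/10
condensed/dilute diffusion ratio, cluster-size distributions to 70 molecules
— require the cluster-scale systems and are *registered* here as
cluster-scale targets, not asserted by the desk-scale suite.

## Numerical choices and degenerate inputs

Bead overlaps below 0.01 Å raise a singular-distance error rather than
propagating infinities; non-finite coordinates or energies name the step at
which divergence occurred.  `minimize_coords()` (capped steepest descent)
removes placement clashes before dynamics.  Cluster methods are
deterministic; ties in "largest cluster" resolve to the lowest cluster id.
A dilute volume that degenerates to zero flags the frame rather than
dividing by it.  The WR scan requires tandem repeats (≥ 2 windows within one
repeat length of each other) so that an isolated tryptophan outside the
repeat block does not masquerade as a WR; the plain maximal scan and
explicit span lists remain available.

## Known limitations

* Local flexible-chain statistical potentials are replaced by simple bonds;
  single-chain dimensions are therefore only approximately those of the
  reference model, which the ±30 % tolerance on the single-chain expansion
  statistic reflects.
* The synthetic three-helix DBD bundle preserves size and shape, not the
  homeodomain fold; nothing downstream depends on DBD internal structure.
* The phosphate −1 default for phosphoserine is the modest-ionisation
  choice; −2 is exposed but untested against any reference behaviour.
* Desk-scale runs cannot nucleate micelles from dispersed starts, measure
  coexistence concentrations, or converge cluster-size distributions; those
  statements are strictly cluster-scale.
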