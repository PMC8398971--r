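---
title: "Excitonic modelling of G-quadruplex circular dichroism with charge-transfer states"
author: "frdex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitonic modelling of G-quadruplex circular dichroism with charge-transfer states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frdex)
```

## The model

A G-quadruplex (GQ) core is a stack of guanine tetrads: planes of four
guanines held together by cyclic Hoogsteen hydrogen bonds, with consecutive
tetrads ~3.3 A apart.  At such stacking distances an exciton model built
only from local excitations (LEs) with Coulombic couplings -- the Frenkel
Hamiltonian with Coulombic couplings (FHC) -- misses two physical
ingredients: charge-transfer (CT) states between closely stacked bases, and
the perturbation of each base's LEs by its neighbours.  Both shape the
electronic circular dichroism (ECD) spectrum that experimentalists use to
assign GQ folding topologies.

`frdex` implements a fragment-diabatization based excitonic model.  The
basis contains, for every base $m$, its two low-lying $\pi\pi^*$ states
($L_a$, $L_b$), and for every nearest-neighbour pair $(m, n)$ a set of CT
states $\mathrm{CT}_\gamma^{m\to n}$ (electron moved from $m$ to $n$,
orbital pair $\gamma$).  The Hamiltonian splits into an intra-molecular part
(site LE energies and same-site $L_a$--$L_b$ mixing) and an inter-molecular
part (cross-site LE--LE couplings, CT energies, LE--CT couplings on the
hole and electron side, and CT--CT couplings within and across transfer
directions).  Couplings between bases that are not nearest neighbours are
exactly zero; nearest neighbours are the stacked pairs in adjacent tetrads,
the Hoogsteen-bonded pairs within a tetrad, and the "diagonal" partners (a
base with the H-bond neighbours of its stacking partner).

### Fragment diabatization

All energies and couplings come from adiabatic calculations on small
supramolecular complexes (SCs): pairs for the inter-molecular block, and
pairs, strands or tetrads for the intra-molecular block.  Given the overlap
matrix $S = \langle R_\mathrm{frags} | a_\mathrm{SC} \rangle$ between the
fragment reference states and the SC adiabatic states, the diabatizing
transform is the Loewdin symmetric orthogonalization

$$ D = S^\top (S S^\top)^{-1/2}, \qquad H^{(d)} = D^\top H^{(a)} D, $$

with $H^{(a)}$ the diagonal matrix of adiabatic energies.  $D$ has exactly
orthonormal columns and is the closest such matrix to $S^\top$ in Frobenius
norm, so the diabatic states resemble the chosen references as much as an
orthonormal set can.  Transition properties are transformed by the same
matrix.  When the adiabatic data are generated from a known diabatic model
(the synthetic generator below) and no states are truncated, the round trip
recovers the model to machine precision; the test suite asserts this at
$10^{-10}$ for dimensions 4--40.

Practical safeguards: the smallest singular value of $S$ must exceed a
threshold (default $10^{-6}$) or the offending reference state is reported;
per-reference completeness (row norm of $S$) below 0.5 raises a warning,
since a projection that misses half a reference state signals a
too-aggressive truncation of the adiabatic space.  Adiabatic and reference
phases are arbitrary; `fix_phases()` makes each adiabatic column's
largest-magnitude overlap positive (ties resolved towards the lowest
reference index), which leaves every gauge-invariant quantity unchanged and
makes outputs deterministic.

### Which SC parameterises what

Pair SCs (projected onto 40 adiabatic states by upstream convention)
provide the inter-molecular block with either 4 CT states per pair (2 per
transfer direction, the default) or 12 (3 occupied x 2 virtual per
direction).  The intra-molecular block can come from (i) the same pair
blocks, averaging each site's entries over all pairs containing it
(unweighted mean -- also applied to the same-site $L_a$--$L_b$ coupling,
where upstream conventions are silent); (ii) an LE-only projection on a
strand (30 adiabatic states; 50 for 6-base strands of a GQ dimer); (iii) a
tetrad; or (iv) isolated-monomer values.  Strand mode updates both site
energies and same-site couplings by default (`update_couplings = FALSE`
restricts it to energies).

## Spectra

The excitonic Hamiltonian is diagonalized with deterministic conventions:
ascending energies, the largest-magnitude coefficient of each state made
positive, exact degeneracies ordered by the basis index of the leading
coefficient.

Rotational strengths use velocity-gauge electric transition dipoles, which
make the result origin independent.  For state $k$ with coefficients
$C_{ik}$, site positions $r_i$ and basis dipoles $\mu_i$ (electric,
velocity gauge) and $m_i$ (intrinsic magnetic),

$$ R_k \;=\; \Big(\sum_i C_{ik}\,\mu_i\Big) \cdot
   \Big(\sum_j C_{jk}\,\big[m_j + \tfrac{1}{2c}\, r_j \times \mu_j\big]\Big), $$

in atomic units, reported in $10^{-40}$ cgs.  The extrinsic term expands
into the familiar pair form
$\tfrac{1}{2c} C_{ik} C_{jk} (r_i - r_j)\cdot(\mu_i \times \mu_j)$.  A
design choice worth stating explicitly: the prefactor of the extrinsic
magnetic moment is state independent (the transition-energy factor is
regarded as folded into the definition of the velocity-gauge dipoles
supplied by the parametrization).  With this convention two properties hold
*exactly*, not approximately: every $R_k$ is invariant under rigid
translations and rotations of the whole system (translation shifts the
state magnetic moment by $t \times \mu_k^{tot}$, orthogonal to
$\mu_k^{tot}$), and the trace sum rule
$\sum_k R_k = \sum_i \mu_i \cdot m_i$ holds for any Hamiltonian (zero for
vanishing intrinsic magnetic moments -- conservative CD).  Variants that
multiply the extrinsic term by the state energy satisfy these properties
only approximately; since the invariances are the properties the package
promises and tests, the state-independent form is used.  Oscillator
strengths are $f_k = \tfrac{2}{3} E_k |\sum_i C_{ik}\mu_i|^2$ (a.u.).

CT basis states carry the diabatized transition dipoles from their pair
block; if a parametrization omits them, CT states contribute intensity only
through mixing with LEs.

Stick spectra are broadened with energy-domain Gaussians of standard
deviation $\sigma$ = 0.21 eV, after a rigid shift of -0.85 eV -- the shift
that places the computed monomeric 9-methylguanine spectrum on top of the
experimental one, applied uniformly so that geometry effects remain
comparable across structures.  Both are configuration defaults
(`frdex_config()`), not hard-coded.  Amplitudes are area normalized
(halving $\sigma$ doubles an isolated peak).  The default grid is 220--340
nm at 0.5 nm; curves carry their shift/broadening/normalization metadata.
Because absolute ECD intensities are not comparable to experiment without
accurate strand concentrations, curves are in arbitrary units and
`normalize_to_peak()` scales a curve so a chosen extremum (default: the
lowest-energy peak) hits a reference value, storing the factor so sibling
curves can reuse it rather than being re-normalized.  Ensembles of
snapshots are averaged pointwise.

## Geometry

Structures come from (multi-model) PDB files.  Bases are reduced to heavy
base atoms by a per-base atom-name whitelist (guanine: N9 C8 N7 C5 C6 O6 N1
C2 N2 N3 C4), which removes sugars, phosphates, ions and hydrogens by
construction.  Each base can be replaced by a geometry-optimized template
rigidly superposed onto it (Kabsch superposition over name-matched atoms),
removing spurious intra-base distortions from force-field geometries.

Stacking descriptors follow the established 3DNA-style conventions:
the overlap area of two bases is the intersection area of their outlines
projected onto a common plane.  The common plane passes through the
midpoint of the two ring centroids with normal the sign-aligned average of
the two base normals.  (An earlier design fitted one least-squares plane to
the union of both atom sets; for stacked bases the ~3.3 A inter-plane
separation rivals the in-plane extent and the fit can lock onto the wrong
principal direction, so the averaged-normal construction -- symmetric in
the two bases and stable -- is used instead.)  Outlines are the convex
hulls of the projected ring + exocyclic atoms, intersected by exact
Sutherland-Hodgman clipping; nucleobase projections are convex to very good
approximation, and the grid-sampling oracle in the tests agrees with the
exact clipping to well under 1%.  A consequence worth noting: the projected
overlap is exactly invariant to pure vertical rise, so overlap fluctuations
in perturbed ensembles are carried by the in-plane channels (twist, slide,
lateral jitter), while rise fluctuations show up in the centre-of-mass
distances.

Neighbour classification prefers an explicit topology file (tetrads in
cyclic Hoogsteen order plus strands), which is independent of coordinates;
a geometric fallback uses configurable cutoffs (stacked: COM distance <
5 A, inter-plane angle < 30 deg, out-of-plane offset > 2 A; H-bonded:
coplanar within 1.5 A, COM distance < 9 A, at least two N/O contacts <
3.5 A) and derives diagonal pairs by composing the stacked and H-bonded
relations.  A pair matching both stacked and H-bonded criteria is reported
as an error rather than silently resolved.  On ideal geometries the two
modes agree exactly.

## The synthetic generator

Quantum-chemistry parametrization is upstream of this package.  To make
every step testable offline, the generator builds (i) idealized tetrad
stacks (template guanines at a configurable radius with O6 pointing inward,
related by rise/twist/slide), (ii) monomer transition data, and (iii)
internally consistent SC adiabatic data: it diagonalizes a known "true"
diabatic Hamiltonian and emits exactly what an electronic-structure step
would -- the eigenvector overlap matrix, adiabatic energies and transformed
properties -- so diabatization must reproduce the truth.

Generator defaults are physically plausible for guanine but are *generator
settings, not reference quantum-chemistry values*: $L_a$ 5.30 eV /
$L_b$ 5.58 eV (which, after the -0.85 eV shift, place the band at ~280/260
nm), velocity-gauge dipole magnitudes 1.0 / 0.65 a.u. at fixed in-plane
angles, zero intrinsic magnetic moments (so the generated CD is exactly
conservative), and a same-site $L_a$--$L_b$ mixing of 12 meV standing in
for the environmental perturbation.  Atomic transition charges are the
minimum-norm solution reproducing the requested dipole with zero net
charge, so transition-charge Coulomb couplings are consistent with the
dipoles by construction.  The CT model is deliberately simple and flagged
as synthetic: $\epsilon_{CT}(R) = 5.90 + 2.0\,(R - 3.4)$ eV on the
donor--acceptor COM distance, orbital pairs staggered by 0.15 eV, LE--CT
couplings $0.12\,e^{-(R - 3.4)/0.6}$ eV with deterministic sign patterns
(electron-side reduced by 0.7), CT--CT couplings 50/30 meV.  The linear
distance dependence encodes the mechanism under study -- closer stacking
stabilizes CT states and strengthens their coupling to the LEs -- and the
package's analysis reproduces it: across a series of stacks with shrinking
rise (and twist, so the projected overlap grows too) the CT weight of the
lowest excitonic state rises monotonically.  That is a property of the
generator's model, reported as a paired overlap/composition table; the
package asserts nothing about real systems.

MD-like ensembles perturb the per-interface helical parameters and add
small rigid per-base jitter under a single seeded RNG stream; the same spec
and seed reproduce outputs bitwise.

What passing tests do and do not show: they establish that the
diabatization, assembly, spectra and analysis machinery is exact and
self-consistent, and that the geometry descriptors behave correctly on
realistic shapes.  They do not validate any electronic-structure quality --
real parametrizations enter through the interchange JSON (schema in
`inst/schema/`), and the spectra are only as good as those inputs.

## Numerical choices and degenerate inputs

* Units: Hamiltonians in eV, dipoles in a.u., coordinates in Angstrom; all
  conversions through one constants table (`frdex_constants()`).
* Singular-value threshold for $S S^\top$: $10^{-6}$ (configurable);
  rank-deficiency is an error naming the dominant reference state.
* Eigenvector phases and degenerate-state ordering are fixed
  deterministically (largest coefficient positive; ties by leading basis
  index), so eigenvector files are comparable across runs.
* The Frenkel limit of the CT-capable model (`decouple_ct()`) zeroes the
  LE--CT couplings *and* shifts CT energies by $10^6$ eV.  Shifting alone
  leaves first-order mixing of order $V/\Delta$ and -- less obviously --
  degrades the eigensolver's absolute accuracy by
  $\varepsilon_\mathrm{mach}\cdot\Delta$ ($\approx 2\times 10^{-10}$ eV at
  $\Delta = 10^6$), which already shows up in tight curve comparisons;
  zeroing the couplings realizes the decoupled limit exactly.
* PDB coordinates carry three decimals; quantities recomputed after a file
  round trip agree with exact-geometry quantities to that precision, not to
  machine precision.  Tests distinguish the two regimes.
* Kabsch superposition rejects point sets with fewer than 3 points or
  collinear configurations; plane fitting rejects collinear rings;
  zero-separation dipoles and coincident atoms across sites are errors.

Problem sizes in the shipped tests and acceptance script are chosen for
exactness rather than scale: diabatization up to dimension 40, full
pipelines on 3-tetrad (12-guanine, 168 basis states) and 6-tetrad
(24-guanine) stacks, 1000-matrix orthonormality sweeps, 50-pair geometry
oracles.  The complete suite runs in well under a minute.

## Known limitations

* No vibronic structure, temperature-dependent broadening or magnetic CD;
  the Gaussian broadening is phenomenological.
* No polarizable-embedding corrections to couplings; no three-body SCs
  beyond LE-only strand/tetrad projections.
* CT states are attached to all nearest-neighbour classes by default
  (restriction to stacked pairs is a config switch); whether H-bonded and
  diagonal pairs should carry CT states is a modelling choice the upstream
  parametrization must support either way.
* The base outline is a convex hull; genuinely concave outline effects in
  the overlap area are below the 1% level for purine/pyrimidine shapes but
  are not represented exactly.
* Only PDB input is supported for structures (models as snapshots); no
  trajectory formats.
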