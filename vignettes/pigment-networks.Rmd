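---
title: "Pigment networks in antenna supercomplexes: models, conventions and limits"
author: "PigmentNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pigment networks in antenna supercomplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PigmentNet)
```

# The problem

Under iron stress, cyanobacteria surround photosystem I (PSI) with rings of
the CP43-like antenna protein IsiA. In the largest assemblies a trimeric PSI
core is enclosed by a closed double ring — 18 inner plus 25 outer IsiA
protomers, each binding 17 chlorophyll a (Chl a) and 4 carotenoids — while a
monomeric form carries an open double layer of 6 + 7 protomers. The
functional question is how excitation energy collected by several hundred
antenna chlorophylls funnels across the ring–ring interface into the core.
Given an atomic model, that question reduces to geometry: where each
chlorophyll sits relative to the membrane, which protomer and ring it belongs
to, which chlorophyll pairs bridge subunit interfaces, and how fast Förster
transfer across each pair would be.

PigmentNet implements that analysis as a pipeline of testable stages, plus a
synthetic-complex generator so every stage can be validated desk-scale
against known ground truth, without downloading deposited coordinates.

# The model

## Transition dipoles and the orientation factor

The Qy transition dipole of Chl a is approximated by the unit vector along
the NB→ND axis of the chlorin ring,
\(\hat u = (\mathbf{x}_{ND}-\mathbf{x}_{NB})/\lVert\mathbf{x}_{ND}-\mathbf{x}_{NB}\rVert\).
The sign of this axis is a convention; every downstream quantity depends on
it only through the orientation factor

\[
\kappa^2 = \left[\hat u_D\cdot\hat u_A -
  3\,(\hat u_D\cdot\hat R_{DA})(\hat u_A\cdot\hat R_{DA})\right]^2 ,
\]

which is invariant under flipping either dipole and under exchanging donor
and acceptor. \(\hat R_{DA}\) is the unit vector between the central Mg
atoms. \(\kappa^2\) ranges over \([0,4]\): 4 for collinear head-to-tail
dipoles, 1 for parallel dipoles perpendicular to the axis, 0 for mutually
orthogonal arrangements, and an isotropic average of \(2/3\) — all of which
the test suite asserts, the last by Monte Carlo.

## Pairwise Förster rates

Each chlorophyll pair gets the point-dipole Förster rate

\[
k_{\mathrm{FRET}} = \frac{C\,\kappa^2}{n^4 R^6},
\qquad C = 32.26,\quad n = 1.55,
\]

with \(R\) the Mg–Mg distance. The constant \(C\) subsumes the Chl a → Chl a
spectral overlap; \(n\) is the medium refractive index. **Units:** the
sources that use this parameterization do not state the unit of \(R\); this
package fixes \(R\) in nanometres, which makes rates come out in ps⁻¹ and
lifetimes \(\tau = 1/k\) in ps. The choice is not arbitrary: at
\(\kappa^2 = 1\), \(R = 2.0\) nm the rate is \(32.26/(1.55^4\cdot 2^6)
\approx 0.0873\) ps⁻¹, i.e. \(\tau \approx 11.45\) ps, and typical
neighboring-pair distances of 10–23 Å then give lifetimes of roughly 1–30 ps
— exactly the scale on which the published 40 ps display filter and 20 ps
"fast pathway" filter operate. Any other unit choice would make those
filters vacuous or all-inclusive.

The lifetime of a pair with \(\kappa^2 = 0\) is reported as `Inf`, never
dropped silently. Because a single \(C\) is used for both directions, rates
are donor/acceptor symmetric and the network stores each pair once as an
undirected edge; the outer→inner table orients edges by ring membership, not
by kinetics.

What this deliberately is **not**: no exciton coupling, no back-transfer or
master-equation kinetics, no spectral-overlap computation from measured
spectra, and no multi-step effective lifetimes. "Lifetime" always means the
single-pair quantity \(1/k\).

## Membrane frame and sidedness

Deposited models carry no membrane. The membrane normal is estimated as the
direction of least spread (smallest principal component) of the chlorophyll
Mg cloud, which works because antenna and core pigments lie in a slab
parallel to the membrane. The sign is fixed so that the centroid of the
cytoplasmic extrinsic subunits (PsaC/PsaD/PsaE by default) projects
positive; models lacking markers must declare a cytoplasmic point.

The midplane that separates "cytoplasmic" from "lumenal" pigments is not
stated by any source; this package's convention is: project all chlorophyll
Mg onto the normal, split the projections with a deterministic 1-D two-means
partition, and put the midplane at the midpoint of the gap between the two
clusters. The rule is seed-free and deterministic, and it is exact when the
pigment arrangement is cleanly two-layered, as it is in these complexes.
Ties (a pigment exactly on the midplane) go to the cytoplasmic side. On the
synthetic double ring this reproduces the 473/258 cytoplasmic/lumenal split
exactly; on a real deposit the counts are a soft target and a deviation of
more than a few pigments should trigger a review of the midplane convention.

## Ring assignment and angular indexing

Antenna protomers are split into inner and outer rings by the largest gap in
their sorted radial distances from the central axis (the membrane normal
through the centroid of the *antenna* chlorophylls — core pigments are
excluded because they would bias the centroid off the ring axis). If the
radial spread is below `min_gap` (default 5 Å) the result is flagged as a
single ring rather than raising an error. For open arcs (the monomeric
double layer) the pigment centroid is not the arc center and the gap split
is unreliable; pass explicit ring lists (`rings =`) in that case — the
generator's ground truth or a deposit's annotations supply them.

Ring indices run anticlockwise as viewed from the lumenal side (implemented
as increasing angle about the negated normal), starting at the protomer
nearest the PsaK pole, matching the field's i-1…i-18 / o-1…o-25 naming.
An explicit `reference_chain` overrides the PsaK rule.

## Interfacial pairs

Chlorophyll pairs from *different* subunits with Mg–Mg distance ≤ 23 Å are
interfacial; pairs strictly under 18 Å are additionally highlighted. The
boundary semantics mirror the reporting convention ("≤ 23 Å", "under
18 Å"): inclusive at the pair cutoff, exclusive at the highlight cutoff.
Categories distinguish inner↔outer interface pairs, core↔inner pairs and
everything else; none of this depends on dipole orientation.

## Structure comparison

Two models are superposed by least-squares (Kabsch) on the Cα atoms of a
reference core subunit — PsaA, matched by residue number; reflections are
rejected. When the reference occurs in several copies (a trimeric core),
every chain pairing is tried and the best-RMSD pairing wins unless chains
are named explicitly. Per-protomer displacement of matched subunit
centroids is decomposed into a signed vertical component along the membrane
normal (+ = cytoplasmic) and an in-plane residual, with
\(total^2 = horizontal^2 + vertical^2\) by construction. Ring rotation is
the 2-D orthogonal Procrustes angle of the in-plane centroid projections,
signed with the same lumenal-view convention; the mean per-subunit angular
offset is attached as an attribute because the published "≈5°" could have
been measured either way — the two agree to well under a degree on rigid
rotations. Shift summaries report both the maximum and the mean over the
compared subunit set.

The vertical curvature profile (per-protomer vertical offset against
angular position, relative to the core centroid) is reported per ring as a
peak-to-peak amplitude. One caveat the tests encode: a \(\cos\theta\)
vertical modulation across a ring is nearly indistinguishable from a rigid
tilt, so the PCA-estimated membrane normal absorbs most of it; curvature
should be measured against an independently fixed frame when one exists.

# The synthetic generator: a stated world

`generateComplex()` builds pseudo-complexes whose defaults are the published
architecture, not tuning knobs: 18 + 25 protomers (trimer preset) or 6 + 7
(monomer preset), 17 Chl a and 4 carotenoids per protomer, and a per-layer
allocation of 11 cytoplasmic + 6 lumenal chlorophylls — the published
473/258 sidedness split equals exactly 43 × 11 / 43 × 6, so the allocation
is implied rather than chosen. Values the sources do not state were fixed
once at field-realistic magnitudes and are not revisited: ring radii
110/155 Å (overall diameter ≈ 380 Å), chlorophyll layers at ±9 Å about the
membrane midplane, NB–ND span 4.2 Å (the chlorin N–N scale; any positive
constant gives the same unit dipole), Cα pseudo-traces sufficient for
centroids and superposition, and 96 chlorophylls per core copy.

Within a protomer, chlorophylls sit on a deterministic polar layout in
which the interface-facing residue numbers match the field's naming: 506,
516, 517 on the outward face of inner-ring protomers and 504, 508, 510, 519
on the inward face of outer-ring protomers. With the default tangential
dipole rule, the fast inner↔outer pathways that emerge are therefore
carried by the published donor/acceptor chlorophyll numbers (508→516,
508→517, 510→506, …) — by construction, which is what makes the qualitative
acceptance check on the stand-in meaningful.

What the generator does *not* emulate: real protein geometry, heterogeneous
per-pigment dipole tilts, resolution-limited coordinate error (available
only as isotropic Gaussian noise), partial occupancy, and the asymmetric
protomer packing of real outer rings. A green test on synthetic data
therefore establishes the correctness of the *computation* — extraction,
classification, rates, superposition — not the accuracy of any biological
claim about a particular deposit.

Determinism: with zero noise the generator is fully deterministic; with
noise, all randomness flows through the spec's `seed`, restoring the
caller's RNG state afterwards.

# Numerical choices and degenerate inputs

- Chlorophylls missing MG/NB/ND atoms are an error naming the pigment;
  `on_missing_dipole = "skip"` downgrades to a warning, never a silent drop.
- Coincident Mg atoms and zero-length donor–acceptor vectors are errors, as
  are NB = ND (degenerate dipole).
- Multiple conformers: the first (altLoc ' '/'A', mmCIF '.') is kept with a
  warning.
- Coordinates stay in Å as deposited; only the rate expression converts to
  nm internally.
- PDB output is refused (with an mmCIF fallback and warning) when chain ids
  exceed one character or coordinates overflow the fixed-width fields —
  the 52-chain synthetic trimer always takes the mmCIF path.
- Fewer than 3 chlorophylls cannot define a membrane frame; fewer than 3
  matched Cα cannot define a superposition; fewer than 2 matched subunits
  cannot define a ring rotation. All are errors, not guesses.
- The two-means midplane split is deterministic (initialized at the range
  endpoints), so sidedness never depends on a seed.

# Design decisions that were genuinely open

- **Subunit roles come from configuration**, not sequence detection:
  deposits differ in chain labelling, and wiring roles through
  `namingConfig()` keeps the parser honest about what it cannot know.
  Likewise ligand codes: Chl a defaults to `CLA`, carotenoids to `BCR`,
  both extendable.
- **Axis center for ring splitting** uses the antenna chlorophyll centroid
  rather than all chlorophylls; core pigments would drag the centroid off
  the ring axis in small or asymmetric fixtures.
- **Monomer-to-trimer comparison** defaults to the best-RMSD core copy as
  the alignment target, since the published comparison aligned against each
  of the three cores and reported the informative one.
- **Edges are stored undirected** (single spectral constant); a directed
  representation would double the storage to encode no extra information.
  Asymmetric constants, if ever needed, belong in `FretParameters`.
- **Pairs beyond the geometric cutoff are excluded from the network**, not
  computed and hidden; `all_pairs = TRUE` provides the dense matrix for
  diagnostics.

# Known limitations

- Point-dipole Förster theory with a fixed \(C\) is a screening-level model;
  at sub-10 Å separations orbital overlap and exciton effects make the
  pairwise rate qualitative.
- The 473/258 sidedness convention, while exact on the synthetic world, is
  this package's operationalization of an unstated criterion; real-deposit
  counts within a few pigments of the published split should be considered
  consistent.
- Ring auto-assignment assumes closed, roughly concentric rings around the
  pigment centroid; open arcs need explicit ring lists.
- Multibody displacement amplitudes and all spectroscopic/AFM observables
  require particle stacks or raw measurements and are out of scope; the
  pipeline neither computes nor reports them.

# A worked run

```{r example, eval = FALSE}
gen <- generateComplex(syntheticComplexSpec("trimer"))
out <- tempfile("run")
summary <- runPipeline(runConfig(gen$model, outdir = out))
summary$antenna_chlorophylls   # 731
summary$sidedness              # cytoplasmic 473 / lumenal 258
summary$n_inner; summary$n_outer   # 18 / 25
```

Every number above is recomputed by the test suite and by
`scripts/acceptance.R`; this vignette states no result the code does not
itself produce.
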