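---
title: "Analysing pentameric beta-bracelet viral fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing pentameric beta-bracelet viral fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentafiber)
```

# The system

The delta proteins of the Orsay-like nematode viruses (Orsay, Santeuil,
Le Blanc) form pentameric fibers that attach to the viral capsid as a
head fiber through a CP-delta read-through fusion and mediate host-cell
attachment. The shaft of the fiber is built from a distinctive period-8
structural repeat, the *beta-bracelet*: five five-residue beta-strands,
one from each chain, close into a small right-handed beta-barrel ring,
and successive rings are connected by three-residue loops. One repeat
therefore spans eight residues per chain, and the repeat carries a
strong sequence signature that can be scanned for directly.

`pentafiber` implements the quantitative analyses this architecture
invites, in five parts: a deterministic consensus scanner with heptad
register assignment and domain segmentation; an additive model of total
fiber length; geometry of five-fold-symmetric coordinates; calculators
for assembly biochemistry; and seeded generators that plant known
ground truth for every stage.

# The consensus scanner

## The motif model

The strand consensus is `(V/L) x x V x x x x V` over nine positions,
where the ninth anchor is the first position of the next repeat, so the
true period is eight. The loop consensus is `y m y` at positions 6-8,
with `y` a charged residue and `m` one of E/D/N. The x positions are
*tendencies* (often small, polar or charged) and are deliberately left
unconstrained: enforcing a preference as a rule would reject genuine
repeats. Two modes are provided:

* **strict** — P1 in {V, L}, P4 = V, loop flank in {D, E, K, R, H},
  loop middle in {E, D, N}. This is the signature of the
  crystallographically observed repeat region.
* **relaxed** — P1/P4 from a generic hydrophobic class
  {A, V, L, I, M, F, W, Y, C} (the "phi" form of the consensus) and a
  widened loop middle (flank residues plus N, Q, S, T). This matches
  the more variable downstream repeat region.

The class tables are constructed so every strict match is a relaxed
match; `residue_classes()` enforces this nesting at construction, and a
property test checks it on random sequences.

## Runs, the trailing anchor, and truncation

`scan_repeats()` reports *runs*: maximal chains of repeats spaced
exactly eight residues apart, each matching all constrained positions
of its mode. One design point deserves emphasis: a repeat's own window
is eight residues, and the ninth-position anchor is enforced only
implicitly, as the next repeat's P1 for internal repeats of a run. The
residue *after* a run's last repeat is never constrained. This is the
only reading consistent with a repeat region that simply stops at a
domain boundary: in the delta protein the strict consensus ends at
residue 102 with non-consensus sequence following, yet the final repeat
(residues 95-102) is unambiguously part of the crystal structure.
`match_repeat_window()` still scores a ninth residue when one is
supplied, because as a standalone window operation the printed
nine-position consensus is the natural contract.

A terminal repeat whose five-residue strand fits before the sequence
end but whose loop is cut off is counted, with its loop recorded as
absent — but only as the continuation of a run whose previous repeat
was complete. A standalone strand-only match constrains just two
positions and is too weak to count as evidence of a repeat.

`min_run` defaults to 2 for de-novo scanning (an isolated period-8
match occurs by chance in unrelated sequence) and should be set to 1
when annotating a region already known to contain repeats. When
candidate runs on different lattices overlap, the longest run wins,
ties broken by the smaller start index — a deterministic rule that a
brute-force enumeration oracle reproduces in the tests.

Emitted repeats carry a `score`: the strict-consensus score of the
window. Strict-mode repeats therefore always score 1.0, and the score
of a relaxed repeat measures how close it is to the strict signature.

## Heptad register

The fiber's N-terminal domain is an alpha-helical coiled coil whose
second helix is kinked by a single-residue insertion in the heptad
repeat. `assign_heptad()` chooses, by exhaustive search over the seven
register phases and all single insertion points, the assignment
maximising the number of `a`/`d` positions holding hydrophobic residues
(positive Kyte-Doolittle hydropathy, excluding alanine, which is so
common that counting it blurs the seam; the summed hydropathy breaks
ties). An insertion is reported only when it improves the a/d count by
at least `margin` (default 2) — one extra residue should not be invoked
unless both flanks of the kink realign. Within a homopolymer stretch
the insertion point is identifiable only up to register equivalence;
the leftmost equivalent position is reported.

## Domain segmentation

`segment_domains()` assembles the five-domain picture of a delta-like
sequence: coiled coil, first (strict) bracelet region, internal
globular domain, second (relaxed) bracelet region, C-terminal globular
head. The first bracelet region is the envelope of the strict repeats;
the second is the envelope of relaxed repeats downstream of it; the
globular domains are the gaps. The relaxed region is reported as runs
with unlabelled inter-run gaps — the analysis does not force a
predetermined segment count onto it, because the spacing of the
downstream repeats (loops of various lengths) is not knowable from the
consensus alone.

# The additive length model

Total fiber length is modelled as

```
L = L_crystal + n_segments * h_segment + d_internal + d_head
```

with `h_segment` defaulting to 15 Å — the rise observed in the crystal
fragment, where five repeats cover ~75 Å. For the Orsay architecture
(145 Å crystal region, 11 extra segments, 30 Å internal globule, 50 Å
head) the model gives 390 Å, against a measured fiber length of
419 ± 36 Å. `infer_segment_count()` inverts the model and always
reports the real-valued count next to its rounding: a count inferred
from an EM length is an estimate, and rounding silently would overstate
it. Whether the internal globule term belongs in the sum for the
Santeuil and Le Blanc fibers, which show no internal globule in EM
despite carrying the corresponding sequence, is left to the caller:
`d_internal` is an explicit component, not a hidden constant.

`residues_per_height()` registers the residue economy of the three
fibrous beta-folds: to span 15 Å one chain must contribute 8 residues
in a pentameric beta-bracelet, 17 in a trimeric beta-spiral, 31 in a
triple beta-helix. The beta-bracelet buys the most length per residue.

# Coordinate geometry

## Axis fitting

`fit_cyclic_axis()` extracts the C5 axis from the five rigid rotations
superposing each chain onto its cyclic neighbour (Kabsch on matched
residue numbers), rather than from an inertia tensor: for a short fiber
the inertia tensor's principal direction is easily dominated by shape
accidents, while the pairwise rotations directly certify the symmetry —
every pair must rotate by 72° within `angle_tol` (default 5°), and a
violation is an error, not a warning. The reported
`mean_rotation_error` is the mean Cα RMSD of the superpositions. Chains
that are straight lines are rotationally featureless and cannot be
fitted this way; such degenerate models need an externally supplied
axis frame.

## Derived measurements

* `rise_per_repeat()` projects per-repeat Cα centroids onto the axis
  and reports the mean consecutive spacing; `covered_length` adds one
  mean rise for the terminal unit, so five repeats at 15 Å rise cover
  75 Å.
* `strand_tilt()` fits a principal line through each strand's Cα and
  reports the acute angle to the axis (≈45° for bracelet strands, ≈90°
  in beta-helices, 0° for an axis-parallel helix).
* `radial_profile()` bins atoms axially and reports radius statistics;
  diameters are twice the radii, and the `atoms` selector reproduces
  main-chain versus all-atom measurements. The channel radius is the
  minimum atom-centre radius minus an explicit probe allowance
  (default 1.4 Å, a water radius), floored at zero — channel diameters
  are method-dependent, so the probe is part of the output metadata
  rather than buried in the code.
* `mainchain_hbonds()` uses a geometric criterion — N···O ≤ 3.5 Å and,
  when the amide hydrogen is inferable from the backbone, an N–H···O
  angle ≥ 120° — rather than an energy function; for a census of who
  bonds whom, DSSP-style energetics add parameters without adding
  information. Cα-only models fail loudly here; everywhere else they
  are fully supported.
* `inward_facing_residues()` classifies side chains by the radial
  component of the Cα→Cβ vector, reconstructing a pseudo-Cβ from the
  backbone where needed; glycine is `undetermined`.

All measurements are equivariant under rigid-body transforms of the
input, which the tests verify with random rotations and translations.
Radial-profile *bins* are anchored to the fitted frame, so individual
bins shift under a transform; bin-independent summaries (atom-weighted
mean radius, radial extremes) are the invariant quantities.

# Assembly biochemistry

* `assign_oligomer_state()` picks the multimer order k minimising
  |observed − k·monomer| up to `k_max`, ties to the smaller k
  (parsimony). For the Santeuil monomer mass of 36,961.6 Da the
  pentamer is 184,808.0 Da, 16.5 Da below the observed 184,824.5 Da;
  the Le Blanc fiber assigns to a pentamer the same way.
  `peak_deviation()` reports minor-peak offsets in Da and percent (two
  decimals, the precision the measurement supports); the chemical
  identity of such offsets is not assigned.
* `estimate_fiber_stoichiometry()` assumes band intensity proportional
  to protein *mass* — standard densitometry physics — so intensities
  are divided by molecular weight before forming the molar ratio r.
  CP-delta competes with CP for the 180 quasi-equivalent positions of
  the T=3 lattice, giving `copies = 180·r/(1+r)` and fibers =
  copies/5. The estimate is scale-invariant in the intensities and
  monotone in the CP-delta band, and the across-replicate SD is
  reported because replicate variation is the only dispersion the data
  offer.
* `particle_stats()` turns particle counts and length lists into the
  fiber-bearing fraction and length mean ± SD (sample SD).

# The synthetic-data generators

Every generator takes a seed and returns its planted truth; identical
seed and parameters give bit-identical output, including written files.

`gen_repeat_sequence()` emulates the delta domain organisation:
ideal-heptad coiled-coil stub, strict periods, non-matching spacer,
relaxed periods, non-matching tail. Spacer and tail residues come from
{G, P, N, Q}, an alphabet outside every anchor and loop-flank class, so
any window overlapping them fails at a constrained position — the
planted repeats are provably the only matches, which the tests confirm
by scanning. The default domain lengths (coiled coil 62, spacer 43,
relaxed span 104, tail 97, with 5 strict and 11 relaxed periods)
reproduce the canonical boundaries 1–62 / 63–102 / 103–145 / 146–249 /
250–346. Because 11 relaxed periods occupy only 88 of the 104 residues,
the surplus is distributed as non-matching linkers between segments —
repeats separated by loops of various lengths — so each relaxed segment
is found as its own run.

`gen_pentamer_coords()` builds five chains related by exact 72°
rotations about z. Strand Cα sit *on* the cylinder of the requested
radius, along a helical arc whose local direction makes the requested
tilt with the axis; loops sit at the loop radius. The Cα spacing
defaults to 1.9 Å — deliberately compact and non-physical — so that the
chord of the arc (what a principal-line fit measures) stays within the
recovery tolerances of the nominal tilt across the tested grid; at a
physical 3.3 Å spacing the arc curvature at small radius and high tilt
would bias the chord by several degrees. The optional pseudo-backbone
places N, C, O at ideal bond lengths purely so the hydrogen-bond census
has atoms to count; it is flagged non-physical in the truth record.

The mass, gel and EM generators are direct parametric emulations:
peaks at k·monomer plus adduct offsets; intensities obtained by
inverting the stoichiometry formula and multiplying by mean-preserving
log-normal noise of a given CV; Gaussian lengths truncated at zero by
resampling.

What the generators do *not* emulate matters for interpreting green
tests: real sequences contain near-miss windows and compositional
drift, real coordinates have correlated (not isotropic) errors, real
mass spectra have charge-state artefacts, and real densitometry has
baseline and saturation effects. Passing the recovery suites shows the
estimators are correct and well-conditioned under the stated noise
models, not that they are robust to every failure mode of real data.

# Numerical choices and problem sizes

Tolerances used by the recovery tests follow the dispersion each
estimator actually shows under the stated noise: over the grid of rise
{10, 15, 20} Å × tilt {30, 45, 60}° × radius {5, 6, 8} Å with 0.3 Å
coordinate noise, rise is recovered within 5%, tilt within 3°, the
strand radius within 0.5 Å, and the C5 angle within 1°. The strand
radius is read from the profile as the innermost bin mean among bins
holding at least 10 atoms, which keeps sparse edge bins from dominating
the estimate. Test problem sizes — four-to-five-repeat pentamers
(160–200 residues), sequences of a few hundred residues, 20–60-mer
oracle comparisons, 200-sample length distributions — are chosen so the
full suite exercises every code path in seconds while leaving the
statistical assertions well-powered.

Degenerate inputs are handled explicitly rather than by accident: two
repeats give a rise with no SD; strand spans with fewer than three
distinct points are skipped with a warning; empty profile bins are
absent rather than zero-filled; a sequence with no repeats segments
into a warning plus empty bracelet regions; an observed mass below half
a monomer has no valid oligomeric state.

# Limitations

The scanner is the deterministic consensus, not a trained profile; it
will not find bracelet repeats whose anchors fall outside the residue
classes, and x-position preferences are not scored at all. The length
model is additive and straight — fiber bending is not modelled. Axis
fitting requires comparable residue numbering across chains and fails
on rotationally featureless (collinear) chains. The hydrogen-bond
census infers amide hydrogens geometrically and skips residues with
incomplete backbones. The stoichiometry calculator inherits the
linearity assumption of densitometry and the T=3 subunit count; both
are explicit arguments, not facts the package asserts about your gel.
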