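---
title: "Model and methods: event-driven dynamics of a four-sphere peptide model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`primedmd` simulates peptide aggregation with an intermediate-resolution
protein model of the PRIME20 family. Each residue is four spheres — the
backbone united atoms NH, CaH and CO plus a single side-chain sphere —
except glycine, which has no side sphere. All interactions are piecewise
constant in distance: hard cores, distance windows (bonds), square wells
and double square wells. Because potentials are discontinuous, the dynamics
is event-driven: spheres fly ballistically between analytically predicted
discontinuity events, and each event applies an impulse along the line of
centres that conserves momentum exactly and energy exactly (well crossings
convert potential to kinetic energy and vice versa; under-powered escape
attempts reflect).

Units: energy in the hydrogen-bond well depth (`eps_HB = 1`), temperature
as `T* = kB T / eps_HB`, mass in CH3 units (15 amu), length in Angstrom.
Reduced time is `t* = t / sigma * sqrt(kB T / m)` with `sigma` and `m` the
NH-sphere diameter and mass.

## Covalent structure

Backbone bond lengths (NH-CaH 1.46 A, CaH-CO 1.51 A, CO-NH 1.33 A) and
three pseudo-bonds per residue (NH-CO 2.45 A, CaH-NH' 2.41 A, CO-CaH'
2.45 A) fix the backbone geometry up to the phi/psi torsions; the peptide
bond is held trans. Each bond is a hard distance window with fractional
half-width ±2.375% around the nominal length. The side sphere is pinned by
three distances, to CaH (per-residue) and, derived from ideal bend angles,
to NH and CO.

### Chirality

The side sphere's three distance constraints admit two mirror-image
solutions. The packaged convention labels L the arrangement with positive
scalar triple product of the CaH-to-NH, CaH-to-CO and CaH-to-side vectors.
Whether dynamics can convert L to D is a question of connectivity in
configuration space: the flip requires an instant at which the four spheres
of a residue are exactly coplanar, and whether coplanarity is reachable
depends on the window widths. A numerical feasibility study (minimising,
over all coplanar configurations, the largest fractional strain across the
six intra-residue distances) showed that at a uniform ±2.375% several
residues can reach coplanarity with at most ~2.1-2.4% strain — i.e. the
mirror flip is *legal* — and flips were indeed observed in test runs. The
side-sphere windows are therefore tighter, ±1.25% by default: at that width
every residue's coplanar transition state requires at least ~1.4x more
strain than the windows allow, so handedness is conserved by the exact
dynamics alone, with no auxiliary constraint force. The independent
triple-product validator is run over sampled frames in the test suite.

## Interaction tables

All pair interactions are classified once per system into dense tables
shared by the configuration generator, the geometry validator and the
engine:

* **Bonded windows** as above.
* **Hard cores** between all other sphere pairs at the sum of radii
  (backbone diameters 3.3/3.7/3.5 A; per-residue side diameters). Local
  pairs (same or adjacent residue, and side-side pairs within two
  residues) use 75% of contact, and the five squeeze distances per residue
  (side sphere to CaH/CO of the previous residue, NH/CaH of the next, and
  CO two back) override the local cores, shaping realistic local geometry.
* **Side-chain double wells** for side-sphere pairs on different chains or
  at least three residues apart: a deep inner well (1.3x the base pair
  energy, diameter from the 4.5 A heavy-atom criterion) inside a shallow
  outer well (0.7x, 5.5 A criterion). The lysine-aspartate salt bridge is
  0.136 eps_HB in the original parameterisation and 0.4 eps_HB when the
  enhanced option is active (the default), reflecting the salt bridge's
  role as a rate-limiting native contact in amyloid assembly.
* **Hydrogen bonds**: an NH-CO square well of depth exactly 1 eps_HB at
  diameter 4.2 A, gated by four auxiliary distances (N_i-Ca_j, N_i-N_(j+1),
  C_j-Ca_i, C_j-C_(i-1)). Two cutoff sets ship: the `original` directional
  set (5.00, 4.74, 4.86, 4.83 A) and the `parallel_preference` set (5.10,
  4.54, 4.96, 4.58 A) that biases bonding toward parallel in-register
  beta-sheets. Formation is checked instantaneously when the pair crosses
  the well diameter inward; an ineligible crossing is transparent. While a
  bond is active the four auxiliary pairs are confined below their cutoffs
  by hard walls, released on breaking; the impulse at formation and
  breaking acts only along the NH-CO line (the auxiliary spheres receive
  no impulse at that instant — a modelling choice, as the event-level
  treatment of the auxiliary partners is not uniquely determined by the
  constraint picture). Intra-chain bonds are forbidden below a sequence
  separation of three residues; inter-chain bonds are unrestricted. Each
  NH and each CO holds at most one bond.

## Parameter provenance

The backbone and side-sphere masses, the 1.3/0.7 double-well multipliers,
the salt-bridge strengths, and both auxiliary cutoff sets are published
constants and are asserted exactly in the test suite. The remaining
numerical tables shipped as defaults — per-residue side-sphere geometry
(`dr_ca` and the derived NH/CO pseudo-bonds), side diameters, squeeze
distances (80% of contact), the inner/outer well diameters (contact +1.2 A
/ +2.4 A) and the full pairwise energy matrix (a hydrophobicity product
scaled so that eps(F,F) = 0.205, with opposite-charge pairs at the
published 0.136 and a small like-charge repulsive shoulder) — are
*synthetic estimates*, marked as such in their file names and headers, and
user-overridable through plain-text tables of the same layout. Masses for
C, W and P, absent from the published list, follow the same side-chain
mass / 15 amu rule that reproduces the published values for the other
residues. `derive_well_diameter()` implements the strict-majority
heavy-atom criterion for sizing wells from structural survey distances;
its summary statistic defaults to the maximum of qualifying centroid
distances (the well must enclose every observed contact geometry), with a
quantile option.

# The engine

Event prediction for a pair reduces to the earliest positive root of
`|r + v t| = d` over that pair's surfaces under the minimum-image
convention. The engine keeps one pending event per nearby pair in a binary
heap; per-sphere modification counters stamp events at scheduling and any
stamp mismatch at pop time discards the event. After each executed event
the two (for hydrogen-bond events, six) affected spheres are re-predicted
by a direct scan over all partners:

* pairs within interaction range get exact surface predictions, capped at
  the time their minimum image would change (a no-op refresh event
  re-predicts them there);
* all farther partners fold into a single per-sphere *rescan* event at a
  provable lower bound on their first possible contact time — the gap to
  interaction range divided by the current relative speed (the
  minimum-image distance is 1-Lipschitz in the relative displacement, and
  relative velocities only change at events, which trigger fresh scans).

This direct-scan design replaces the cell-list machinery conventional in
large event-driven simulations; at the package's target scale (tens to a
few hundreds of spheres per run) it is both simpler and faster, and it is
exact — no event can be missed. Positions advance synchronously at each
event; when the executed pair's distance deviates from its surface by more
than 1e-9 A it is re-projected onto the surface (in practice this does not
trigger: the audit counter in the return value reports zero).

Temperature control is an Andersen-style thermostat: ghost collisions
arrive as a Poisson process in time (default rate 0.1 per sphere per
internal time unit) and resample one uniformly chosen sphere's velocity
from the Maxwell-Boltzmann distribution at the instantaneous scheduled
temperature. Cooling is piecewise-linear in the executed pair-event count,
from `T*_start` (0.5 by default) to `T*_final`; ghost and bookkeeping
events do not count against the event budget — "collisions" means executed
pair events, which matches the conventional discontinuous-dynamics
collision count (thermostat inclusion is configurable in effect by
adjusting the budget, and the choice is recorded here because published
collision budgets do not state it).

Determinism: all randomness (coil growth, placement, velocities,
thermostat, sampling) flows through R's RNG, so a single `set.seed()`
reproduces a run bit-for-bit; ties in event time break lexicographically
by kind and sphere ids. Checkpoints store the state, the bond registry,
the executed-event count, the next scheduled ghost time and the RNG state
in exact hexadecimal text, giving event-identical restarts.

# Initial configurations

The generator grows each chain as a self-avoiding random coil: backbone
torsions are drawn uniformly, each residue is rejected against every
hard-core and squeeze constraint (retrying the two torsions that position
it) and the whole chain restarts if a residue exhausts its retries. Chains
are then placed with uniform random rotations and positions such that no
inter-chain sphere pair is within the largest interaction diameter plus a
clearance — the initial state has *no inter-peptide contacts*, and its
energy is exactly zero. Velocities are Maxwell-Boltzmann at the starting
temperature with the centre-of-mass drift removed. The default study
conditions follow the simulated system: 8 chains of the 26-residue
Abeta17-42 fragment in a (160 A)^3 periodic box, cooled from T* = 0.50 and
then held near the fibrillisation temperature (T* about 0.19-0.205). The
molar concentration is always derived from the chain count and box edge
(8 chains in (160 A)^3 come to about 3.2 mM); it is reported, never
asserted.

# Analysis

* **Dihedrals** phi(k) = CO(k-1)-NH(k)-CaH(k)-CO(k) and psi(k) =
  NH(k)-CaH(k)-CO(k)-NH(k+1), undefined at termini.
* **Secondary structure**: `strand` needs beta-region dihedrals (phi in
  [-180, -45], psi in [45, 180) or [-180, -150]) *and* membership in a
  hydrogen-bond ladder (two or more consecutive residues bonded across
  strands — inter-chain or at sequence separation >= 3); `helix` needs
  alpha-region dihedrals (phi in [-90, -30], psi in [-77, -17]) over four
  or more consecutive residues supported by a short-range intra-chain
  bond; everything else, including termini, is coil/turn. These windows
  are fixed, documented stand-ins for a full secondary-structure grammar;
  the load-bearing property — a chain with no hydrogen bonds can never be
  labelled strand — is what the initial-state checks rely on.
* **Strand-content profiles**: per residue position, the fraction of
  (frame, chain) observations labelled strand within a reduced-time
  window.
* **SASA** on the four-sphere geometry: deterministic sphere-point
  (Shrake-Rupley style) accessibility with probe 1.4 A, 960 points per
  sphere (antipodally symmetric point set), radii equal to the hard-core
  radii, summed per residue. Numerical SASA values depend on this
  tailoring and are not comparable across coarse-grainings.
* **P_max**: within each reduced-time window of width 5000, the fraction
  of sampled configurations whose total interaction energy lies within
  ±4 eps_HB of the most populated energy; `-T* log(P_max)` is its
  free-energy-like transform. The band search is exact (sorted two-pointer
  count; ties resolve to the lowest energy) and is cross-checked against
  an exhaustive quadratic-time search in the tests.
* **Salt bridges**: K-D side-sphere pairs within their outer well
  diameter, split intra-/inter-chain. Using the interaction's own outer
  diameter rather than a fixed cutoff keeps the count consistent with the
  force field's notion of contact.
* **Chain shapes**: turns are local reversals of the CaH trace (over 120
  degrees across a 7-residue window); a central turn in the 24-26 region
  with side-sphere contact between the two strands is a U; an additional
  C-terminal turn at 37-38 an S; an additional turn near 33 a triangle;
  anything else disordered. These thresholds are explicit heuristics for a
  classification that was originally visual.

# Scope of the synthetic-data checks

The generator plus engine emulate spontaneous aggregation runs at desk
scale: two to eight chains and 10^6-10^7 events, versus hundreds of
billions of collisions for full fibrillisation. Tests therefore validate
*mechanics* (exact conservation, two-body oracle agreement, bound-state
statistics against the analytic Boltzmann ratio, constraint preservation,
0% initial strand content) and *directional* behaviour, not fibril
structures: no claim about protofilament geometry, S-to-U conversion
kinetics or salt-bridge statistics at production scale follows from a
passing suite. The energy-landscape consequences of the synthetic pair
energies are likewise not validated against real aggregation propensities.

Problem sizes used by the tests and the acceptance script were chosen to
exercise each property at the smallest scale where it is meaningful: the
two-body oracle runs tens of events; conservation checks run 10^6 events
on a dimer; the directional hydrogen-bond comparison runs a few times
10^6 events per cutoff set on a two-chain fragment system; the
initial-state strand check generates the full 8-chain, 792-sphere system.

## A known limitation: the parallel-preference bias is not reproduced

The two auxiliary-cutoff sets are implemented exactly as published, and the
suite contains a matched-ensemble experiment
(`parallel_preference_experiment()`) designed to detect their differential
effect: identical orientation-symmetric two-chain strand encounters at
T* = 0.20 are run under each set, intra-chain hydrogen bonds disabled (at
desk scale they dominate the statistics and carry no orientation
information) and every formation event classified parallel or antiparallel
from the strand directions at the moment of formation. With the package's
*synthetic* side-chain geometry the experiment does not show the expected
direction: across 150 encounters per set, the parallel-preference cutoffs
pass parallel-geometry formation attempts slightly *less* often than
antiparallel ones, and re-optimised ideal parallel sheets are about equally
near-feasible under both sets. The discriminating power of those four
distances evidently depends on fine features of the true model geometry
(exact side-sphere placements, squeeze values and association well
diameter) that the synthetic defaults do not reproduce. The corresponding
test is kept as the specification of the intended behaviour and currently
fails; users supplying the genuine geometry tables can re-run it as is.

# Numerical choices

* Root finding works on squared distances; a relative dead band of 1e-12
  at each surface classifies just-executed pairs consistently (a pair at
  its surface counts as inside when moving inward, outside when moving
  outward), which provably avoids zero-time event loops.
* Double-well shell occupancy is persistent state, updated only by
  crossing events, so energy bookkeeping is exact by construction; the
  engine's incremental energy is compared against a from-scratch
  recomputation in the tests.
* The minimum-image horizon adds 1e-9 to the boundary-crossing time so a
  refreshed pair definitely sees its new image.
* Placement failures name the constraint that failed and are bounded
  (80 retries per residue, 200 chain restarts, 2000 placements).
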