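---
title: "Gate coordination landscapes of rocker-switch transporters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gate coordination landscapes of rocker-switch transporters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescape)
```

## The scientific problem

The mitochondrial pyruvate carrier (MPC) is a heterodimeric membrane
transporter that moves pyruvate across the inner mitochondrial membrane by
an alternating-access rocker-switch mechanism: a central substrate site is
alternately exposed to the intermembrane space (outward-open state) and the
matrix (inward-open state), passing through an occluded state in which
hydrophobic gates seal the site from both sides. Large ensembles of
predicted structural models can sample this conformational landscape, and
the analysis problem is to turn tens of thousands of conformers into a
small set of interpretable states: which models are outward-open, occluded
or inward-open, which single models best represent each state, how the
helices move between states, and how substrates and inhibitors engage the
central site.

`gatescape` implements that analysis pipeline as reusable, tested
components, together with a synthetic data generator that reproduces the
regime's *structure* (a rigid-bundle rocker with two gates and known ground
truth) so that every stage can be validated quantitatively.

## Gate coordination numbers

Closure of each side of the transporter is measured by a smooth
coordination number over two residue groups flanking the gate. A pair of
non-hydrogen atoms at distance $r$ contributes

$$ s(r) \;=\; \frac{1 - (r/R)^6}{1 - (r/R)^{12}} \;=\; \frac{1}{1 + (r/R)^6},
\qquad R = 4.5\ \text{Å}, $$

and the gate metric is $C = \sum_{i \in \text{group1}} \sum_{j \in
\text{group2}} s(r_{ij})$. A value of about 100 means roughly one hundred
atom pairs in close contact: a closed gate. The two forms of $s$ are
algebraically identical once the removable singularity at $r = R$ is filled
with its limit $1/2$; the package evaluates the simplified form, which is
well-conditioned everywhere, and the test suite keeps the unsimplified
rational as the oracle. No distance cutoff is applied by default — all
pairs are summed exactly — and the optional neighbor-list acceleration
prunes only pairs whose contribution falls below $10^{-12}$ (cutoff
$R \cdot 10^{2}$), so it is lossless at that tolerance; a test compares it
against a plain double loop.

The default residue groups are the carrier's published gate definitions
(`mpc_gate_metrics()`): N-gate 68/71/75/76/79/82 (MPC1L) or 66/69/73/74/77/80
(MPC1) against 82/85/89/90/93/96 (MPC2); C-gate 47–55 (MPC1L) or 45–53
(MPC1) against 61–69 (MPC2); author numbering per protomer chain, $R$ =
4.5 Å. The groups must be disjoint on every model because the cross-group
sum has no self-pairs.

## Filtering, clustering, representatives, states

**Quality filter.** Models are retained when their interface quality score
is *strictly greater* than 0.4 — the conventional boundary above which a
predicted dimer interface is considered at least medium quality. Models
without a score are an error unless dropping them is requested explicitly;
every stage logs its counts.

**k-medoids.** Retained models are clustered in the $(C_N, C_C)$ plane
with k-medoids, $k = 9$ by default, Euclidean distance on the raw
coordination numbers (z-scoring is available as a flag; the default is raw
because the two metrics share units and scale). Initialization is the
deterministic PAM BUILD step — the first medoid minimizes total distance,
each further medoid maximizes the cost reduction — followed by alternation
of nearest-medoid assignment and within-cluster medoid update until the
cost is stationary. BUILD was chosen over randomized D²-sampling seeding
because the alternation has no swap phase and cannot repair a double-seeded
cluster, whereas BUILD is deterministic and recovers well-separated
clusters reliably. When the ensemble exceeds the distance-matrix cap
(`max_matrix`, default 5000), the medoid search runs on a seeded uniform
subsample of that size and all models are then assigned to the nearest
medoid. All ties (medoid updates, representatives) break lexicographically
on model id, making every run bit-reproducible given the seed.

**Representatives.** Each cluster is depicted by its most central member:
the model minimizing the mean metric-space distance to all members of its
cluster (the medoid whenever the cluster was fully enumerated).
`representative_tightness()` reports the structural meaning of that choice
as the mean superposed RMSD between the representative and the other
members; on the synthetic study conditions below this is ~0.4 Å, i.e.
members of a state cluster are structurally near-identical.

**State labels.** Classification is reference-anchored: the outward-open
and inward-open endpoint models provide, per gate, an open and a closed
reference value, and a gate counts as closed (open) when its metric is
within a margin of the closed (open) reference — margin defaulting to 10%
of that gate's reference span. N open + C closed is outward-open, the
reverse inward-open, both closed occluded, anything else intermediate. The
margin is configurable because the original analysis assigns states by
inspection of the landscape rather than by a printed threshold.

## Rigid-body rotation analysis

The conformational change between two states is quantified as a
fixed-selection rotation: superpose state B onto state A on a fixed
selection (e.g. the partner protomer or the static helices), then fit the
residual rigid transform of the mobile H2–H3 bundle. The angle comes from
the rotation-matrix trace, $\theta = \arccos((\mathrm{tr}\,R - 1)/2)$ with
the argument clamped to $[-1, 1]$ against round-off; the axis is the
rotation's invariant direction; the screw translation is the axis component
of the residual displacement. This is deliberately *not* an automatic
dynamic-domain decomposition: the selections are supplied by the caller,
because the published bundle rotations (16.5° and 19° for the two
protomers) are defined under stated alignments. `hinge_report()` gives the
per-residue Cα displacement after the fixed alignment and flags the window
of maximal displacement gradient — the point where the chain switches from
staying put to moving — as the candidate hinge region.

## Protein–ligand interaction profiling

Interactions are typed from geometry alone, following the cutoff
conventions of the standard interaction profilers (all overridable in
`interaction_criteria()`): hydrogen bonds by heavy donor–acceptor distance
≤ 3.5 Å (the target structures carry no hydrogens; with hydrogens a 3.6 Å
/ ≥ 100° rule applies), ionic contacts by charged-group centroid distance
≤ 5.5 Å, parallel π-stacking by ring-centroid distance ≤ 5.5 Å with
interplanar angle ≤ 30° and lateral offset ≤ 2 Å, perpendicular stacking at
60–90° within 6 Å, and hydrophobic contacts by apolar C–C distance ≤ 4 Å
collapsed to one record per residue. Protein-side chemistry comes from a
built-in standard-residue dictionary; histidine is donor and acceptor, and
a protonation flag turns it into a positively charged imidazolium (and
removes its acceptor role), matching docking runs performed with the
binding-site histidine modeled in either state. Ligand chemistry is
*declared* in a `ligand_spec` (donor/acceptor/charged/ring/apolar atom
names) rather than perceived from connectivity — this keeps the package
free of a chemistry toolkit and the typing rules fully transparent;
schematic declarations for pyruvate and the three inhibitor classes ship
under `inst/extdata/`.

A pose's *fingerprint* is the canonical set of (interaction kind, protein
residue) tokens. Pose convergence takes the most frequent fingerprint as
the modal interaction set (ties towards the larger set, then
lexicographic) and reports the fraction of poses containing it. Pose
*clustering* uses the unfitted RMSD over the non-hydrogen atoms of ligand
plus binding-site residues, average-linkage agglomeration, and the Kelley–
Gardner–Sutcliffe penalty to choose the number of clusters: the mean spread
of multi-member clusters at each level, normalized across levels to
$[1, n-1]$, plus the cluster count, minimized over levels (ties to the
smallest $k$). When the penalty curve is flat — all poses identical, or no
level mixes distinct groups — the choice degenerates to $k = 2$ and is
flagged. A structural property of this criterion worth knowing: on exactly
two well-separated tight groups no level carries a large-spread baseline to
normalize against, so a two-group count is identified only through the
degenerate tie rule (exact duplicates), not through the penalty minimum.

## Buried interface area

Protomer interface burial is computed as buried solvent-accessible surface,
$(\mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB})/2$, by
Shrake–Rupley sampling on a deterministic Fibonacci (golden-angle) sphere
lattice — no RNG, so values are bit-stable — with Bondi van der Waals radii
keyed by element (an unknown element is an error, never a silent default)
and a 1.4 Å water probe. Heavy atoms are used by default; `atoms = "all"`
includes hydrogens when present, since the atom set entering the original
interface-area computation is not stated. The tangent-two-spheres analytic
cap solution and a lattice-refinement check validate the implementation to
within 2%.

## The synthetic rocker-switch generator

`build_template()` and `generate_ensemble()` provide the ground-truth data
the tests run on. The template is an idealized, backbone-only (N, CA, C, O)
heterodimer: per chain one static vertical helix (H1) and a mobile H2–H3
bundle that rotates rigidly about a horizontal pivot axis, by $t \cdot
16.5°$ (chain A) and $t \cdot 19°$ (chain B) for a progress coordinate
$t \in [0, 1]$ drawn per model (uniform by default). The gate-bearing
helices lie horizontally above (H2, N-gate) and below (H3, C-gate) the
pivot, so each gate segment keeps a single lever arm and the two chains'
gate rods approach edge-on, reaching x-registry exactly at the gate's
closed endpoint with a small vertical stagger (2.2 Å) setting the contact
distance. Residue numbering is chosen so the carrier's published gate
groups select real residues.

This layout was designed against the generator's contract and verified at
construction time: both gate metrics are strictly monotone and roughly
linear in $t$ (noise-free), ground-truth $t$ and computed $C_N$ correlate
at Spearman ρ ≥ 0.998 under 0.3 Å coordinate noise, endpoint clusters
classify correctly at the 10% margin, and the applied bundle rotations are
recovered to numerical precision. Coordinate noise defaults to σ = 0.15 Å,
a typical coordinate-level heterogeneity for high-confidence predicted
models. Pseudo-quality scores follow a clipped half-normal,
$\mathrm{clip}(1 - |N(0, 0.15)|, 0, 1)$, independent of $t$ by default so
filtering is unbiased; a `mid_biased` mode depresses mid-transition scores
for probing filter/landscape interactions.

Two deliberate abstractions deserve emphasis. First, the geometry is an
*abstraction of a rocker-switch gate*, not a model of the real fold: helix
orientations were chosen for controllable gate engagement, the rotation
axis passes through a designated pivot at the bundle waist rather than
through a hinge residue's Cα (no mobile Cα can sit on the axis without
collapsing that rod's lever arm), and steric plausibility is not enforced.
The generator's `hinge_onset` ground truth is therefore the first mobile
residue per chain — the fixed/mobile boundary that `hinge_report()`
localizes. Second, because the bundle rotation is *linear* in $t$ and at
most 19°, per-pair gate distances change essentially linearly across a
travel of a few Å while the switching function responds over a ~3 Å window:
no such generator can complete a gate's closure by mid-transition and then
hold it within 10% of span. Consequently mid-transition models sit near 50%
of each gate's span and classify as *intermediate*, not *occluded*, at the
10% margin — the synthetic landscape's arc connects the endpoint states
through a genuinely transitional region rather than through a both-gates-
closed corner. A real occluded conformation requires a nonlinear gate
schedule (closure saturating early) that a linear rigid rotation cannot
produce; passing the endpoint-classification and monotonicity checks on
this generator therefore validates the pipeline's machinery, but says
nothing about whether a *real* ensemble contains occluded states — that is
a property of the data, not of the method.

What the generator does not emulate at all: side chains (gate groups
contribute four backbone atoms per residue, so absolute coordination
numbers are smaller than with full side chains), amphipathic/linker
helices and their flexibility, membrane context, predicted-model confidence
fields, and any particular density of models along the landscape (the $t$
distribution is a free knob, not a claim).

## Numerical choices and degenerate inputs

* Switching function evaluated as $1/(1+(r/R)^6)$; the printed rational is
  kept as a test oracle away from its removable singularity, where double
  precision loses ~4 digits per decade of proximity to $r = R$.
* Superposition by SVD of the covariance with determinant correction;
  near-collinear selections (second singular value below $10^{-10}$ of the
  first) are rejected as degenerate rather than silently fit.
* Rotation-angle arccos argument clamped to $[-1, 1]$; the rotation axis
  falls back to an eigen-decomposition within ~$10^{-8}$ of 0°/180° where
  the skew-part formula loses precision.
* k-medoids cost comparisons and tie-breaks use a $10^{-12}$ slack;
  cluster labels are ordered by lexicographic medoid id so the labelling
  itself is stable.
* Duplicate atom keys, insertion codes, unknown elements, missing residues
  and missing quality scores are errors by default; every
  "skip-and-continue" behavior is an explicit flag plus a logged message.
* All RNG use is locally seeded and restores the caller's RNG state.

## Study sizes used in the validation suite

The packaged checks run, per seed: ensembles of 2,000 models (the original
study's 100,000-model sets, scaled down to a size where the full pipeline
completes in seconds while leaving every stage non-trivial), 9 clusters
with a 5,000-point matrix cap, 80-pose docking sets at 70% modal fraction,
1,800-point blob benchmarks for the clusterer, and 10⁶-point switching-
function sweeps. Five independent seeds cover the end-to-end pipeline.

## Known limitations

* The interaction cutoffs are conventions; published interaction lists
  from external profilers are a qualitative, not numeric, comparison
  surface.
* Ligand chemistry must be declared correctly by the user; nothing is
  perceived from connectivity or element patterns.
* The fixed-selection rotation analysis reproduces published angles only
  under the same fixed/mobile selections; it does not discover domains.
* mmCIF reading supports single-model files as provided by `bio3d`;
  multi-model ensembles are expected in PDB format.
* The Kelley criterion's two-group blind spot (above) is inherent to the
  published normalization, not specific to this implementation.
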