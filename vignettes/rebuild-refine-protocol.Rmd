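---
title: "Rebuilding and refining TMH protein models from distant homolog templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rebuilding and refining TMH protein models from distant homolog templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmhrebuild)
```

## The modeling problem

α-helical membrane proteins are chronically under-represented in the
structure databases, so a target of interest usually has to be modeled
from a homolog of 15–40 % sequence identity.  At that distance the
membrane-embedded scaffold is broadly conserved but two things are not:
the loops, and the precise geometry of helices distorted by local bends
— most often induced by a proline, whose missing backbone hydrogen bond
lets the helix kink.  Copying the template's helix through such a
region propagates several Ångström of error into the model core.

`tmhrebuild` treats this as a decision-and-search problem:

1. **Gate** (`gate_tmh`): decide per TMH, from the alignment alone,
   whether the template helix can be kept.  A helix is rebuilt when the
   aligned span contains gaps, when a bend-inducing position is
   unaligned or not conserved, or when the annotated helix lengths
   differ by more than a helical turn.  A position counts as
   bend-inducing when the target has a proline there or when at least
   10 % of homolog sequences do; sequence motifs other than prolines
   are deliberately not gated on, because sequence-based predictors for
   them are not reliable enough to automate.
2. **Sample** (`mc_run`): explore alternative rigid-body conformations
   of the kinked helix under Metropolis Monte Carlo.
3. **Close** (`rebuild_region`, `remodel_bend`): rebuild the bend and
   any loop junction the accepted moves displaced, by fragment
   insertion with CCD closure.
4. **Refine** (`refine`): local backbone moves with chain re-closure
   under a surrogate all-atom score with ramped repulsion.
5. **Select** (`rank_and_truncate`, `cluster_tm`, `select_final`): keep
   the 1000-or-10 % lowest-energy models, cluster the TM region into
   structural families, and pick the lowest-energy member of each of
   the five largest families.

`rebuild_and_refine()` drives stages 2–5 for one kinked TMH.

## Kink parameterization and the move set

A kinked helix is three contiguous regions: the moveable fragment m,
a 4–6 residue bend, and the fixed fragment f whose first residue is
the bend-inducing reference (e.g. the proline).  `measure_kink`
reports:

* **kink angle** — angle between the helical axes fitted to m and f;
* **translation** — distance from the m C-terminus Cα to the
  f N-terminus Cα;
* **swing** — azimuth of the m N-terminus projected on the plane
  orthogonal to the f axis through the reference residue's CB,
  measured right-handed about the f axis from the −x reference
  (−x pointing from the m C-terminus towards that CB).

Axes are fitted by projecting each interior Cα to the local helix
centre using its two flanking residues (the flank bisector points at
the axis and the axial components cancel), then fitting a
total-least-squares line through the centres.  This stays stable on
4-residue fragments, where PCA on raw Cα positions is biased by
helical wobble.

The sampler's moves redraw the kink absolutely rather than
incrementally: the translation places the m C-terminus on a hemisphere
of radius N(7.2 Å, 0.6 Å) on the m-side of the f N-terminus; the
rotation redirects the outward m axis into the +z/+x quadrants of the
kink frame, which confines the m N-terminus to the semicircle away
from the proline ring.  Each fragment can additionally spin about its
own axis (default ±30°), and the whole kinked unit can make small
rigid moves.  Move kinds are chosen uniformly per step; the scheduling
is a free choice, since nothing in the sampled geometry prefers an
ordering.

## The surrogate energies

The original protocol runs inside a membrane-specific coarse-grained
and all-atom force field; those potentials are outside this package's
scope, and are replaced by documented surrogates.  The consequence is
deliberate and should be kept in mind: the package validates the
*search and selection logistics* — move geometry, constraint scheme,
closure, ranking — not packing physics.

The coarse score used during sampling is
`clash + 3·constraints + restraint + 0.1·membrane`:

* **clash** — soft-sphere on Cα/CB pairs (radius 3.6 Å, residues ≥2
  apart), the open bend window excluded;
* **constraints** — flat-bottom harmonics on template-derived Cα–Cα
  pairs: zero within `width` of the template distance, then
  `((|d−d0|−width)/σ)²` with σ = 1 Å.  The harmonic form and the width
  semantics follow the protocol; the spring scale is a package choice;
* **restraint** — Gaussian penalty `(disp/radius)²` on the displacement
  of the rigid-body *jump anchors* (the m C-terminus and f N-terminus
  Cα) from the start pose, radius 1.0–1.5 Å.  The restraint is applied
  to the anchors rather than to whole-fragment RMS deliberately: a
  fragment-RMS reading is lever-arm-amplified (a 30° kink rotation
  moves the far end of a 7-residue fragment ~3 Å even though the
  sampled translation stayed put) and would veto exactly the
  reorientations the move set exists to sample;
* **membrane** — quadratic penalty on TMH Cα atoms beyond a ±15 Å
  hydrophobic slab, normal along z of the input frame; the hemisphere
  of the translation move is oriented along the f axis, not the
  membrane normal (the figure-level geometry of the move is defined in
  the helix frame), with the frame exposed through `kink_frame`.

The refinement score replaces the clash weight by the schedule's
ramp (default 0.25 → 0.55 → 1.0) and adds two regularizers: a mild
penalty on positive φ, and a **helicity restraint** holding TMH φ/ψ
within ±30° of (−57°, −47°), exempting annotated bend windows, the four
residues N-terminal to any proline, and two fraying residues per helix
end.  The helicity term stands in for the hydrogen-bond physics the
surrogate lacks: without it the score happily satisfies template
constraints by denting a helix end, a motion that costs several
backbone H-bonds in reality.  Ranking, clustering and selection all
operate on this full-repulsion refinement score.

## Loop and bend rebuilding

Fragment libraries carry backbone torsions only, in sizes 9 and 3.
Three sources exist: `ideal` (canonical helix, 3₁₀, π, extended,
polyproline-II and turn templates plus helix–turn chimeras),
`ramachandran` (basin-restricted Gaussian draws), and `file`
(externally generated fragments, whitespace TSV).  The geometric
libraries replace profile-based fragment picking, which requires
sequence-database machinery outside this package's scope.

Each rebuild cycle inserts a random fragment at a random position of
the moving window — or, with probability 0.5, perturbs all window
torsions by N(0, 20°) — then closes the break with CCD and accepts by
Metropolis under `loop clash + constraints + w·gap²` where the
chain-break weight `w` doubles every cycle from 1.  The torsion-noise
move exists because the discrete geometric library alone leaves CCD in
local minima on strained windows; mixed moves close hard kink-junction
loops about twice as often within the twelve-cycle budget.  The twelve
"rebuilding steps" are counted as full insertion+closure cycles.  If
the best closure deviation still exceeds 0.2 Å, the window expands by
one residue on both sides (the designated break keeps its offset from
the window end, so both sides gain freedom) up to a configurable cap,
default 5.

Closure is judged on the *whole window*: the maximum deviation over
the anchor bond, internal junctions and the designated break
(`window_gap`).  Judging only the designated break is exploitable —
an expansion can relocate the break into an intact helix segment and
"close" trivially while an interior junction stays broken.  When a
rigid-body move has broken the junction at the window's anchor, the
moving side is first re-derived from the anchor at ideal geometry
(`heal_window`) so CCD starts from a connected chain.

The bend of a kinked TMH is rebuilt as the annotated four-residue
window by default; when the closed bend is distorted beyond the
tolerated classes a larger 5–8 residue window can be remodeled
(`remodel_bend`).

## Model selection

Truncation keeps `min(1000, ceil(0.10·N))` models by energy, ties
broken by model id.  Clustering is greedy leader clustering on
TM-region Cα RMSD after superposition: models are visited in ascending
energy, each joins the first cluster whose founder is within the
radius, else founds a new cluster.  The radius defaults to 2.0 Å — a
sensible scale for receptor-sized proteins — but should be matched to
the conformational spread of the system: the desk-scale fixture
ensembles spread well under 1 Å, where a 2 Å radius collapses
everything into one family and the five-family selection degenerates;
the packaged recovery experiment uses 0.6 Å.  When a reference
structure is available, `most_accurate_model` implements the
benchmarking convention of reporting the most accurate of the ≤5
selected models.

## The synthetic fixture generator

`make_kinked_bundle` builds idealized TMH bundles: helices on a circle
with ~10 Å neighbour spacing, antiparallel, membrane normal along z,
hydrophobic-biased sequences with prolines only at kink reference
sites, loops and bends closed by the package's own loop builder.  Two
generator choices encode the geometry of native kinks rather than of
ideal helices: the kink tilts the m axis into the half-space away from
the proline CB, and the bend is compressed so the m C-terminus sits
7.2 Å from the f N-terminus — the canonical native value; an
uncompressed ideal-helix bend (~8.9 Å) would place the target outside
the sampler's translation distribution and make recovery impossible by
construction.  Because loop closure can fray a helix edge and shift
the fitted axis, a corrective pass re-measures the realized kink and
applies the small residual rotation, which re-closes without further
expansion.

`make_template_from_target` derives the homolog: kinks straightened
(and their prolines mutated away, so the sequence-level gate can see
the mismatch), Gaussian coordinate noise, optional loop deletions
producing alignment gaps, and mutation down to a requested sequence
identity with bend bookkeeping positions protected.

What the fixtures do *not* emulate: side chains beyond CB, lipids and
water, β-barrels, irregular native loop conformations, and the
sequence statistics real profile HMMs are built from.  Passing tests
therefore demonstrate correct algorithmic behaviour under idealized
geometry, not predictive accuracy on real proteins.

## The packaged recovery experiment

The end-to-end check builds a three-helix bundle with one 30° kink,
straightens it into the template, and derives constraints from the
target's own contacts, excluding every region rebuilt de novo (bend
and loops) as the constraint rules require.  Two levels are exercised:

* a single annealed Monte Carlo run (2000 steps, kT 4 → 0.2 geometric —
  within the protocol's 1000–5000 step band; the constant-kT default
  remains available) must end with a best-energy kink angle closer to
  30° than the straight template's;
* ten end-to-end runs of 200 models each (120-step anneals per model,
  cluster radius 0.6 Å) must, in at least eight, contain a selected
  model with better TM-region Cα RMSD than the template.

The 200-model ensembles are a deliberately scaled-down analog of the
10000–40000 models the full protocol generates per target; the model
count, step counts and the desk-scale cluster radius are stated here
as the package's chosen operating point for the synthetic system.

## Numerical choices and degenerate inputs

* Residue indexing is 1-based with closed intervals throughout,
  matching PDB author numbering.
* Missing CB atoms (glycine included) are rebuilt at ideal tetrahedral
  geometry and flagged virtual; the kink frame requires a CB at the
  reference residue.
* altLoc resolution keeps the highest occupancy, ties alphabetically.
* Chain breaks are flagged when C(i)–N(i+1) leaves (1.0, 2.0) Å; the
  closure deviation is |C–N distance − 1.329 Å|.
* `fit_helix_axis` rejects fits with a rise outside (0.5, 2.5) Å per
  residue and errors on collinear traces.
* CCD tolerance is 0.02 Å with 30–60 sweep budgets; the analytic
  per-torsion update is verified against a grid search in the tests.
* Similarity classes for constraint eligibility: {ILVMF}, {KR}, {DE},
  {ST}, {NQ}, {FYW}.  The 8 Å vicinity cutoff and the 4-residue
  length-mismatch margin are exposed as arguments.
* Budget interpolation between identity bands is linear, bands
  inclusive on the left; selection keeps the shortest contacts first,
  ties by larger sequence separation, making it deterministic.
* GDT's full search is approximated from below by per-threshold maxima
  over sliding 4/8/16-residue window superpositions, the global
  Kabsch fit and the input frame.  TM-score uses
  d0 = 1.24·(L−15)^{1/3} − 1.8 and the same window-seeded iterative
  superposition idea; both are tested against exhaustive small-instance
  oracles.

## Known limitations

* The surrogate energies rank idealized decoys; they carry no claim of
  transferability to real membrane proteins.
* Refinement validates search logistics, not side-chain packing —
  "side-chain optimization" here is re-derivation of the virtual CB.
* One kinked TMH is sampled per run, with the remainder rigid;
  multi-TMH rebuilding is covered by sequential per-helix runs, not by
  combinatorial helix-pair moves.
* The TM-score and GDT maximizations are approximations from below;
  values can be marginally lower than the reference implementations'.
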