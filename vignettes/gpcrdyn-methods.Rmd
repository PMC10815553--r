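---
title: "Methods: activation descriptors, dynamical networks and PIEDA post-processing"
author: "gpcrdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation descriptors, dynamical networks and PIEDA post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrdyn)
```

# Scope and data model

`gpcrdyn` post-processes two kinds of upstream results for class-A GPCR
ligand–receptor complexes: molecular-dynamics trajectories (consumed as
multi-model PDB, Å, with a user-supplied time-per-frame in ns) and
per-residue pair interaction energy decomposition (PIEDA) tables
(kcal/mol, canonical CSV). It never runs simulations or quantum
chemistry itself; everything it computes is a deterministic function of
those inputs plus, for the occupancy comparison, one seeded permutation
draw.

Residues are addressed throughout by Ballesteros–Weinstein (BW) generic
numbers, `helix.position` strings in which position 50 marks the most
conserved residue of each transmembrane helix. The mapping between
generic numbers and sequence residue ids is an *input table*
(`bw_map.csv`), not something inferred from sequence: assignment
pipelines differ, and analyses should be reproducible against the
numbering the study actually used. Generic numbers are kept as strings
("6.48" and "6.480" are different labels), and a mismatch between the
mapping's expected residue name and the structure is a warning, never a
silent re-assignment.

# Activation-state descriptors

Six per-frame distances track the canonical microswitches:

| descriptor | atoms | rationale |
|---|---|---|
| `lbs_tightening` | Cα(5.46)–Cα(7.42) | subtle contraction of the ligand-binding site upon activation |
| `npxxy_hbond` | O(OG, 3.39) … nearest side-chain amide H of 7.49 | donor–acceptor distance of the potential Ser–Asn hydrogen bond; ≈ 5 Å means no bond |
| `npxxy_ca` | Cα(3.44)–Cα(7.53) | NPxxY backbone separation (TMH3 vs TMH7) |
| `pif_36` | Cα(3.40)–Cα(6.44) | P-I-F switch: TMH3–TMH6 arm |
| `pif_56` | Cα(5.50)–Cα(6.44) | P-I-F switch: TMH5–TMH6 arm |
| `edry_ionic` | min over {NH1,NH2,NE,CZ}(3.50) × {OE1,OE2,CD}(6.30) | E/DRY ionic lock; salt-bridge range (≈ 3.5 Å) when inactive, near 20 Å when the G-protein cavity opens |

Two deliberate conventions: (i) `npxxy_hbond` measures to hydrogens when
they exist and falls back to the O…N heavy-atom distance with a warning
otherwise, because production trajectories are often stored
hydrogen-stripped; the fixed donor/acceptor assignment (Ser hydroxyl as
acceptor, Asn amide as donor) is a package convention, as the roles are
not observable from distances alone. (ii) Both P-I-F arms terminate at
residue 6.44, the TMH6 member of the switch.

RMSD is computed after optimal rigid (Kabsch) superposition of the
selection onto a reference frame; RMSF superposes every frame onto the
ensemble mean (twice: first onto a reference, then onto the refined
mean) and reports the population standard deviation of each atom about
its mean position. `fit = FALSE` skips superposition for pre-aligned
input, in which case the oscillating-atom value is analytic. Both lean
on `bio3d` for the superposition itself, which is standard machinery.

**Block reduction.** Frame series are reduced to medians over
contiguous blocks anchored at *t* = 0 (default 10 ns — long enough to
smooth over transient excursions, short enough to keep ten points per
100 ns trajectory). The median of an even count is the midpoint of the
two central values; a trailing partial block is dropped with a message,
never silently. No sliding windows: blocks are disjoint by design so
block medians are independent summaries.

**State classification.** Each block's (x, y) median pair is tested
against *closed* rectangles per state: a point on an edge belongs to
the region, and the active/inactive rectangles of a pair must not
overlap (validated). Everything else is "intermediate" — deliberately a
first-class label, since simulated agonist complexes frequently park in
intermediate conformations. The rectangle bounds shipped in
`inst/extdata/regions.yaml` are illustrative configuration: published
figures shade such regions rather than tabulate them, so the package
treats them as a user input with documented defaults.

# Dynamical network analysis

Nodes are one Cα per protein residue plus the ligand's basic nitrogen
(ligands with several basic nitrogens must name one — a single ligand
node is a modelling choice, not a chemical claim). The motion
correlation between nodes i and j is

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle |\Delta r_i|^2\rangle\,\langle |\Delta r_j|^2\rangle}},$$

with Δr the displacement of the anchor atom from its trajectory-mean
position. The implementation assumes the trajectory is already aligned
(the package's own generators produce aligned frames; for real data,
superpose first). An independent cross-correlation routine
(`bio3d::dccm`) is used in the test suite to cross-check this matrix;
it is never the implementation.

**Edges.** A pair is connected when it is in persistent contact
(minimum heavy-atom distance ≤ 4.5 Å in ≥ 75 % of frames), is not a
sequence self/nearest-neighbour pair (|Δresid| ≤ 1 for protein–protein;
trivially correlated through bonding), and has |C| > 0. The contact
cutoff and persistence fraction are configurable; the defaults mirror
the 4.5 Å contact convention used in the energy module and the
established dynamical-network protocol. Edge weights are
$w_{ij} = -\ln |C_{ij}|$: weight 0 for perfectly (anti)correlated
motion, growing without bound as the correlation vanishes. The
*magnitude* |C| is used deliberately — correlated and anti-correlated
motion both transmit information — and this choice is one the
literature describes inconsistently; using |C| makes the weight
monotone in communication strength and keeps all weights non-negative,
which the path search requires.

**Paths.** The optimal ligand→sink pathway is the minimum-total-weight
simple path (Dijkstra); suboptimal pathways are enumerated *exactly* by
depth-first search with admissible branch-and-bound pruning (the exact
distance-to-sink from a reverse Dijkstra bounds every extension). A
path is retained while its distance is strictly below optimal + offset
("less than", not "at most"; default offset 20) — except that optimal
ties are always retained, including at offset 0. Distance equality uses
an absolute tolerance of 1e-9 (weights are O(1)). Ties are ordered by
node index (ascending residue id, ligand last) and a path-count cap
raises an error rather than truncating silently. The summary reports
*n* (node count of the optimal pathway) and *N* (number of pathways
found, the degeneracy), the ligand's anchor residue (its
smallest-weight edge, ties to the lower residue id with a message), and
a helix-hop segmentation distinguishing intra-helix runs from
inter-helix transfers.

# PIEDA post-processing

Records carry the total pair interaction energy (PIE) and its
electrostatic, exchange-repulsion, charge-transfer and dispersion
components plus a solvation term. The polarity share

$$\%E_{es+ct} = \frac{|E_{es}|+|E_{ct}|}{|E_{es}|+|E_{ct}|+|E_{disp}|}\times 100$$

is computed on absolute values, so it is always in [0, 100] regardless
of component signs: 100 % is a purely polar contact, 0 % purely
dispersive. Exchange repulsion and solvation pass through the I/O
schema and totals but never enter the share — it is a three-component
statistic by definition. When all three components are zero the share
is undefined and flagged, not thrown.

Contacts use minimum heavy-atom distance with a *closed* 4.5 Å
boundary (exactly 4.5 Å is a contact; "no contact" means strictly
beyond, or an undetermined distance). Contacted residues are classified
attractive (PIE < 0) or repulsive (PIE > 0); an exact zero lands in the
attractive branch with a message, since the two-colour convention has
no neutral class and the case has measure zero. The cross-complex heat
map copies PIE values verbatim (no scaling), orders rows
agonists–antagonists–unknown and columns by helix and position, and by
default drops the conserved D3.32 salt-bridge column, whose ≈ −100
kcal/mol would dominate the colour scale; exclusions are recorded in
the output rather than discarded.

**Occupancy comparison.** Binding-site occupancy is the count of
contacted residues per complex. The antagonist-minus-agonist difference
of class means is tested with a seeded label-permutation test (add-one
correction, two-sided on |difference|). A permutation test was chosen
because per-class sample sizes in this kind of study are ~7–10
complexes, far too small for normal-theory comparisons, and counts are
bounded integers; the test is distribution-free and its calibration is
verified empirically in the suite (type-I error within the binomial
confidence band of the nominal level over 500 label-exchangeable
replicates).

# Synthetic generators

The generators define the package's study conditions; their defaults
are fixed and not tuned per analysis.

`makeToyGpcr` builds a minimal structure carrying exactly the atoms the
six descriptors touch, placed so every descriptor equals its target at
zero jitter (machine precision, verified at 1e-6 Å). The default
targets place the inactive state at a 3.5 Å ionic lock and a 5 Å
(non-bonded) Ser–Asn distance, and the active state at a ~20 Å open
lock — the literature's distance scales — with the remaining four
targets chosen as plausible geometries; they are generator defaults,
not measurements. Per-frame isotropic Gaussian jitter emulates thermal
motion. What the toy does *not* emulate: real secondary structure,
side-chain rotamers, correlated backbone motion, membrane or solvent —
so passing descriptor tests demonstrates the geometry code, not force
fields.

`makeCorrelatedTrajectory` plants motion correlation: every node of a
group moves along the group's fixed unit vector u_g as
$a_g s_g(t) + \varepsilon_i(t)$, a shared standard-normal mode plus
node-local noise *along the same vector*. Restricting each node's
motion to one direction is what makes the planted correlation exact in
closed form, $\rho = a^2/(a^2+\sigma^2)$, for pairs sharing exactly one
group — with isotropic noise the measured 3-D displacement correlation
would instead depend on the noise dimensionality. The closed form is
inverted by `amplitudeForCorrelation()` and verified to three standard
errors (Fisher-type SE $(1-\rho^2)/\sqrt{T}$) at 5000 frames. Residue
base positions sit on a 20 Å ladder so only *planted* contacts (pairs
placed ~3 Å apart, optionally via explicit offset vectors to close
contact cycles) satisfy the persistence criterion; jointly infeasible
placements raise an error. Nodes in several groups superpose modes, so
their pairwise correlations are diluted below the single-group closed
form — the planted-pathway fixtures exploit exactly this, giving a
strong relay chain (planted ρ = 0.8 per edge) a decisive weight
advantage over a weak decoy chain (ρ = 0.4).

`makePiedaTables` draws, per complex, a Bernoulli contact indicator per
binding-site residue (class-specific probability — the planted
occupancy effect), designates a class-specific fraction of contacts
repulsive, and draws energy components from Gaussian mixtures
*conditioned on the designated PIE sign* (rejection sampling), so
"repulsive fraction zero" really implies zero repulsive calls.
Non-contacted residues get near-zero energies and distances beyond the
cutoff. Defaults (7 agonists / 10 antagonists, contact probabilities
0.55 vs 0.8) mirror the batch shape and direction of effect such
studies report.

All generators are bit-deterministic given their seed and restore the
caller's RNG state.

# Numerical choices and problem sizes

* PDB coordinates round-trip at the format's three-decimal precision;
  energies and distances are kcal/mol and Å throughout, no unit options.
* Path-distance comparisons use absolute tolerance 1e-9; correlation
  matrices are clamped to [−1, 1] against rounding; frozen nodes (zero
  fluctuation) are an error naming the nodes, not NaNs.
* Tie-breaks are always by ascending residue id and are announced.
* The test suite's standing problem sizes: 5000-frame trajectories for
  correlation recovery; 200 random graphs of ≤ 10 nodes against
  exhaustive path enumeration; 100 seeded replicates for anchor/pathway
  recovery; 500 replicates for permutation-test calibration. These sizes
  keep every Monte-Carlo assertion's sampling error well inside its
  margin while the whole suite runs in about a minute.

# Limitations

* The contact criterion's cutoff and persistence fraction are
  conventions; real systems may warrant residue-specific criteria.
* `correlationMatrix` does not superpose frames; un-aligned input
  inflates correlations through global motion.
* The toy receptor validates geometry and plumbing, not physics; region
  rectangles must be calibrated per receptor before real use.
* Heat-map cells carry total PIE; component-resolved maps can be built
  from the same tables but are not pre-packaged.
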