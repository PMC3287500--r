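---
title: "Methods: simulating constant-time alignment on a reconfigurable mesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating constant-time alignment on a reconfigurable mesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmeshalign)
```

# The computing model and its one assumption

A reconfigurable mesh (r-mesh) is a grid of processing units, each with four
ports — N, S, E, W — that the unit may fuse into groups before a broadcast.
Fused groups, chained through the fixed grid adjacency, form *buses*; in one
atomic broadcasting step every bus carries a single one-bit value and every
port on it reads that value.  The simulator in this package implements
exactly that and nothing more: `mesh_config()` describes a (possibly sparse)
grid of port partitions, `resolve_buses()` computes the connected components
of the port graph, and `mesh_broadcast()` assigns each bus the value of its
drivers.

The one semantic choice the model description leaves open is what happens
when several units drive the same bus.  We resolve concurrent writes by
**logical OR**, the behaviour of a common-collector electrical bus.  This is
a design decision, not model text, but it is the only rule under which the
max-switch constructions work: a 1 ("the max bit") dominates the bus.  All
components below inherit it.  Two consequences are worth keeping in mind:
OR is monotone (adding a driver can never turn a 1 into a 0 — a property the
test suite asserts on random meshes), and cyclic configurations are
well-defined (a cycle simply reads the OR of its drivers), so no Pr-mesh
style acyclicity restriction is needed.

A *broadcasting step* is atomic: configure, drive, read.  Multi-phase
algorithms are sequences of such rounds; there is no propagation delay
inside a round.  Timing-accurate hardware simulation is a non-goal.

# Unary numbers

Values travel in the 1UN unary format: `x` in `w` bits is a prefix of
`x + 1` ones (`un_encode(3, 8)` is `11110000`), and the all-zero pattern is
reserved as the underflow marker.  Encodable values are `0 .. w-1`;
operations that would exceed the width raise a *capacity error* rather than
saturate silently, because a silently clipped score would corrupt an
alignment without any visible symptom.  The bit width is chosen per run as
the smallest multiple of eight that holds the maximum attainable score plus
one (rounding to multiples of eight only improves reuse of cached component
templates; it has no semantic effect).

The load-bearing fact about 1UN is that the bitwise OR of two encodings is
the encoding of their maximum, since both are one-prefixes.  The affine-gap
selector bit is deliberately *not* part of the number (it rides as a separate
tagged field), which keeps the prefix invariant testable.

# Components

**Max switches.**  The 2-input 1-bit switch is a single unit fusing
\{NSEW\}.  The 4-input switch uses four units with the configurations
\{NSW,E\}, \{NSE,W\}, \{NE,S,W\}, \{NSW,E\} — note the repeated first/last
configuration, which we take as given.  The figure showing their geometric
arrangement is not available in the extracted source, so the package places
them on a 2×2 grid where those four configurations put the four input ports
(N and W of the top-left unit, N of the top-right unit, E of the top-right
unit) and the output port (S of the bottom-right unit) on one shared bus;
the exhaustive 16-row truth table is then the behavioural contract, and the
test suite asserts it.  A 3-input max feeds a zero into the spare port.  The
`w`-bit switch stacks `w` 4-input blocks, one per bit plane, on a sparse
grid (sparseness keeps the blocks electrically isolated); `4w` units total.
Underflow inputs contribute no ones and therefore never beat a valid
encoding.

**Adder/subtractor.**  The second operand of every addition in the DP
recurrence is predefined (a substitution score or gap cost), so it is built
into the mesh: its 1UN encoding is left-shifted once (dropping the bit that
represents zero) and drives the West border, one bit per row; rows for its
trailing zeros are omitted, leaving `k = b` rows of `w` units, all fusing
\{NE,SW\}.  A bit entering a row at N leaves one column to the right at S —
a unary increment per row — while the West-border 1 surfaces as the new low
bit.  Subtraction runs the same mesh upward (minuend at S, East border
undriven, result at N); bits shifted off the West edge vanish, so any
negative result is exactly the all-zero underflow pattern.  One broadcast
either way.  An underflow *input* propagates as underflow output — a rule
the model description leaves open, adopted so that a discarded negative
branch can never be resurrected by a later addition.

**On/off switch.**  The `w × (w+1)` gate routes bit `j` down column `j` to
the anti-diagonal (\{NE,S,W\}), then East along its row (\{N,S,EW\}) to the
last column.  The construction as described has the last-column units fuse
\{NSEW\} "when a signal travels through them", with a timing argument that
the selector bit arrives first.  Under the atomic OR-bus semantics this
cannot work as written: \{NSEW\} on the whole last column would merge every
row onto one bus and every output bit would read 1.  Since the selector is
known to the *sender* (it is the stored gap tag of the value being emitted),
the package configures the last column before the broadcast — \{N,S,EW\}
(pass, per row) when the selector is 1, \{NS,E,W\} (block) when 0 — which
preserves the unit count, the single-broadcast cost, and the input/output
behaviour, and replaces the timing argument with configure-then-broadcast.

# The DP mesh

Each cell of the `(n+1) × (n+1)` alignment matrix combines three
adder/subtractors and a max switch: the diagonal input gains
`s(x_i, y_j) ≥ 0`, the vertical and horizontal inputs lose `|g|`, and the
switch forwards the maximum.  The first row and column are held at zero —
the initialisation the model states for all three algorithms, which makes
leading gap runs free (the oracle and the mesh agree on this convention; it
is *not* the textbook global-alignment boundary `−i·|g|`).  Smith–Waterman
adds the floor value (0, or the scale-up shift β for scaled schemes) as a
fourth max input; the LCS cell follows the 4-way-switch routing — on a
match only the incremented diagonal value passes, on a mismatch only the
max of up/left — with the gap cost pinned to zero.

**Hierarchical simulation.**  Values flow only down and right, so the
package evaluates the assembly component by component in row-major
(topological) order, passing 1UN values between cells at port level.  This
is functionally equivalent to the one-shot flat broadcast: every component
is itself evaluated through the bus simulator in a single broadcast, and the
composition graph is acyclic with the same dataflow.  A monolithic flat
layout of a full alignment mesh is not constructed — the inter-component
routing is not specified at bit level, and a flat `O(n³)` port
graph at useful `n` would add memory cost without adding checking power.
Resource accounting still reports flat totals.

**Scaling.**  Two scale-up notions coexist and are kept deliberately
distinct:

* `scale_up(matrix, g)` implements the stated recipe on its own terms:
  β = max(0, −min(scores ∪ {g})), everything including the gap shifted so
  the minimum is ≥ 0 (equivalently: antilog, multiply the probabilities by
  `a^β`, log again — the test suite checks the two routes agree).
* The DP pipeline shifts **only the substitution matrix**.  The gap must
  remain a *subtraction* through the "−" units — the underflow discussion
  and the subtractor units in the cell construction presuppose it — so the
  mesh subtracts `|g|` unchanged.  With the matrix non-negative, every cell
  value stays non-negative (the diagonal chain from the zero boundary
  guarantees it), underflowed gap candidates always lose the max, and the
  mesh provably equals the signed sequential recurrence.

Whether a β-shift preserves the *argmax* alignment is a separate question:
paths with different numbers of diagonal steps shift by different totals, so
in general it need not.  The package therefore does not claim it;
`rescore_original()` recovers the original-scheme score of a traced path by
a functional prefix-sum, and the test suite asserts the recovered score
equals the oracle optimum in the β = 0 case, where the question is vacuous.

**Affine gaps.**  Values gain a one-bit selector: 1 means already
gap-penalized.  The modified "−" unit subtracts the extension cost `g`,
then either charges the extra opening cost ε = o − g, or — when the
selector is 1 — admits the un-ε-charged branch through the on/off switch
and lets a 2-input max pick the larger, so the effective charge is `o` on
opening and `g` on extension.  Gap-sourced values leave with selector 1;
diagonal-sourced values carry selector 0.  One contract point is ours: when
a gap-penalized and a fresh candidate *tie* at a cell's max switch, the
resulting tag is the OR of the tags of the maximal candidates.  (A fully
literal bit-plane OR would fold in the tags of *losing* candidates too and
set the tag almost everywhere, degenerating the scheme; the prose rule is
clearly per-value.)  The mesh and the sequential tagged-bit oracle share
this contract, and the suite checks them against each other on random
instances, and against both the linear recurrence and the Gotoh
three-matrix oracle in the `o = g` case where all three provably coincide.
Whether the single-matrix tagged scheme equals Gotoh in *all* cases is left
as an empirical question; the tests record agreement on the instances they
run, not a theorem.

**Back-tracking.**  The maximum cell is located by the staged
cube procedure: rows fan out to slices, each slice finds its row maximum
with the flag-bit subroutine (`f(i,j) = a_i > a_j`; a column whose ORed
flags are zero holds the max), the winning column indices return, and a
final flag round fixes the row — ties land on the lexicographically
smallest `(i, j)`, which the linear-scan oracle mirrors.  The trace then
follows, from the end cell, the neighbor whose *penalized contribution*
achieved each cell's value — the value that actually won the cell's max
switch in the forward pass — so the decoded path always reproduces the
matrix score (asserted on every random traceback in the suite).  Equal
contributions default to the deterministic preference diagonal > up > left;
the model's "randomly selects one" is available as a seeded option, kept
off by default for reproducibility.  Local alignment stops at the first
cell holding the floor value.

# Sum-of-pairs in counting form

The column-pair score is computed from the per-symbol counts of the two
columns' **merged residue pool**:
`Σᵢ C(nᵢ,2)·s(i,i) + Σ_{i<j} nᵢnⱼ·s(i,j)`.  The merged pool includes
within-column pairs — that is what the worked 15-pair expansion of columns
ACT and GTT contains — even though the nested-sum notation of the pairwise
definition reads as cross-column-only; the expansion is taken as normative
and the brute-force oracle enumerates the same pool, so the headline
"counting form ≡ brute force" property is checked on like terms.  The gap
is a symbol type (alphabet size T + 1); the gap–gap score is not defined by
the model and defaults to 0 (configurable).

# Guide trees

Neighbor joining follows the five classic steps.  Implementation choices:

* Join selection minimises `M_ij = D_ij − r_i − r_j`, computed in the
  integer-exact form `(m−2)·D_ij − ΣD_i − ΣD_j` to keep tie detection
  deterministic on integral distances.  (The mesh description mentions
  locating a *max* at this step; minimisation is the standard and
  implemented reading.)
* Ties resolve to the pair with the smallest `D_ij` — "the pair of nodes
  with the shortest distance" — then to the lexicographically smallest
  label pair.
* The stated distance update `D_vu = D_iv + d_jv − D_ij` mixes matrix and
  branch-length symbols and omits the ½ of the standard derivation; the
  default is the standard `(D_iv + D_jv − D_ij)/2`, with
  `literal_update = TRUE` available for the stated form read with `d_jv`
  as `D_jv`.
* Branch lengths are computed even though the merge order alone drives the
  progressive stage; Newick output needs them.  At `m = 2` (including the
  final pair) the nodes join directly with half the distance each, since
  `r` is undefined there.
* The score-to-distance transform is unspecified upstream;
  `distances_from_scores()` uses `D = max(S) − S` with a zero diagonal —
  any monotone-decreasing transform yields the same join order, and this
  one keeps integral scores integral.

Clustering is implemented sequentially: the mesh realisation of the five
steps is a complexity argument, not a different algorithm, and its unit
counts are reported analytically in the resource log.

# Progressive alignment

Merges run in guide-tree creation order (children always precede parents).
Group-to-group DP runs over columns, the diagonal score being the
counting-form sum-of-pairs of the two columns and a gap step charging the
sum-of-pairs of the column against an all-gap column — no extra
per-sequence multiplier, which keeps the group step literally the pairwise
step with a different score table (two singleton groups reduce *exactly* to
pairwise DP, a reduction the suite asserts).  Because merged columns can
score negative, each merge shifts its diagonal score table non-negative
(the group-level analogue of the matrix scale-up); the shift is part of the
algorithm and applied identically on every engine, so the mesh and
reference engines, and the independently coded sequential reference
(`oracle_progressive()`), produce identical alignments under the shared tie
policies.  Row order of the result is the input order, and de-gapping the
output recovers the inputs exactly.

# Synthetic data

`synth_family()` draws one random ancestor and mutates independent copies:
per-position substitutions (always to a different symbol) at rate 0.1 and
indels at rate 0.05 (split evenly between deletion and insertion), defaults
chosen as a realistic closely-related DNA family at the scale the mesh
engine targets (m = 6 sequences of length 12 — the simulator's unit counts
grow as n³, so these are desk-scale sizes, and the upstream constructions
themselves are stated for small constant score magnitudes).  Families
regenerate bit-exactly from a seed through a private RNG stream.  What the
generator does *not* emulate: rate heterogeneity along the sequence,
indel length distributions (all indels are single-column), back-mutations
correlated across lineages, and composition bias.  A green end-to-end test
therefore establishes that the mesh pipeline equals the sequential
reference on tree-structured families of this kind — not that either is a
biologically competitive aligner.

# Resource accounting

The constant-run-time claims are not wall-clock measurable in a simulator,
so they are accepted through unit accounting.  `pu_accounting()` reports
the stated closed forms — 1 / 4 / `n` / `4n` for the max switches,
`n(n+1)` for the on/off switch, `k×n` for the adder, `10n` per DP cell for
unit-constant schemes (hence `10n³` per DP mesh), `n³` for back-tracking,
`m³` for clustering, `m·n²` for sum-of-pairs, and the pipeline totals —
and `msa_resource_log()` instantiates them for a run's `n`, `m`.  The
simulator's own `pu_count()` values agree with the component formulas where
both exist (4-input switch, n-bit switch, adder, on/off) but can be
*smaller* than the per-cell accounting: the stated `10n` counts `2n`
per adder/subtractor while the `k×n` construction with the k-row reduction
needs `n` at `k = 1` — an inconsistency internal to the source accounting.
Both numbers are reported, never blended.

# Known limitations

* The flat single-broadcast layout of a whole DP mesh is not constructed
  (see above); component-level simulation plus the acyclic composition
  argument stands in for it.
* Affine traceback reconstructs a path consistent with the tagged-bit
  matrix; where the tagged scheme diverges from Gotoh (if it does), the
  package follows the tagged scheme.
* The aligner itself is quadratic-time sequential R per instance with
  large constants; it exists to certify the constructions, not to compete
  with production aligners.
* Protein alphabets and NCBI-format matrices are supported throughout, but
  all seeded validation families are DNA.
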