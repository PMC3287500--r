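# rmeshalign

Progressive multiple sequence alignment on a simulated reconfigurable mesh
(r-mesh), with every stage of the pipeline — pairwise dynamic programming,
guide-tree clustering, sum-of-pairs group alignment — cross-validated against
independent sequential reference implementations.

## Who this is for

The r-mesh is a parallel computing model: a grid of processing units whose
four ports (N, S, E, W) can be fused into groups, dynamically forming buses
that carry a broadcast signal in one step.  On this model, pairwise sequence
alignment by dynamic programming can be made to run in constant time, and the
whole progressive multiple-alignment paradigm for `m` sequences of length up
to `n` in `O(m)` time using `O(m n³)` processing units (three-valued
match/mismatch/gap schemes) or `O(m n⁴)` units in general.  This package is
for people who want to *study* those constructions: it simulates the
electrical bus semantics port by port, builds the described components on top
of them, and checks each one against a plain sequential oracle — it is a
correctness instrument, not a fast aligner.

## The model in brief

Numbers travel in the unary `1UN` format: a value `x` in `w` bits is a prefix
of `x + 1` ones (`3` at width 8 is `11110000`); all-zeros marks underflow.
Because buses OR their drivers and 1UN encodings are prefixes, a bitwise OR
of encodings *is* the maximum — that single fact powers the max switches.
On top of them:

* **max switches** — 1 unit (2-input, 1-bit), 4 units (4-input), `4w` units
  (`w`-bit), all resolving in one broadcast;
* **adder/subtractor** — a `k × w` mesh (`k` = magnitude of the predefined
  operand) that shifts a 1UN prefix diagonally, one column per row, in one
  broadcast; subtraction below zero yields the all-zero underflow pattern;
* **on/off switch** — a `w × (w+1)` mesh gating a value by a selector bit,
  used by the affine-gap extension (values already gap-penalized carry a tag
  bit and are charged only the extension cost);
* **DP cell** — three adder/subtractors (diagonal `+s(x_i, y_j)`, vertical
  and horizontal `−|g|`) feeding a 3-input max switch; cells compose into the
  alignment mesh for Needleman–Wunsch, Smith–Waterman (floored at the
  scale-up shift `β`) and LCS, with the classic zero first row/column
  initialisation `c_{0,j} = c_{i,0} = 0`;
* **sum-of-pairs in counting form** — column-pair scores computed from
  per-symbol counts, `Σᵢ C(nᵢ,2) s(i,i) + Σ_{i<j} nᵢ nⱼ s(i,j)`, so the cost
  is independent of the number of sequences;
* **neighbor joining** — the standard `M_ij = D_ij − r_i − r_j` construction
  for the guide tree, with Newick output.

## Worked example

```r
library(rmeshalign)

sc <- scoring_scheme(match = 2, mismatch = 0, gap = -1)
rmesh_align("GATTACA", "GCATGCA", sc, mode = "nw", engine = "mesh")
#> pairwise NW alignment, score 8
#>  GATTACA
#>  GCATGCA

fam <- synth_family(m = 5, n = 10, seed = 11)   # seeded mutate-from-ancestor family
res <- progressive_msa(fam$seqs, sc, engine = "mesh")
res
#> progressive MSA of 5 sequences (mesh engine)
#>  seq1         CCTATAA-CT
#>  seq2         CCTAT-ATCC
#>  seq3         CCTATAATCT
#>  seq4         CCTATAATCC
#>  seq5         TCTATAATCT
#> guide tree: (seq1:1.25,((seq2:2.66667,seq4:0.333333):1.5,(seq3:0,seq5:2):0.5):1.25);
#> merge scores:  17,  18, 127, 156
```

The score 8 is four matches at +2 with no gaps under this scheme; the family
alignment recovers the shared ancestry of the five mutated copies (stripping
the gaps returns the inputs exactly), the guide tree lists the
neighbor-joining merge order with branch lengths, and the merge scores are
the group-DP optima of the four merges, in order.  `res$resource_log` holds
the processing-unit accounting for the run (here 50 625 units for the
`m = 5`, `n = 10` constant-scheme pipeline); the mesh components themselves
report their simulated sizes, e.g.

```r
un_decode(adder_subtractor(3, 3, "add", 8))   # 6, computed on a 3-row mesh
pu_count(build_adder_subtractor(3, 8))        # 24 = k x w units
```

A thin command-line front end with `align`, `msa`, `tree` and
`simulate-component` subcommands is installed at
`system.file("scripts", "rmeshalign", package = "rmeshalign")`.

## Acceptance script

`scripts/acceptance.R` re-derives, by running the package from scratch, the
checkable quantities the constructions commit to: the 8-bit unary encoding
of 3, the unit count of the 1-bit 4-input max switch (after verifying its
full truth table), and the row count of the adder mesh for the worked
addition 3 + 3.  Run it from the repository root against the installed
package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
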