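# geobuild

Reconstruction of 3D molecular structures from **sparse sets of exact
inter-atomic distances** — the molecular distance geometry problem (MDGP) —
using the geometric build-up family of algorithms, for structural
bioinformaticians working with NMR-style short-range distance data.

## The method

A point in 3D is uniquely determined by its distances to four positioned,
non-coplanar points (*a metric base*): from the sphere equations
`||x − x_i|| = d_i, i = 1..4`, squaring and subtracting the first leaves
the nonsingular linear system `A x = b` with `A = 2 (x_2−x_1; x_3−x_1;
x_4−x_1)`. Build-up algorithms exploit this to place one atom at a time,
starting from an initial 4-clique of the distance graph. The package
implements three variants:

* **GB** — general build-up: trilateration against current coordinates;
  fast, but rounding error compounds from placement to placement.
* **UGB** — updated build-up: each 4-atom base with all six mutual
  distances in the input is *re-initialized* exactly in a canonical local
  frame, the new atom is solved there, and the 5-atom K5 complex is
  rigidly mapped back (Procrustes rotation `Q = U V^T` from the SVD of
  `C = Y1^T X1`), replacing the old base coordinates. Updating stops
  error accumulation.
* **RUGB** — revised updated build-up: the base is relaxed to **three**
  atoms with original mutual distances plus one disambiguating atom that
  resolves the two mirror-image candidates, and base search walks only
  per-atom adjacency arrays whose length is bounded by the maximum degree
  `d_max` (O(d_max³) per atom). Faster searches and, empirically, smaller
  error than UGB.

Because exact distances cannot distinguish enantiomers, reconstructions
are compared to a reference by aligned RMSD minimised over rotations *and*
reflection (`used_reflection` reports which enantiomer was built).

## Worked example

```r
library(geobuild)

## a 300-atom protein-like chain with a 5 A cutoff graph, solvable by design
inst <- generate_solvable_instance(
  generator_config(n = 300, mode = "chain", cutoff = 5, seed = 42))
degree_stats(build_adjacency_index(inst$dset))
#> n=300  d_max=83  d_max/n=0.2767   (5185 distance pairs kept)

res <- solve_buildup(inst$dset, solver_options("rugb"))
res
#> recon_result: status complete, 300/300 atoms positioned, 1 restart(s)

aligned_rmsd(res$structure, inst$structure)
#> aligned RMSD: 1.08e-12 A (reflection used: TRUE)
max_distance_violation(res, inst$dset)
#> 4.93e-12

run_experiment(reference = inst$structure, dset = inst$dset)
#>   algorithm   status n_total n_positioned restart_count aligned_rmsd max_violation
#> 1        gb complete     300          300             1     6.08e-08      1.20e-06
#> 2       ugb complete     300          300             1     9.63e-12      4.95e-11
#> 3      rugb complete     300          300             1     1.08e-12      4.93e-12
```

The RUGB reconstruction reproduces the hidden ground truth to ~1e-12 Å;
plain GB, with no updating, is already four orders of magnitude worse at
this size and degrades much further on larger or sparser instances.

Real structures enter through `read_pdb()` (default selection: first
model, ATOM records, hydrogens kept, altloc ''/'A'), and
`build_distance_set(structure, cutoff)` produces the MDGP instance; the
distance-list TSV format (`read_distance_list()`/`write_distance_list()`)
serializes instances. A command-line interface wrapping the same functions
ships at `inst/cli/geobuild.R` with subcommands `reconstruct`, `evaluate`,
`graph-stats`, `simulate` and `experiment`.

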