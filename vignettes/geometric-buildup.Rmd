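---
title: "Geometric build-up reconstruction from sparse exact distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric build-up reconstruction from sparse exact distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geobuild)
```

## The problem

The molecular distance geometry problem (MDGP) asks for 3D coordinates of
`n` atoms consistent with a given set of inter-atomic distances. Distances
come from chemical knowledge (bond lengths, bond angles) or NMR experiments;
in the NMR regime essentially only distances below about 5 Å are observable,
so the available distance set is sparse. The general MDGP is NP-hard, but
when the distances are *exact* and sufficiently many, a family of fast
*geometric build-up* algorithms solves it by placing one atom at a time.

A point in 3D is fixed uniquely by its distances to four positioned,
non-coplanar points (a *metric base*): squaring the four sphere equations
and subtracting the first from the rest leaves a nonsingular 3×3 linear
system (`trilaterate4()`). With only three non-collinear reference points
there are two solutions, mirror images across the base plane
(`trilaterate3()`); a known distance to any fourth positioned atom off that
plane picks the correct one (`disambiguate()`).

## The three solvers

All three solvers share an outer loop: seed four atoms from an initial
4-clique of the distance graph (four atoms with all six mutual distances
known, realized in a canonical frame by `init_tetrahedron()`), then sweep
the unpositioned atoms in ascending id order, placing every atom for which
a base is found. If a full sweep places nothing, the solver restarts from
the next 4-clique in lexicographic order, keeping the best partial result.

* **GB** places an atom from any four positioned, non-coplanar neighbours
  by plain trilateration against their *current* coordinates. Each
  placement inherits the error of earlier ones, so rounding error
  compounds as the build-up proceeds — on sparse data catastrophically.

* **UGB** requires the four base atoms to have all six mutual distances in
  the *original* input. The base tetrahedron is then rebuilt exactly in a
  local frame from those distances, the new atom is solved there (the five
  atoms form a K5 complex whose ten distances are all original), and the
  fresh complex is rigidly mapped back onto the old base positions
  (`reinsert()`, Procrustes rotation via SVD). The mapped base coordinates
  *replace* the old ones. This updating stops error accumulation.

* **RUGB** relaxes the base to three atoms with original mutual distances
  plus one extra positioned neighbour used only to disambiguate the mirror
  candidates, and searches for bases only inside the atom's adjacency
  array. Since the length of those arrays is bounded by the maximum degree
  `d_max`, which is small relative to `n` on cutoff graphs, a base search
  costs O(d_max^3) per atom instead of a search over all atom subsets.

The rigid map is allowed to be improper (determinant −1): the canonical
tetrahedron produced from distances may be the enantiomer of the placed
base, and only a roto-reflection can carry it onto the old coordinates.
Exact distances cannot distinguish enantiomers at all, so the global
chirality of the reconstruction is arbitrary; `aligned_rmsd()` resolves it
at evaluation time by minimising over the reflected superposition too and
reporting `used_reflection`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `degeneracy_rel_tol` | 1e-8 | scale-invariant threshold for coplanar/collinear base rejection (determinant over edge-norm product) |
| `distance_consistency_tol` | 1e-6 Å | residual tolerance for trilateration on original distances, and for mirror disambiguation |
| `max_restarts` | 25 | initial 4-cliques tried before accepting the best partial result |
| `cutoff` | 5 Å | distance-graph cutoff (inclusive: pairs with d ≤ cutoff are kept) |

The degeneracy tolerance matters because a near-flat base amplifies
placement error roughly by the inverse of its relative height; 1e-8 rejects
only bases that are flat to roundoff levels. The consistency tolerance is
deliberately loose relative to machine precision — inputs are exact, so a
violation signals corrupted input rather than noise. GB alone runs its
trilateration with the residual check disabled: its base coordinates
legitimately accumulate error, and that growth is the phenomenon the
algorithm comparison is about.

## Base selection among valid candidates

Where several valid bases exist for an atom, candidates are enumerated
lexicographically but *attempted* in order of geometric conditioning: the
product of the triangle's relative height (twice the area over the squared
longest edge) and the extra atom's relative off-plane distance (RUGB), with
ties broken by enumeration order. The first lexicographic triangle is
frequently a sliver, and sliver bases are exactly the flat-tetrahedron
failure mode that inflates reconstruction error; ranking by conditioning is
deterministic and measurably reduces RUGB error below UGB's, which is the
qualitative behaviour the method family is known for. Candidate
enumeration per atom and sweep is capped (200 coplanarity tests for GB
4-subsets, 50 quadruples for UGB, 30 triangles for RUGB) to bound
worst-case sweeps; a truncated atom is simply revisited on a later sweep.

## The synthetic generator

Real NMR-style inputs are PDB coordinates turned into cutoff distance
graphs (`read_pdb()` + `build_distance_set()`). For self-contained testing
the package generates protein-like ground truths:

* **chain** mode: a self-avoiding random walk with exact 1.5 Å bonds,
  1.0 Å excluded volume, and direction persistence, confined to a sphere
  sized for 0.05 atoms/Å³ — protein interior packing density. This makes
  5 Å cutoff graphs locally dense enough to contain metric bases while
  staying globally sparse.
* **cloud** mode: uniform points at the same density with the same minimum
  separation, used mainly for complete-distance exactness checks.

`generate_solvable_instance()` additionally verifies — by a purely
combinatorial dry run of the RUGB base-existence check, no coordinates
involved — that a build-up ordering positioning all atoms exists, raising
the cutoff by 10% (bounded) if not. Geometric degeneracies are left to the
solvers and surface as restarts.

What the generator does *not* emulate: covalent geometry beyond a fixed
bond length (no angles, rotamers or secondary structure), heteroatoms,
and crystallographic artefacts. Passing tests on synthetic instances
therefore demonstrate numerical correctness of the build-up machinery on
solvable sparse exact-distance instances, not robustness to real
experimental data with distance *ranges*, which are out of scope.

## Numerical choices

* Canonical frames fix orientation deterministically (atom 1 at the
  origin, atom 2 on +x, atom 3 in the xy-plane with y ≥ 0, atom 4 with
  z ≥ 0), so identical distances give bit-identical local coordinates.
* `init_tetrahedron()` accepts a squared height for atom 4 down to
  −1e-8·d₁₄² (clamped to zero) to absorb roundoff in exact inputs, and
  rejects anything flatter as degenerate.
* A linear solve that fails numerically inside `trilaterate4()` (base flat
  at machine precision despite passing the relative-determinant test) is
  reported as a degenerate base so solvers skip it.
* Sweep order is ascending atom id; restarts enumerate initial 4-cliques
  lexicographically. Determinism throughout makes every run reproducible.
* Atom ids are 1-based internally (the R convention) and 1-based in all
  file formats (PDB serials, the distance-list TSV).

## Problem sizes and what the checks compute

The package's standard self-checks use 200-atom clouds with complete
distances (all three algorithms must reconstruct to RMSD ≤ 1e-8 Å) and a
20-seed study of 300-atom chains at the 5 Å cutoff, sizes at which the
whole study runs in well under a minute. On that study the observed
pattern is: RUGB completes every instance with median aligned RMSD around
1e-13–1e-12 Å, UGB around 1e-11–1e-10 Å, and GB — without updating —
drifts to errors many orders of magnitude larger, often rendering the
structure meaningless. That ordering, and the roughly 10³–10¹³-fold
GB/RUGB error ratio, is the package's reproduction of the known behaviour
of the algorithm family; `scripts/acceptance.R` recomputes all of it from
scratch.

## Known limitations

* Exact distances only: distance intervals/bounds (the real NMR setting)
  are not solved.
* O(n²) pair generation and a dense distance-lookup matrix limit practical
  sizes to a few thousand atoms, ample for the intended use.
* Success on sparse data depends on the input graph admitting a build-up
  ordering; when it does not, the result is an honest `partial` status
  with the largest positioned subset found across restarts.
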