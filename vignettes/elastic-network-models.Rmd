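---
title: "Elastic network models and ensemble comparison: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic network models and ensemble comparison: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmodes)
```

# The model and its assumptions

An elastic network model replaces a biomolecular structure with N point
masses connected by harmonic springs and asks only one question: given this
connectivity, what are the directions and relative amplitudes of thermal
motion around the input conformation? The assumptions are strong and worth
stating plainly:

* the input conformation is the energy minimum — the model cannot predict
  the minimum, only fluctuations about it;
* all interactions are harmonic with a single stiffness scale γ (or a
  simple distance-dependent profile), so chemistry enters only through
  geometry and packing density;
* motion is overdamped/thermal: eigenvalues are squared mode frequencies in
  units of γ, and all reported fluctuation magnitudes are relative — only
  ratios and correlations are meaningful until scaled against experiment.

Within those assumptions the low-frequency modes of the spring network are
robust predictors of collective functional motions, which is why the model
family has survived with so little chemistry in it.

Two variants are built here. The **GNM** works on the N×N Kirchhoff matrix
(graph Laplacian of the contact graph) and predicts fluctuation
*magnitudes* only; a connected network has exactly one zero mode (the
all-ones vector). The **ANM** assembles the 3N×3N Hessian from 3×3
super-elements −(γ/d²) r rᵀ per contact and adds *directions*; a connected,
non-collinear network has exactly six zero modes (rigid translations and
rotations). Both matrices are symmetric positive semidefinite by
construction, and the test suite asserts this, the zero-mode counts, and
covariant transformation of the Hessian under rigid rotation.

All fluctuation quantities flow from the spectral pseudo-inverse over
non-zero modes (modes 2..N for GNM, 7..3N for ANM): the per-node diagonal
(MSF), the pair contraction G_ii + G_jj − 2 G_ij (internal distance
fluctuations, contracted onto the inter-node unit vector in the ANM case),
normalized cross-correlations, and per-node 3×3 covariance blocks (ADP
tensors comparable to crystallographic ANISOU records).

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| GNM cutoff r_c | 7.3 | Å | customary value capturing first-shell CA contacts |
| ANM cutoff r_c | 13 | Å | upper end of the customary 10–13 Å band; ANM needs a denser graph for stable directional modes |
| γ | 1 | arbitrary | pure scale; cancels in correlations and overlaps |
| weighted exponent p | 2 | — | inverse-power springs k = γ/d^p over *all* pairs; p is not fixed by the model family, so it is exposed (p = 0 degenerates to a complete uniform graph) |
| nearest-neighbor atomic cutoff | 4.5 | Å | heavy-atom contact distance; decides coarse connectivity from atomic packing |
| mixed-resolution cutoffs | (r_atomic, r_coarse) | Å | cross-region pairs use √(r_atomic·r_coarse); the geometric mean keeps the cross scale between the two regimes |
| zero-mode tolerance | 1e-8 × λ_max | — | scale-free, so the γ choice cannot reclassify rigid modes |

The cutoff comparison is **inclusive** (d ≤ r_c). The strict reading
("less than") differs only on measure-zero ties, but lattice fixtures hit
those ties constantly, so the choice is documented and tested.

# Numerical choices

**Eigensolvers.** The dense path is LAPACK's symmetric solver; eigenvalues
are re-sorted ascending and eigenvector signs fixed by making the
largest-magnitude component positive (eigenvectors are sign-ambiguous, and
a fixed convention makes runs byte-reproducible). The sparse path computes
the lowest k pairs by shift-invert: ARPACK (via igraph) applied to
(H + σI)⁻¹ using a sparse Cholesky factor, with eigenvalues recovered
exactly as 1/μ − σ. Agreement with the dense path is tested at 1e-8
relative on eigenvalues for all shared modes; eigenvectors are compared
only at simple eigenvalues, because symmetric fixtures have degenerate
eigenspaces within which individual vectors are arbitrary.

**Superposition.** Frames are fitted by the Kabsch SVD rotation (with the
determinant correction to exclude reflections). The ensemble default
iterates fitting against the running mean. Two details are deliberate
deviations from the obvious implementation: the convergence tolerance is
1e-10 on the mean shift (not the looser 1e-6 one might pick), and after
convergence the whole system is re-anchored by aligning the mean onto the
input's first frame. The reason is that the iterate-to-mean fixed point is
unique only up to a *global rigid transform*; without the anchor, re-running
superposition on its own output drifts by whatever orientation the iteration
happened to stop at. With both choices, re-superposing aligned frames moves
coordinates by less than 1e-8 Å, which the property suite asserts.

A related subtlety shows up in a test oracle: displacing one node of a
10-node frame by 1 Å gives a *raw* RMSD of 1/√10, but any least-squares fit
necessarily removes the translational and rotational components of that
displacement, landing strictly below. The test checks the bound and the
exact post-fit value against a rigid-body projection oracle evaluated in a
wide-cloud geometry where the first-order projection is exact to tolerance.

**PCA.** Uniform node weights, covariance of mean-centred flattened
coordinates, SVD of the deviation matrix (numerically preferable to forming
the 3N×3N covariance), at most min(3N, M−1) non-trivial components from M
frames. Coordinate layout (x1, y1, z1, x2, ...) matches the ANM mode layout
so PCs and modes are directly comparable. PCs are compared only against
non-zero modes. Overlap, cumulative overlap and RMSIP are all absolute
inner products, hence invariant to the sign conventions on either side;
reports flag CO > 0.5 (strictly greater) as significant.

**Spherical coarse-graining.** The greedy radius packing is stated as:
retain the seeds; remove every unretained point within the radius of a
retained point; retain the unretained point *closest to the retained set*
(minimum over all retained points, ties to the lowest index); repeat. The
"closest to the whole retained set" reading — rather than closest to the
last-retained point — was chosen because it is deterministic and
order-independent; the two readings coincide on the collinear reference
case. The result satisfies both packing properties (retained pairs > r
apart; removed points ≤ r from the retained set), asserted by brute force
on random instances.

**Density maps.** Candidate points are all voxel centers at or above the
contour threshold (filled volume, with the contour as lower bound), then
spherically coarse-grained seeded at the densest voxel. The
surface-voxels-only alternative reading would thin shells further but
cannot be distinguished from the available description; filled volume was
chosen because packing-density fidelity is what the downstream model uses.
The MRC reader normalizes any MAPC/MAPR/MAPS axis order to X-fastest
internally and refuses non-orthogonal cells and exotic storage modes.

**Degenerate inputs.** Exactly coincident nodes are rejected when a point
model is built (a zero-distance spring is undefined in both models);
selections matching nothing, empty density contours, constant experimental
B-vectors, zero-MSF nodes in correlations, and zero-mean subsets in
directional correlations all have explicit error or set-to-zero-and-log
policies rather than NaN propagation.

**Collectivity.** The exponential-entropy measure
κ = N⁻¹ exp(−Σ u_i² ln u_i²) over per-node squared displacement fractions:
1/N for a fully localized mode, 1 for uniform participation. No formula is
fixed by the model family's description; this is the standard choice and is
flagged as such. Similarly, subset directional correlations use the cosine
between subset *mean displacement vectors* (not averaged pairwise cosines —
the alternative reading), which makes antiparallel rigid halves give
exactly −1.

# What the synthetic fixtures do and do not establish

The fixture generator produces cubic lattices, helical CA traces with a
bowl-shaped B-factor profile, two-domain hinge toys, rank-1 deformation
ensembles with optional Gaussian noise, and Gaussian-blob density grids —
every input type the toolkit consumes, deterministic under a seed. These
are *stated worlds*: the rank-1 ensemble makes PCA recovery exactly
checkable (PC1 must equal the generating direction at σ = 0), and the
lattice makes zero-mode counts and contact counts hand-derivable.

What green tests on fixtures do not establish: that any particular protein's
functional motion is captured (that depends on the structure, not the code),
realistic noise statistics (crystallographic and NMR uncertainty is neither
isotropic nor Gaussian), or force-field realism (fixture conformers are
geometric, not physical). The one published benchmark tied to a real
structure — the r ≈ 0.70 B-factor correlation for HIV-1 protease — needs a
download and therefore lives in a clearly-marked optional script outside
the test suite.

One fixture behavior worth knowing: a cubic lattice whose cutoff admits
only axis-aligned springs gives an ANM with a *large* null space (motions
perpendicular to all of a node's bonds cost nothing). That is correct
physics, not a bug; connected fixtures used for zero-mode tests always
include diagonal contacts.

# Known limitations

* No mmCIF, compressed-trajectory, symmetry or assembly support; PDB is
  fixed-column only, and coordinates ≥ 10000 Å are refused on write.
* The weighted scheme stores a complete graph — memory is O(N²); use the
  cutoff schemes for large systems, where matrices stay sparse.
* Torsional/bond-angle energy terms (Spring-Tensor-style models) and
  Markov propagation analyses are out of scope.
* ANISOU output rounds U×1e4 to integers, the format's own precision.
* The altloc policy (keep blank/'A', drop others) and insertion-code
  handling (part of residue identity) are documented package choices, not
  facts about any upstream convention.
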