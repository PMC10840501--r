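---
title: "Multiscale bead-chain reconstruction of 3D chromatin: model and methods"
author: "chromfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale bead-chain reconstruction of 3D chromatin: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfold)
```

## The problem

A Hi-C experiment counts, over millions of cells, how often every pair of
genomic bins is found in spatial contact, yielding a symmetric contact
matrix per chromosome. The matrix constrains — but does not determine — the
3D path of the chromatin fibre: the inverse problem is severely ill-posed,
and the cell population itself is structurally heterogeneous. `chromfold`
therefore does not reconstruct a single consensus structure. It samples a
*population* of configurations compatible with the data, then validates the
ensemble by re-simulating a contact matrix from it and comparing with the
input by rank (Spearman) correlation.

Two modelling commitments distinguish the approach from distance-geometry
methods:

1. **No contact-to-distance conversion.** Contact counts are used directly
   as evidence of proximity; pairs that touch rarely are *not* assumed to be
   far apart. This avoids generating inconsistent target distance matrices.
2. **Multiscale decomposition.** At every observable scale chromatin is
   organised in compact, TAD-like domains with dense internal contacts and
   sparse external ones. Each diagonal block of the matrix is reconstructed
   independently, then summarised as a single "modified bead" of the next
   coarser chain, recursively, which keeps each optimisation problem small.

## The solution model

A chain element is a **modified bead**: centroid $C$, in/out endpoints, and
an approximate radius $r$. Consecutive beads share an endpoint, so the chain
is connected by construction and flexes only at the shared endpoints; every
move is rigid on each bead. A bead at scale $\ell+1$ stores the whole chain
it summarises at scale $\ell$ as its *payload*, together with its reference
triple (endpoint-in, centroid, endpoint-out), so that after the coarse chain
is rearranged the payload can be transported rigidly back to the finer scale
(`refine_chain()`).

The relative pose of consecutive beads is parameterised by two dihedral
angles: $\zeta$, between the previous bead's plane $P_1$ and the hinge plane
$P_{12}$ (the two centroids plus the shared endpoint), measured about their
common line $C_1\!-\!E_{12}$; and $\xi$, between $P_{12}$ and the new bead's
plane $P_2$, measured about $E_{12}\!-\!C_2$. When $\zeta = 0$ the hinge
plane coincides with $P_1$ and $\xi$ is exactly the $P_1$–$P_2$ angle. The
bend angle $C_1\!-\!E_{12}\!-\!C_2$ is a third degree of freedom that the
pose angles leave free; `place_bead()` exposes it explicitly (default
$2\pi/3$, a generic polymer bend). The bead's internal angles are fixed once
the finer-scale chain is summarised.

## The objective

For a block with restrained pair set $L$ (pairs whose — possibly
CTCF-augmented — count $n'_{ij}$ exceeds a threshold), configurations are
scored by

$$\Xi(C) = \Phi_{HiC\text{-}TF}(C) + \mu_1\,\Phi_{ChIP}(C) +
\mu_2\,\Phi_{RNA}(C) + \lambda\,\Psi(C)$$

with

* $\Phi_{HiC\text{-}TF} = \sum_{(i,j)\in L} n'_{ij}\,
  (D^{min}_{ij}/d_{ij} - 1)^2$, where $d_{ij}$ is the centroid distance and
  $D^{min}_{ij} = r_i + r_j$ the touching distance. Each restrained pair is
  happiest exactly at touching distance; violations are weighted by the
  contact count. Interpenetration ($d < D^{min}$) is permitted and only
  mildly penalised here.
* CTCF anchors (ChIA-PET pairs) enter by adding a pseudo-count
  (`tf_factor`, default 100) to the matrix at each anchor bin pair before
  thresholding; with no anchors the term reduces bitwise to the pure Hi-C
  fit. Because the pseudo-count is added even where Hi-C rows are missing,
  CTCF information can re-create restraints in masked regions — the rescue
  mechanism probed by `run_ctcf_rescue()`.
* $\Phi_{ChIP} = (\max_{ij} d_{ij} - D_{min})^2$ when the block carries
  H3K27me3 (strict packing), else 0; $\Phi_{RNA} = (\min_{ij} d_{ij} -
  D_{max})^2$ when it overlaps expressed genes (loose packing), else 0.
  $D_{min} = D_c\rho^{6/5}/(6\pi)$ and $D_{max} = 2 D_{min}$ are
  polymer-scaling bounds on the physical size of an element of genomic size
  $\rho$ kbp, with $D_c = 30$ nm the chromatin filament diameter. These
  terms act only at the finest scale, where the track resolution is
  meaningful.
* $\Psi = \sum_{i<j} \psi(d_{ij}/D^{min}_{ij})$ is a soft steric prior (see
  below).

### The steric kernel

The kernel must satisfy three stated behaviours: $\psi(1) = 1/2$ exactly
(touching beads mildly penalised), $\psi(\tilde d) \approx 1/\tilde d$ for
$\tilde d \ll 1$ (deep interpenetration strongly penalised), and
$\psi \to 0$ rapidly for $\tilde d \gg 1$ (far pairs unconstrained). The
implementation uses the rational sigmoid form

$$\psi(\tilde d) = \frac{1}{2\tilde d}\left[1 -
\frac{c\,u^b}{1 + c\,|u|^b}\right],\qquad u = \tilde d - 1/\tilde d,$$

with $b$ odd (default 5) and $c > 0$ (default 1). The argument
$u = \tilde d - 1/\tilde d$ is the key choice: it diverges to $-\infty$ as
$\tilde d \to 0$, driving the bracket to 2 and the kernel to $1/\tilde d$,
and to $+\infty$ as $\tilde d \to \infty$, killing the kernel at rate
$O(\tilde d^{-(b+1)})$; the naive argument $\tilde d - 1$ saturates at $-1$
on the left and cannot produce the $1/\tilde d$ limit for finite $c$. As in
the design intent, $c$ controls the width of the moderate-penalty plateau
around $\tilde d = 1$ and $b$ the steepness of its flanks. All three
behaviours are enforced as tests, not assumed.

### Weights

$\mu_1 = \mu_2 = 1$ by default. $\lambda$ cannot be a constant: the
magnitudes of the data and prior parts change with the scale and with the
block. It is re-tuned for every block at every scale on that block's
*initial* configuration, as
$\lambda = \text{ratio} \times (\Phi_{HiC\text{-}TF} + \mu_1\Phi_{ChIP} +
\mu_2\Phi_{RNA}) / |\Psi|$, with `lambda_ratio = 1` by default (data and
prior start with equal weight). Because this quotient depends on the initial
configuration, the initialisation is part of the model specification — see
below.

## Optimisation

Minimisation uses an *approximated* simulated annealing: a fixed-budget
Metropolis scheme with geometric cooling, no convergence guarantee, and one
full run per population member. That near-optima differ between seeds is a
feature — it is what generates the ensemble. Chain moves are quaternion
rotations (axis-angle conjugation) of contiguous stretches:

* **pivot** — the chain tail from a random bead onward rotates about a
  random axis through the preceding shared endpoint;
* **crankshaft** — the beads strictly between two random beads rotate about
  the axis joining the flanking shared endpoints.

Both preserve shared-endpoint continuity and intra-bead geometry exactly by
construction. Schedule defaults: the starting temperature is calibrated so
the median-magnitude cost change of 100 probe moves is accepted with
probability about 0.8; cooling 0.95 per stage; 60 stages;
$10 \times n_{beads}$ moves per stage; maximum move angle $\pi/4$. The inner
loop (cost evaluation, moves, Metropolis test) is compiled (Rcpp) with a
private seeded generator, making every anneal bit-reproducible; the R-level
cost functions are the reference implementation and the two are held equal
in the tests.

### Initial configurations

Initial chains are self-avoiding random walks *confined to a sphere at
roughly 20% bead volume fraction* (radius $\bar r\,(5n)^{1/3}$). The
confinement reflects the modelling assumption that a diagonal block is a
compact, TAD-like domain, and it matters twice: it starts the sampler in
the physically plausible density regime, and it keeps the
$\lambda$-tuning quotient meaningful (an extended initial walk would make
the data part enormous and the prior tiny, yielding an overwhelming
$\lambda$ that freezes compaction). At coarser scales, summarised beads are
placed sequentially with random poses under the same confinement
preference.

## Multiscale orchestration

Per scale: (1) `decompose_blocks()` cuts the matrix where the
cross-boundary contact fraction in a sliding window drops below `tau`
(default 0.1), then enforces size bounds (defaults 3–40 bins) by merging
and even splitting — the TAD-like extraction algorithm is this package's
own choice, a greedy density scan; (2) each block chain is annealed and
summarised as one bead; (3) the matrix is binned block-wise (total count
conserved exactly) and the recursion continues until a single block
remains, or only blocks at the minimum size (those are then annealed
jointly as the coarsest chain). Finally the coarsest chain is expanded
top-down through the payloads back to the input resolution.

Finest-scale bead radii interpolate exponentially between the envelope
bounds at the bin's genomic size — $D_{max}/2$ at zero internal contacts
shrinking towards $D_{min}/2$ as the count grows, with the sibling mean as
the decay scale (the monotone "more internal contacts, smaller bead" rule;
the exponential form is this package's interpolation choice). Coarser bead
radii are the standard deviation along the first principal axis of the
summarised centroids — the square root of the leading covariance
eigenvalue, floored at the largest member radius: an eigenvalue has nm²
units, a radius needs nm, and the floor prevents zero-size beads for
near-coincident chains.

A block is "carrying" a track (H3K27me3 / expressed genes) when at least
50% of its genomic span is covered (configurable); genes often extend
beyond block boundaries, so partial overlap must be decided somehow and a
majority rule is transparent.

## Validation machinery

`contacts_from_configuration()` declares pair $(i,j)$ in contact when
$d_{ij} < f\,(r_i + r_j)$, with $f = 1.2$ by default (a contact is "just
beyond touching"; the value is a package default, configurable and logged).
Summing these binary matrices over an ensemble gives the estimated contact
matrix (ECM), a simulated Hi-C experiment. Comparisons use Spearman
correlation over the strict upper triangle, ties mid-ranked.

`stability_analysis()` answers "how many configurations are enough": for
each ensemble size $s$ it draws repeated subsets of $s$ configurations from
a sub-pool of $10s$, builds ECMs and reports mean and standard deviation of
their correlation with the reference block; the sd curve flattening in $s$
indicates stability.

`mask_matrix()` implements the missing-data protocol: rows and columns
within ±`halfwidth` bins of a site are zeroed and flagged ("a neighbourhood
of two loci" is read as ±2 bins, i.e. five rows per interior site;
configurable). Rescue quality is always scored against the *complete*
original block, masked bins included, because that is the quantity the
rescue is supposed to recover.

## The synthetic generator

`synthetic_spec()`/`generate_ground_truth()`/`matrix_from_structure()`
emulate the data-generating picture the method assumes: a confined
self-avoiding walk (compact domain at ~20% volume fraction, bead radius 15
nm = half the filament diameter, step = one diameter) with planted loops
(the walk is guided so a loop's later anchor lands at touching distance
from its partner), compacted H3K27me3-like regions (step × 0.6) and
decompacted expressed-gene-like regions (step × 1.6). The matrix
accumulates thresholded contacts over `n_cells = 200` jittered copies
(Gaussian centroid jitter, sd 10 nm) — Hi-C sums over a heterogeneous cell
population, and the resampling machinery needs that heterogeneity to be
real. Concordant CTCF/H3K27me3/expression tracks are emitted in the same
formats the readers consume.

What the generator does *not* emulate: sequence-dependent bias, ligation
noise, unmappable regions, genuine polymer physics (no excluded-volume
dynamics beyond the walk's clearance rule, no confinement by the nuclear
envelope), or trans-chromosomal contacts. Passing the parameter-recovery
tests therefore shows that the pipeline recovers planted structure under
its own generative assumptions — not that it is calibrated for any
particular real dataset.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on deliberately small replicas chosen to exercise
every code path: a 40-bin block with two planted loops for ensemble
recovery (five fits of 100 configurations each, against a radius-matched
random-walk baseline); a 30-bin block with a 1000-chain jittered pool for
the resampling stability analysis (sizes 25/50/100, 20 resamples, pool
multiplier 10, 20 repetitions); and the same 40-bin block with ±2-bin
masking around both loop anchors for the three-condition rescue comparison
(full / masked / masked + CTCF, five fits of 25 configurations per
condition). Masking both anchors is the regime where rescue is measurable:
on very small blocks chain continuity alone reproduces most of the rank
signal and masking barely hurts.

## Known limitations

* The annealer's fixed budget under-converges large frustrated blocks;
  restrained pairs typically sit near, not at, touching distance. The
  ensemble read-out is designed around this, but absolute Spearman values
  depend on the schedule.
* Blocks are reconstructed independently per scale; inter-block contacts
  inform only the coarser scales.
* $\rho$ (genomic size) has a sharp meaning only at the finest scale; at
  coarser scales the packing terms are therefore disabled.
* The block decomposition is a greedy density scan, not a calibrated TAD
  caller; boundary placement on noisy matrices inherits its limitations.
* Serialized configuration tables do not carry payloads (finer-scale
  sub-chains); they are an end-product format.
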