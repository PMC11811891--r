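---
title: "Mapping tethered cryo-EM particle populations by pair distances"
author: "tetherlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tethered cryo-EM particle populations by pair distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherlink)
```

## The problem

Some multi-subunit assemblies are built from two stable bodies joined by a
long, intrinsically flexible polypeptide linker. General transcription factor
IIIC (TFIIIC) is the motivating case: its τB module binds the B-box promoter
motif of a tRNA gene with high affinity while the τA module must reach the
A-box, and the two are connected through a linker of roughly 550 residues of
the largest subunit. In single-particle cryo-EM such an assembly does not
average as one rigid particle; instead the two bodies are picked and refined
as two separate particle populations from the *same* micrographs.

The linkage is nevertheless recoverable from geometry alone. If a τA particle
and a τB particle in one micrograph are two ends of the same molecule, their
projected separation follows the statistics of the tether; if they are
unrelated molecules, their separation follows the statistics of random
placement. `tetherlink` implements the coordinate-level analysis that makes
this comparison: per-micrograph pairing of the two populations, a pooled
pair-distance histogram, and a randomized-coordinate null.

## Refined coordinates

Input is a pair of refinement particle tables (RELION-style STAR files),
one per population, sharing micrograph identifiers. The refined physical
position of a particle is

```
x_A = x_px * pixelSize - originX_A
```

with picked coordinates in pixels and origin shifts in Angstrom, the modern
RELION convention (`OriginX/YAngst`); legacy pixel-unit origin columns are
converted by multiplying with the pixel size. Whether origin shifts were
stored in Angstrom or pixels is a property of the upstream software version,
so both are readable and the Angstrom form is the default. The pixel size is
taken from the optics block when present; a conflicting explicit value is an
error rather than a silent preference. Micrograph identity is the verbatim
name string (a `basenameOnly` flag strips directories for tables refined
from different working directories). The y axis is never flipped: distances
are invariant to axis orientation.

## Greedy delete-minimum pairing

Within one micrograph, with `N_B` τB and `N_A` τA particles, all pairwise
Euclidean distances form an `N_B x N_A` matrix. Pairs are assigned by the
successive-minimum rule: take the globally smallest entry, record the pair,
delete its row and column, repeat until rows or columns run out. Every
particle is used at most once, `min(N_B, N_A)` pairs are produced, and the
recorded distances are nondecreasing in selection order (deleting a row and
column can never reveal a smaller minimum).

This greedy rule is deliberately *not* the optimal bipartite assignment: on
the matrix `[[1, 2], [5, 8]]` it selects 1 and 8 although the assignment
{2, 5} has the smaller total. The greedy rule mirrors the physical intuition
"the closest co-occurring pair is most likely the same molecule" and is the
procedure this analysis is defined by; `greedyPair()` therefore implements
the literal delete-minimum loop, and the test suite pins it against an
independent brute-force simulation of that loop on hundreds of random
matrices. Exact distance ties are broken toward the smallest row index, then
the smallest column index — real-valued ties have measure zero, but
synthetic fixtures hit them, and a documented deterministic rule keeps runs
reproducible.

Micrographs are processed independently and the pair distances pooled.
Micrographs present in only one table contribute nothing and are reported as
skipped; two tables with no shared micrograph give an empty result with a
warning, not an error.

## The randomized null

The same per-micrograph particle *counts* are kept but every coordinate is
replaced by a uniform draw on the field `[0, W) x [0, H)`, and the identical
pairing is run. Distances from tethered molecules vanish under this
randomization while distances from incidental proximity are reproduced, so
the observed histogram minus the null histogram isolates the tether signal.

Choices the null requires:

* **Field extent.** The physical micrograph dimensions are the natural
  extents and should be supplied when known. When omitted, each micrograph's
  extent defaults to its maximum observed coordinate per axis, with a
  warning — data-derived extents bias the null slightly inward.
* **Replicates.** The null is stochastic; `nullPairingDistances()` draws a
  configurable number of independent replicates (default 10). Replicate
  counts are pooled by per-bin *mean*, not concatenation, so the excess
  stays on the observed count scale and its total equals
  `n_obs - mean(n_null)` exactly.

`compareToNull()` reports the per-bin excess, the bin center of the maximal
excess, and the two-sample Kolmogorov–Smirnov statistic between the raw
samples. `ksCriticalValue()` supplies the large-sample rejection threshold;
note that pooled greedy distances are not strictly i.i.d. (selection within
a micrograph orders them), which in practice makes the KS comparison
conservative — the calibration test measures the realized rejection rate
under the null at α = 0.01 and finds it well below nominal.

## Histogram readout and its resolution limit

The readout is a fixed-width histogram (default 20 Å bins, half-open
`[kw, (k+1)w)`, last bin closed) and its mode — the plotted peak of the
distance distribution. Ties resolve to the smallest center, and a bootstrap
percentile interval (`bootstrapModeCI()`) quantifies the peak's sampling
uncertainty. A kernel-density alternative (`kdeModeEstimate()`) is offered
as a smoothness check.

One property of this estimator deserves emphasis. The projected separation
of a Gaussian tether is Rayleigh distributed, and a Rayleigh density is
*flat* near its mode: with scale σ = 200 Å and 20 Å bins, the bins flanking
the two central ones hold only about 2% less probability mass. The argmax
bin is therefore highly noise-sensitive — at a few thousand pooled pairs the
maximal bin lands one bin away from σ roughly half the time, and the excess
peak should always be read together with its bootstrap interval rather than
as a point estimate. This is a resolution limit of the binned-mode readout
itself, not of the pairing.

## The synthetic scene generator

`simulateScene()` stands in for real refinement tables and provides ground
truth. Per micrograph it places pair anchors uniformly in the field; each
pair emits a τB particle at the anchor and a τA particle displaced by a 3D
isotropic Gaussian (per-axis sd σ) projected to the image plane, so the true
planar separation is Rayleigh(σ) with mode σ. Displacements leaving the
field are re-drawn (truncation, not clipping; the bias is negligible for
σ much smaller than the field). Each emitted particle survives with its
species' detection probability, and unlinked "free" particles of both
species are added uniformly. The truth ledger records every pair whose two
particles were both retained, with the exact sampled separation.

Defaults are the study conditions of the analysis the package is built
around: 100 micrographs, 20 tethered pairs per micrograph at σ = 200 Å, 10
free particles of each species per micrograph, 90% detection, 0.822 Å/px.
The default field is 11210 × 7965 Å. That extent is chosen to match
*particle density*, not detector size: a refined dataset of this kind holds
only a handful of useful particles per physical K3 micrograph
(4735 × 3364 Å), about 3 × 10⁻⁷ particles/Å², and the pairing readout is
informative precisely in that sparse regime, where the tether length is
well below the typical nearest random neighbor. At ~28 particles per
species per synthetic micrograph, matching that density requires the larger
field (the K3 aspect ratio is kept). Simulations are reproducible from one
master seed via per-micrograph substreams, so micrograph `k` is identical
no matter how many micrographs are generated.

What the generator does *not* emulate: images (no CTF, noise or picking
errors beyond the Bernoulli detection model), particle orientation, body
size (separations are center-to-center, as picked coordinates are), and any
physical linker elasticity — σ is a free scale parameter and no claim maps
residue count to Angstrom. Passing recovery tests therefore show the
*coordinate analysis* is correct, not that a particular biological linker
must produce a particular peak.

## Binding curve fit

Filter-binding data (retained signal vs protein concentration) are fit to
the hyperbolic single-site isotherm — the Hill equation with coefficient
fixed at 1:

```
signal = plateau * c / (Kd + c)
```

by Levenberg–Marquardt least squares (`minpack.lm`). The plateau is a fitted
parameter and the normalization divides by it; normalizing by the maximal
observed count instead would propagate the noise of a single top point into
every fraction. Bound fractions are reported clipped to [0, 1] (with noise,
`counts/plateau` can slightly exceed 1; the unclipped value is recoverable
from the stored plateau). Inputs must span at least a decade with ≥ 4
points; data with no rising trend return a diagnosed failure object instead
of throwing. Concentrations are fixed to nM in the data model; the TSV
reader converts µM with an explicit unit tag only.

## Duplex molecular weight

`duplexMW()` sums anhydrous nucleoside-5′-monophosphate residue masses
(A 313.21, C 289.18, G 329.21, T 304.20 Da) over both strands of an
in-silico annealed duplex, with no end-group correction. This is one member
of a family of conventions; `fiveprimeOH` (−61.96 Da per strand) and the
650 Da/bp rule of thumb are available behind flags and clearly non-default.
For the 98-bp tRNA gene duplex shipped in `inst/extdata` the default
convention gives 60.55 kDa, i.e. 61 kDa at integer rounding — the mass used
to identify the free-DNA species in mass-photometry-style measurements.
IUPAC ambiguity codes are rejected with the offending position named.

## Conservation scoring

For protein alignments the per-column score is entropic over a reduced
alphabet: residues are mapped onto seven physicochemical classes (default
partition {AVLIMC}, {FWYH}, {STNQ}, {KR}, {DE}, {G}, {P} — this package's
own convention, fully overridable; no byte-compatibility with any external
scorer is claimed) and the score is `1 − H/ln 7` with `H` the natural-log
Shannon entropy of the class frequencies. The normalization makes an
invariant column exactly 1 and a class-uniform column exactly 0. Gaps are
excluded from the frequencies; an all-gap column scores `NA` and is never
framed; columns over 50% gapped are best flagged low-confidence
(`gapFraction()`). Framing of "highly conserved" positions uses a strict
`> 0.9` threshold. For DNA alignments the per-column information content is
`2 − H₂` bits (no small-sample correction), the height basis of sequence
logos. Alignment construction itself is out of scope — the module consumes
alignments.

## Problem sizes and numerical choices in the test suite

The test suite regenerates every fixture in code. The pairing oracle runs
100 random matrices up to 6×6 against a literal brute-force delete-min
simulation; invariants run over 1000 random micrograph scenes; the
end-to-end recovery check runs 10 seeded scenes at the default study
conditions with 10 null replicates each; the null calibration runs 100
seeded tether-free scenes; Kd recovery uses 50 noisy curves (2%
multiplicative noise) on a 0.1 nM–1 µM log grid. Tolerances are stated in
the tests themselves: exact equality for closed forms, 1e-6 Å for STAR
round trips, 1e-6 relative for noiseless fit recovery.

## Known limitations

* The greedy rule slightly *shortens* the recovered tether distribution at
  higher particle densities: a genuine partner far out on the Rayleigh tail
  can lose its mate to a nearer random particle. The effect shrinks with
  sparsity and is visible in the generator's ground truth.
* The binned-argmax peak has the resolution limit described above; report
  it with its bootstrap interval.
* The null preserves particle counts but not any spatial clustering of
  picks (ice gradients, carbon edges); a structured background that
  co-clusters both species inflates short-distance excess for reasons
  unrelated to tethering.
* 2D projected distances underestimate 3D separations; no deprojection is
  attempted.
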