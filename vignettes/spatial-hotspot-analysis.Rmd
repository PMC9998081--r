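---
title: "Spatial hotspot analysis of protein structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial hotspot analysis of protein structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldspot)
```

## The problem

A protein's residues live in 3D: positions far apart in sequence can be
close in space, and functional pressure (binding partners, immune
selection, disease mutations) often acts on spatial neighbourhoods rather
than sequence windows. Given a per-residue feature — binary flags such as
"site under positive selection", or continuous scores — `foldspot` tests
*where* the feature is spatially concentrated, segments those regions, and
exports everything for downstream modelling or visualization.

The package treats the residue as the unit of analysis. Every operation
works in a single coordinate system: the 0-based linear residue index of the
parsed structure. Author numbering and insertion codes are carried as
metadata (and used when writing viewer attribute files) but never drive the
statistics, so user-supplied feature vectors and index lists are interpreted
exactly as given.

## Spatial weights

All local statistics are defined relative to a neighbourhood structure, an
$n \times n$ nonnegative matrix $W$ built by `build_weights()` from CA
coordinates:

* **binary radius** (default): $w_{ij} = 1$ iff $0 < d_{ij} \le r$. Default
  $r = 8$ Å — a conventional CA-CA contact radius: it spans roughly two
  helical turns along a chain and captures side-chain-mediated contacts
  without bleeding across secondary-structure elements.
* **k-nearest neighbours**: possibly asymmetric; distance ties are broken by
  the lower residue index so results are deterministic.
* **distance decay**: $w_{ij} = e^{-d_{ij}/\lambda}$, a continuous
  neighbourhood for users who prefer not to pick a hard radius.

Self-inclusion and row standardization are orthogonal switches. The G\*
variant of the Getis-Ord statistic corresponds to self-inclusive, raw
weights; local Moran's I conventionally uses row-standardized weights
without self. `find_hotspots()` applies exactly those per-method defaults
unless overridden. A residue with no neighbour inside the band yields a
zero weight row and a warning rather than an error: isolated residues are
legitimate in sparse selections, and their statistic is well-defined (zero
numerator, handled below).

## Local statistics

**Getis-Ord.** For residue $i$,

$$z_i = \frac{\sum_j w_{ij} x_j - \bar{x} \sum_j w_{ij}}
{s\sqrt{\big[m \sum_j w_{ij}^2 - (\sum_j w_{ij})^2\big]/(m-1)}}$$

with $\bar{x}$ and $s$ the mean and *population* standard deviation of $x$,
and $m = n$ for the self-inclusive G\* variant. The plain G variant excludes
$i$ from the sums and from $\bar{x}, s$ for that residue ($m = n - 1$).
Positive $z$ means the residue sits in a high-valued neighbourhood.

**Local Moran.** The Anselin-style decomposition
$I_i = \frac{x_i - \bar{x}}{m_2} \sum_j w_{ij}(x_j - \bar{x})$ with
$m_2 = \sum_k (x_k-\bar{x})^2 / n$ and the self-weight forced to zero.
Note the interpretation difference: positive $I_i$ means *similarity* with
the neighbourhood — both high-high and low-low coherence — whereas positive
$z_i$ specifically means high values. With sparse binary features, Moran's
"greater" flag can therefore include residues in coherently empty regions;
the Getis-Ord default is the better hotspot detector for that common case,
which is why it is the default.

Both statistics satisfy exact analytic identities that the test suite
asserts: $z \equiv 0$ on complete self-inclusive weights, and
$\sum_i I_i = S_0 I_{\mathrm{global}}$ with $S_0 = \sum_{ij} w_{ij}$.

## Inference

Significance comes from **conditional permutation**: for residue $i$, $x_i$
is held fixed while the remaining $n-1$ values are permuted over the
remaining positions, and the statistic is recomputed per draw. Because the
permuted vector is the same multiset as $x$, the global moments are
unchanged, so only the weighted neighbourhood sum needs recomputation — the
implementation exploits this for speed but is tested against a naive
re-evaluation and, on 5-residue fixtures, against exhaustive enumeration of
all $4!$ conditional permutations.

P-values use the $+1/+1$ correction,
$p_i = (1 + \#\{\text{perm} \ge \text{obs}\}) / (1 + n_{\mathrm{perm}})$, so
$p_i \in [1/(n_{\mathrm{perm}}+1),\, 1]$ and a permutation p-value is never
zero. Ties count as exceedances, which keeps the p-values valid (if
conservative) for heavily tied binary features. Defaults: 999 permutations,
seed 42, one-sided "greater" — hotspot analysis asks for high-value
clustering; a two-sided mode is available. The default permutation count
makes the granularity $1/1000$, fine enough to clear an FDR threshold of
0.05 after correction at realistic protein sizes; users scanning thousands
of proteins may want 9999.

Multiple testing is controlled by **Benjamini-Hochberg** (`bh_fdr()`, a thin
wrapper over the standard step-up adjustment, cross-checked in the tests
against an independent hand implementation). The `hot` flag requires both
$q_i \le$ FDR and a positive statistic, so significant cold-spots are
visible in the output but not flagged.

Degenerate inputs are hard errors by design: a constant feature has no
spatial structure to test, and returning NaN statistics would silently
poison the FDR step downstream.

## Clustering back-ends

`cluster()` groups residues *purely by CA coordinates* (features only enter
through the optional hotspot selection), with a common label contract:
noise/unselected = −1, clusters numbered 0..K−1 by decreasing size, ties by
lowest member index.

**Density clustering (default)** follows the HDBSCAN construction: core
distances at `min_samples = min_cluster_size`, mutual-reachability
distances, a single-linkage hierarchy, condensation by minimum cluster size,
and excess-of-mass cluster extraction. The root of the condensed tree is not
selectable by default (`allow_single_cluster = FALSE`), the standard
convention — the root always contains everything, so allowing it would
collapse all structure; the flip side, also standard, is that a selection
with no genuine density split (e.g. six contiguous hotspot residues) comes
back as all noise rather than one forced cluster. `min_cluster_size`
defaults to 5.

**Markov clustering** runs on a binary contact graph (edges within
`mcl_radius`, default 8 Å): add unit self-loops, column-normalize, then
iterate expansion (matrix power 2), inflation (elementwise power, default
2.0), renormalization, and pruning of entries below $10^{-6}$, until the
largest entry change drops below $10^{-6}$ or 100 iterations (canonical MCL
parameters). Clusters are connected attractor sets; a node attracted to
several attractors joins the first by index. Non-convergence is reported via
`params$converged`, not an error.

On clearly separated geometry the two back-ends agree (asserted on two-blob
fixtures); they differ in philosophy — density clustering has an explicit
noise notion, MCL partitions every connected node — which is why both are
exposed behind one interface.

## Structure model and geometry

The PDB reader accepts paths or in-memory text and applies fixed policies:
first `MODEL` only (predicted structures ship one; NMR ensembles are out of
scope), first-seen altloc conformer, HETATM/waters/hydrogens excluded from
the residue sequence (the spatial statistics operate on amino-acid
residues), malformed fixed-width numeric fields reported with their line
number. A residue without a CA atom is an error in `ca_coords()` unless the
`first_atom` fallback is explicitly requested — a silent fallback would
corrupt distance statistics. mmCIF is not supported in this version.

Geometry helpers (`distance_matrix` with CA or minimum-heavy-atom modes,
`distance_to_chain`, `interface_residues`) are brute-force-checked in the
tests against all-atom-pair scans. pLDDT values outside [0, 100] in
AlphaFold input warn and are kept, flagged on the object: real-world files
contain them, and silently clamping would hide the anomaly.

## Scenes and export

The visualization layer deliberately stops at a *declarative scene
document*: JSON (`scene_version: 1`) with the embedded PDB text, the panel
grid, and each layer resolved to concrete atom serials and per-residue hex
colors. Rendering pixels is a viewer concern; a deterministic document is a
testable one (two renders of the same scene are byte-identical). Palettes
resolve through a small built-in table (`binary`, `greys`, `viridis`,
`rdbu`, `Set2`, `Set2_r`); continuous tracks are min-max normalized and
interpolated linearly through the palette's ordered colors, so a binary
track maps to exactly the two endpoints. The palette names follow common
plotting conventions but the hex values are this package's own documented
table. `write_attributes()` emits ChimeraX-style `defattr` text addressed
by chain, author number and insertion code, with values at full precision.

## Synthetic fixtures: what they do and do not show

All tests and the acceptance script run on generated structures:

* `make_helix()` — an ideal screw (rise 1.5 Å, twist 100°, radius 2.3 Å,
  α-helix-like), the substrate for the statistical calibration;
* `make_two_blob()` — two Gaussian clouds (sd 2 Å) at a chosen separation,
  the canonical two-cluster geometry;
* `make_two_chain()` — parallel CA+CB strands for complex/interface tests;
* `plant_feature()` — a binary feature painted within a radius of a centre
  residue, emulating a spatially clustered signal.

These fixtures have exact, known structure, which is what makes the
statistical claims testable: FDR control is measured over 50 null draws of
a random binary feature on a 100-residue helix (999 permutations each), and
recovery over a planted 10-residue patch on a 60-residue helix — problem
sizes chosen to keep the full calibration suite around a minute on one
core while leaving the Monte-Carlo error well inside the asserted margins.
They are *not* realistic proteins: no side-chain packing, no density
variation along the chain, no missing residues, no correlated features.
Passing tests demonstrate the statistics, inference and clustering are
implemented correctly — not that an 8 Å radius or FDR 0.05 is optimal for
any particular real protein family.

## Numerical choices

* $0/0$ in the Getis-Ord ratio (complete self-inclusive weights make both
  the numerator and the variance term vanish) is defined as $z = 0$; a
  nonzero numerator over a zero denominator is $\pm\infty$.
* Permutation draws are generated per residue from a single seeded stream;
  results are exactly reproducible under a fixed seed, and the caller's RNG
  state is restored afterwards.
* knn ties, cluster renumbering ties, and multi-attractor MCL assignment
  all break toward the lower index: every output is deterministic.
* PDB coordinates are written with 3 decimals (the format's precision);
  round-trip identity is asserted to that precision.

## Known limitations

* PDB input only; no structure alignment, domain/binding-site prediction,
  protonation or topology perception.
* Hotspot inference assumes exchangeability of the feature under the null;
  features with strong sequence-autocorrelation (e.g. smoothed scores)
  violate it and will look "significant" — permute at the level at which
  your feature is exchangeable.
* The density back-end inherits HDBSCAN's behaviour on tiny or split-free
  selections (all noise), which is informative but can surprise users
  expecting k-means-style forced partitions.
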