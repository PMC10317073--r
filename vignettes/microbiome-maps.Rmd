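---
title: "Microbiome maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(micromaps)
library(ggplot2)
```

## The problem

A metagenomic abundance profile assigns a relative abundance to every
genome of a reference collection — tens of thousands of strains for
shotgun (mWGS) data, thousands of species for 16S data.  One-dimensional
displays (bar charts, line plots) collapse under that many taxa: dominant
taxa crowd out everything else, and comparing two samples taxon by taxon
is hopeless.

`micromaps` instead turns each profile into a square image — a
*microbiome map*.  The taxa are arranged along a Hilbert space-filling
curve, so each image cell is one taxon and its brightness is that taxon's
relative abundance in one sample.  Because the Hilbert curve keeps
1D-adjacent items 2D-adjacent, taxa that are neighbors in the chosen
linear ordering form connected regions — *microbial neighborhoods* — and
a sample's character can be read off the image as clusters of bright
cells ("hotspots") inside a neighborhood.

## The Hilbert grid

A level-$k$ curve visits all $4^k$ cells of a $2^k \times 2^k$ grid so
that consecutive visits are always edge-adjacent.  We fix the coordinate
convention once: $x$ is the column, $y$ the row, origin at the top-left
of the rendered image, and the level-1 curve visits
$(0,0) \to (0,1) \to (1,1) \to (1,0)$.  Higher levels follow by the
standard recursive quadrant construction; the implementation uses the
equivalent iterative bitwise transforms (cheap at any level) and the test
suite checks it cell-by-cell against a direct recursive-subdivision
enumerator.  The published figures of Hilbert-curve tools rarely pin down
their orientation, and it cannot be recovered from coarse images, so we
declare ours rather than infer it; it is recorded in every export's
metadata.

```{r path}
hilbert_path(1)
```

The grid level is the minimal $k$ with $4^k \ge n$ taxa
(`hilbert_level()`).  When $4^k > n$, adjacent curve segments are merged
so the number of map regions equals the number of taxa: each taxon
receives $\lfloor 4^k/n \rfloor$ or $\lceil 4^k/n \rceil$ consecutive
curve indices.  The remainder cells are given to the earliest-ordered
taxa — a deterministic rule that keeps each clade's start aligned with
its curve start; which taxa receive the merged cells is otherwise
arbitrary, and this choice is declared, not inherited from any prior
tool.

## Orderings

A reference collection has no natural linear order, so two orderings are
offered.

**Taxonomic ordering.**  The taxonomy tree is linearized depth-first;
every clade then occupies one contiguous run of the curve, hence one
connected map region.  Trees have no left/right either, so a child-order
rule is needed: by default children sort by descending leaf count (ties
lexicographically).  Large clades thus occupy coherent blocks, and the
order is a pure function of tree content — shuffling input rows cannot
change the map.  A `lexicographic` alternative is available.  The
ordering used by the original databases (e.g. a pan-taxonomic database's
internal order) is not reproducible offline, which is why a declared
deterministic rule is used instead.

**Labeled (condition) ordering.**  Given a sample-by-taxon matrix, a
sample-to-condition labeling, and a user-declared condition order
$C_1, \dots, C_c$, each taxon is *anchored* to the condition in which its
arithmetic mean relative abundance is highest, provided that mean clears
the noise threshold $\tau$.  Ties go to the earliest condition in the
declared order; taxa below $\tau$ everywhere form a trailing
*unassigned* block.  Within each block, taxa follow the taxonomic order,
so condition neighborhoods keep internal taxonomic structure.  The means
are taken over row-normalized relative abundances (not re-normalized
within condition); this is stated here because either reading is
defensible, and the package fixes one.

## Parameters that matter

* **`tau` (noise threshold)** — minimal relative abundance at which a
  taxon counts as present, both for anchoring and for coloring.  No
  universal rule exists; the default is data-driven: for raw counts,
  $\tau = 1/\mathrm{median}(\text{sample depth})$ (one-read resolution);
  for matrices already supplied as proportions, $\tau = 10^{-5}$.
  Always user-overridable, always recorded in output metadata.
* **`level`** — auto-selected minimal level by default; can be forced
  higher to leave headroom.
* **`reserve` (gap policy)** — off by default.  When on, each top-level
  group is placed in an aligned $4^g$ block ($g$ minimal with
  $4^g \ge$ group size), one cell per taxon, the rest left blank, so
  every group starts at the boundary of an aligned $2^g \times 2^g$
  subsquare and new genomes can be added later without moving existing
  ones.
* **`scale`** — `linear` max-normalizes intensities over the map;
  `log` stretches $[\tau, \max]$ on a log10 axis, which keeps
  low-abundance taxa visible under the heavily right-skewed abundance
  distributions typical of microbiomes.  Differential maps use a signed
  diverging scale normalized by the largest absolute difference.

Degenerate inputs are handled explicitly: all-zero samples are flagged
and excluded from ordering computations (their maps render as all-zero);
gap cells carry a distinct class (and a neutral tone) so "absent" and
"not a taxon" never look alike; records missing an intermediate rank get
a synthetic `<parent>__unranked` placeholder so clade contiguity
survives.

## A worked example

The classic toy collection — 2 genera, each with 2 species of 4
strains — fills a level-2 grid exactly:

```{r toy}
records <- simulate_taxonomy(2, 2, 4)
ord <- linearize(build_taxonomy(records))
lay <- build_layout(ord)
glance(lay)
neighborhoods(lay, "genus")$regions
```

```{r toyplot, fig.height = 4}
sim <- simulate_profiles(records, seed = 1)
ab <- normalize_abundance(sim$abundance)
m <- intensity_map(ab[1, ], lay)
autoplot(overlay_boundaries(m, lay, "genus"))
```

## What the generator emulates — and what it does not

`simulate_profiles()` draws abundances from a log-normal background
(mimicking the right-skew of real communities) and plants disjoint
per-condition signature taxa whose expected abundance is `effect_size`
times background.  Defaults are three conditions with three samples each
(a typical small-cohort group size), `effect_size = 10`, `sdlog = 1`,
and one signature taxon per ten collection taxa.  The generator is
seeded and bit-reproducible.

It deliberately omits ecological covariance between taxa, compositional
coupling beyond row normalization, sequencing-depth variation, and
zero-inflation.  Tests that pass on these fixtures therefore demonstrate
that the ordering, layout and rendering machinery is correct — taxa
planted in a condition are anchored to it, clades stay contiguous,
intensities scale as declared — not that condition neighborhoods will
separate as cleanly on real cohorts, where effect sizes are smaller and
noise is structured.

Scales used in the test suite and acceptance script were chosen to match
the collections the method targets: structural checks run at 44,048 and
5,127 taxa (real mWGS/16S collection sizes; both finish in seconds
because the layout arithmetic is vectorized), while statistical checks
(signature recovery) run on a 64-taxon collection, large enough for 18
planted signatures.

## Numerical and design choices

* Curve arithmetic is exact integer arithmetic on doubles (exact through
  level 26); no floating-point geometry is involved.
* Ties inside one condition block (equal means) are resolved by the
  taxonomic order, never by input file order.
* Samples labeled with a condition absent from the declared order are an
  error, not silently appended — a declared order is a contract.
* Layout export (`write_layout()`) writes the full interval table plus
  level/orientation/ordering headers, so the identical geometry can be
  reused across studies; `read_layout()` restores it.  All numeric
  output is written at full precision.
* PNG export rasterizes the cell grid directly (no graphics device), so
  identical inputs give byte-identical files; `autoplot()` +
  `ggplot2::ggsave()` is the vector route.  Animations are exported as
  numbered PNG frame sequences for any standard encoder.
* The per-map maximum defines intensity 1 (the brightest cell is always
  saturated); animation frames instead share the global series maximum
  so brightness is comparable across frames.

## Known limitations

* Adding genomes to a collection re-flows the layout unless gaps were
  reserved; adding samples changes a labeled ordering whenever it shifts
  a condition mean.  Both are inherent to precomputed orders; the layout
  TSV is the mitigation.
* The labeled ordering uses the arithmetic mean as its anchoring metric;
  a hook exists for alternatives (e.g. median) but only the mean is
  exercised by the test suite.
* Only the Hilbert curve is implemented.  Curves that partition into
  more than four regions per level (e.g. Peano) trade locality for
  harder-to-read images at high levels and are out of scope.
* The colormaps are package defaults, declared in the render options,
  and not claimed to match any prior tool's palette.
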