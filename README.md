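# micromaps

Microbiome maps: Hilbert-curve visualization of metagenomic abundance
profiles.

Metagenomic profiling reduces a sample to a vector of relative
abundances over a reference collection of microbial genomes — often tens
of thousands of strains (shotgun/mWGS) or thousands of species (16S).
`micromaps` renders such a profile as a square image in which every cell
is one reference genome, placed along a space-filling **Hilbert curve**,
and the cell's intensity is that genome's relative abundance.  Because
the curve maps 1D-adjacent taxa to 2D-adjacent cells, any contiguous
block of the taxon ordering becomes a connected image region — a
*microbial neighborhood* — and dominant clades or conditions show up as
clusters of bright cells.

The package is for microbiome researchers who need to eyeball (and batch
featurize) profiles at reference-collection scale, where bar charts and
line plots stop working.

## The method

For a collection of *n* taxa the package picks the minimal curve level
*k* with 4^k ≥ *n* (a 2^k × 2^k grid) and, when the grid is larger than
the collection, merges adjacent curve segments so the number of map
regions equals *n*: each taxon gets ⌊4^k/n⌋ or ⌈4^k/n⌉ consecutive curve
indices.  Taxa are ordered one of two ways:

* **Taxonomic ordering** — deterministic depth-first linearization of
  the taxonomy tree (children sorted by descending clade size, ties
  lexicographic), making every clade a contiguous run and hence a
  connected neighborhood;
* **Labeled ordering** — given an *m* × *n* sample matrix `M`
  (`M[i, j]` = relative abundance of taxon *j* in sample *i*), a
  sample-to-condition labeling and a declared condition order
  C₁, …, C_c, each taxon anchors to the condition with its highest mean
  relative abundance (ties → earliest condition; all means < τ →
  trailing *unassigned* block), and follows the taxonomic order within
  its block.

Rendered maps can be single-sample, colorless (geometry only), average,
aggregate, differential (signed, diverging scale), or animation frames
with a shared intensity scale, each with optional neighborhood-boundary
and curve-path overlays.

## Worked example

```r
library(micromaps)

records <- simulate_taxonomy(2, 2, 4)       # 2 genera, 4 species, 16 strains
ord     <- linearize(build_taxonomy(records))
lay     <- build_layout(ord)
glance(lay)
#> # A tibble: 1 × 10
#>   level  side n_cells_grid n_taxa n_assigned_cells n_gap_cells min_interval
#>   <int> <dbl>        <dbl>  <int>            <dbl>       <dbl>        <dbl>
#> 1     2     4           16     16               16           0            1
```

The 16 strains exactly fill the level-2 (4 × 4) grid, one cell each.
Each genus occupies one connected 8-cell region:

```r
neighborhoods(lay, "genus")$regions
#> # A tibble: 2 × 6
#>   label      run n_taxa n_cells anchor_x anchor_y
#>   <chr>    <int>  <int>   <int>    <int>    <int>
#> 1 Genus_01     1      8       8        1        1
#> 2 Genus_02     2      8       8        2        2
```

Simulate a labeled cohort, normalize, and render one sample:

```r
sim <- simulate_profiles(records, seed = 1)
ab  <- normalize_abundance(sim$abundance)
m   <- intensity_map(ab[1, ], lay)
glance(m)
#> # A tibble: 1 × 8
#>   kind   scale     tau level n_assigned n_zero n_gap max_value
#>   <chr>  <chr>   <dbl> <int>      <int>  <int> <int>     <dbl>
#> 1 single linear 0.0326     2          4     12     0     0.444
```

Four taxa clear the noise threshold τ (here 0.0326, one-read resolution
at the simulated depth); the most abundant reaches relative abundance
0.444 and renders at intensity 1.  Plot it, or export a byte-stable PNG:

```r
autoplot(overlay_boundaries(m, lay, "genus"))   # ggplot2; ggsave() for SVG/PDF
write_map_png(m, "map.png")                     # + sidecar map.png.json metadata
```

A batch run over files (also available via
`Rscript inst/cli/micromaps.R`):

```r
run_pipeline("abundance.tsv", "taxonomy.tsv", out = "maps/",
             order = "labeled", metadata = "metadata.tsv",
             conditions = c("control", "stage1", "stage2"))
```

writes one PNG per sample, the reusable `layout.tsv`, a run-metadata
JSON and a log of every decision value (level, τ, orientation,
child-order rule).

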