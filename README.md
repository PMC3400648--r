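# mldcyto

Automated cell identification, tracking, mitosis detection and lineage
reconstruction from nanoparticle **moving light displays** (MLDs).

## The problem

Cells loaded with endocytosed quantum dots carry 10–50 bright, photostable
point sources in intracellular vesicles, arranged around the nucleus. In
time-lapse fluorescence movies each cell therefore appears not as a dim
outline but as a sparse cluster of point lights — a moving light display.
This package turns such movies (multi-focal-plane TIFF stacks, one per
timepoint) into quantitative cell biology:

1. **Imaging** — focal planes are fused by the absolute-gradient rule
   (per block, the plane maximizing
   ∑ |I(x+1,y) − I(x,y)| + |I(x,y+1) − I(x,y)| wins), thresholded at
   θ = µ + σ (image mean plus standard deviation), and reduced to *binary
   elements*: local intensity maxima of the row and column profiles within a
   5 px window, one per QD-loaded vesicle.
2. **Clustering** — elements are partitioned into cells by seeded k-means
   (the per-cluster objective ∑ᵢ ∑_{b∈Cᵢ} ‖b − µᵢ‖², Lloyd iteration from
   the previous frame's centroids), with silhouette validation
   s = (b − a)/max(a, b), new seeds for elements > 30 µm from every
   centroid, removal of centroids with no element within 12.5 µm, and a
   silhouette-gated split test for over-dispersed clusters.
3. **Tracking** — centroids are linked frame to frame by ascending-distance
   nearest-neighbour assignment within one cell diameter (10 µm); a parent
   with two children is a division candidate.
4. **Mitosis** — each track's *mitotic curve* (mean element separation vs
   time) is scanned for the contraction–expansion signature: the cloud
   condenses as the cell rounds up, reaches a minimum, and the cluster is
   split into two daughters when the separation again exceeds the stable
   pre-contraction baseline.
5. **Lineage** — confirmed divisions assemble binary lineage trees with
   motility vectors (net displacement per hour between mitotic events) and
   population statistics, including the two-point doubling time
   T = Δt / log₂(N₁/N₀).

A fully ground-truthed simulator (`simulateMovie()`, `frameGenerator()`,
`renderFixture()`) generates movies with known cell positions, vesicle
assignments and division times, so every stage is testable without external
data.

## Worked example

```r
library(mldcyto)

# a 4-hour synthetic movie: 3 cells, 2 focal planes, bright labelling
cfg <- simConfig(fieldUm = c(96, 96), pixelSizeUm = 0.5, nFrames = 48L,
                 initialCells = 3L, nPlanes = 2L, snr = 4,
                 vesiclesPerCell = c(20L, 35L), domainMarginUm = 0,
                 minInitialSeparationUm = 30, rngSeed = 4L)
gen <- frameGenerator(cfg)
seeds <- with(subset(gen$truth@positions, frame == 0 & in_field),
              data.frame(id = cell_id, x = x_px, y = y_px))
res <- runPipeline(gen, pipelineConfig(pixelSizeUm = 0.5), seeds = seeds)

res$states[[1]]
#> ClusterState: frame 0 - 3 centroids over 52 elements; mean silhouette 0.848
res$trackGraph
#> TrackGraph: 5 tracks over 48 frames; 2 child tracks from bifurcations
res$divisions
#>   parent_track daughter_a daughter_b frame_min frame_confirmed baseline_um
#> 1            2          4          5        43              47    6.353441
#>   minimum_um
#> 1          0
res$lineage
#> LineageTree: 5 cells, 3 progenitors, 1 divisions
cat(lineageNewick(res$lineage), sep = "\n")
#> c1:3.91667;
#> (c4:0,c5:0)c2:3.83333;
#> c3:3.91667;
doublingTime(41, 133, 40)   # the two-point estimator on reference counts
#> [1] 23.56087
```

Each simulated cell is recovered as one centroid of ~17 binary elements
(nearby vesicles merge under the 5 px peak window), tracked without identity
changes. One cell truly divides at frame 43: the pipeline places the
contraction minimum exactly there, confirms the division when the daughters'
separation re-crosses the mother's 6.4 µm baseline at frame 47, and the
lineage holds three progenitors, one of which has two daughters. The
doubling-time estimator applied to a population growing from 41 to 133 cells
over 40 h gives 23.6 h.

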