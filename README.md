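# CortexQuant

Single-cell image quantification of **cortical protein localization and
filopodia** in fluorescence micrographs of amoeboid cells.

Motile amoebae such as *Dictyostelium* recruit actin regulators and
filopodial myosins to a thin actin-rich layer under the plasma membrane —
the cell cortex — and extend thin, tip-bright protrusions (filopodia) from
it. Experiments that perturb cortical actin (depolymerizing drugs,
nucleator knockouts, autoinhibition mutants) are read out through a small
set of per-cell statistics, which this package computes reproducibly from
segmented cells:

- **Cortex:cytoplasm ratio** — mean intensity of a 0.8 µm band inside the
  cell boundary divided by the mean of the remaining cytoplasm (nucleus
  excluded):
  `R = ⟨I⟩_band / ⟨I⟩_cyto`. R ≈ 1 means no cortical enrichment; control
  cells expressing a cortically recruited protein typically show R ≈ 1.2
  (20% enrichment).
- **Cortical asymmetry (SD)** — the band is divided into angular bins
  about the centroid; the standard deviation of the per-bin mean
  intensities around the whole periphery. A band modulated as
  `M (1 + A cos(θ − θ₀))` has SD = `M·A/√2`; uniform localization gives
  SD ≈ 0, leading-edge polarization a high SD.
- **Filopodia per cell** — counted by a radial tip search: rays cast from
  the centroid, sampled from the boundary outward, with the outermost
  rooted intensity peak above `background mean + k·SD` per ray, clustered
  across adjacent rays.
- **Pixel-wise colocalization** — cytofluorogram Pearson r of two channels
  within the cell mask.
- **Linescan averaging** — intensity profiles normalized to [0, 1] and
  averaged across cells with a restricted cubic spline (natural cubic,
  5 knots), with pointwise SD and SEM bands.
- **Statistics** — ROUT-style robust outlier exclusion (FDR Q = 0.001),
  one-way ANOVA with Tukey or Dunnett post hoc comparisons, Student's t,
  per-experiment (replicate) means, and condition summary tables
  (percent of cells with ≥1 filopodium; mean count among positive cells).

Because the package is validated by **parameter recovery**, it ships a
synthetic micrograph generator (`SceneParams()`, `makeCellScene()`,
`makeTwoChannelScene()`, `makeField()`) that renders cells with known
enrichment, polarity, filopodium positions, channel correlation and
Poisson+Gaussian camera noise over a z-stack, together with full
ground-truth masks.

## Worked example

```r
library(CortexQuant)

sc    <- makeCellScene(SceneParams(enrichment = 1.2, nFilopodia = 3L, seed = 42))
img   <- maxProject(sc$stack)              # analysis runs on max projections
cells <- segmentCells(img)
part  <- partitionCortex(cells[[1]], bandWidthUm = 0.8)
part
#> CorticalPartition: band 857 px, cytoplasm 3350 px, nucleus 280 px (band 0.80 um)

cortexCytoRatio(img, part)
#> [1] 1.188
corticalAsymmetry(img, part, cells[[1]])$corticalSd
#> [1] 5.99
tips <- radialTipSearch(img, cells[[1]])
nrow(tips)
#> [1] 3
```

The cell was generated with 20% cortical enrichment and 3 filopodia; the
pipeline recovers a ratio of 1.19, a low asymmetry SD (the band is
unpolarized) and exactly 3 tips. Condition-level summaries follow the
usual conventions:

```r
summarizeFilopodia(c(0, 0, 1, 3, 4))
#> $percentWithFilopodia  60
#> $meanCountPositive     2.67   (± 0.882 SEM, over the 3 positive cells)
```

`runPipeline(config)` ties the stages together (simulate or read TIFFs →
project → segment → partition → metrics → tips → summaries → ANOVA) and
writes per-cell CSV, tip CSV, summary JSON, comparison CSV and a run
manifest; identical config + seed reproduces identical bytes. A thin CLI
wrapper is installed at `inst/scripts/pipeline.R`.

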