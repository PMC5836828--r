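# CometKit

Fully automated analysis of comet-assay (single-cell gel
electrophoresis) fluorescence micrographs in R.

The comet assay measures DNA damage cell by cell: fragmented DNA
migrates out of the nucleus during electrophoresis and forms a
comet-shaped fluorescent object whose bright compact **head** is the
residual nucleus and whose **tail** is the smear of migrated fragments.
High-throughput protocols produce images with tens of comets at
arbitrary positions, frequently overlapping and surrounded by debris.
CometKit detects every comet without assumptions on count or placement,
separates overlapping comets, measures each one, and classifies its
damage state — for assay labs and image-analysis methodologists who
need a scriptable, reproducible alternative to manual outlining.

## Method at its core

Working on the per-column integrated intensity profile of each comet
(intensity treated as mass):

* CPH = profile peak column; head radius *r* = distance to the first
  column below HT x peak (HT is the user-set head threshold);
* tail = columns from CPH + *r* to the last positive column;
* DNA = Σ<sub>x∈comet</sub> I(x),  TDNA = (1/DNA) Σ<sub>x∈tail</sub> I(x);
* extent moment = TDNA x tail length, Olive moment = TDNA x tail
  distance (CMT − CPH), moment of inertia =
  (1/DNA) Σ<sub>x∈tail</sub> I(x)(CPH − x)².

Detection uses **first-valley adaptive thresholding** (the first local
minimum of the smoothed gray-level histogram after the background peak —
far lower than Otsu's threshold, so faint apoptotic comets survive),
8-connectivity labeling, border/fragment filtering, and an overlap
corrector: Euclidean distance transform → Haar wavelet smoothing →
watershed from regional maxima → horizontal re-merging → Fourier
contour / area validity. Classification uses HOG features (900 on a
50x50 resize, 360 on the left half; 901/361 with the box ratio) with a
linear-SVM cascade, softmax regression, AdaBoost, or CART.

A seeded synthetic-scene generator with complete ground truth
(`composeScene()`) and region-/centroid-based evaluation metrics make
every stage testable without external data.

## Worked example

```r
library(CometKit)

sc  <- composeScene(nComets = 6, overlapRate = 0.2, nDebris = 3, seed = 11)
res <- runPipeline(sceneImage(sc), verbose = TRUE)
#> threshold          : 12.00 (valley)
#> candidates        : 7 object(s)
#> border-filtered   : 7 object(s)
#> fragment-merged   : 4 object(s)
#> overlap-corrected : 6 object(s)
#> characterized     : 6 object(s)
res
#> CometResult: 6 comet(s) on a 416 x 608 image
#>   stages: candidates=7 -> border-filtered=7 -> fragment-merged=4 ->
#>           overlap-corrected=6 -> characterized=6
#>   TDNA: mean 0.232, range [0.066, 0.398]
#>   classes: unclassified:6
```

Seven candidate components become six comets: two debris speckles are
merged into their nearest comets, and one touching pair is split by the
watershed stage. The records hold the per-comet measurements:

```r
round(cometRecords(res)[, c("id", "tdna", "tail_length",
                            "extent_moment", "olive_moment")], 3)
#>   id  tdna tail_length extent_moment olive_moment
#> 1  1 0.387         168        65.031       12.913
#> 2  2 0.094           8         0.754        0.836
#> 3  3 0.398          41        16.301        8.536
#> 4  4 0.066           6         0.395        0.614
#> 5  5 0.094           7         0.661        0.810
#> 6  6 0.355          40        14.193        8.002
```

Comets 1, 3 and 6 are heavily damaged (TDNA near 0.4, long tails and
large moments); the rest are near-intact cells whose small TDNA is the
head-fringe baseline of the half-maximum head boundary. Against the
scene's ground truth:

```r
rec <- cometRecords(res)
centroidMatch(cbind(rec$centroid_row, rec$centroid_col),
              sc@centroids, radius = 15)[c("precision", "recall", "f1")]
#> $precision [1] 1
#> $recall    [1] 1
#> $f1        [1] 1
heterogeneitySummary(rec$tdna)[c("mean", "sd")]
#> $mean [1] 0.2323...   $sd [1] 0.1634...
```

A thin command-line front end (run / batch / synth / evaluate) is
installed at `inst/scripts/cometpipe.R`.

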