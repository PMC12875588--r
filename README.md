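# peelnet

Image-based vintage and origin authentication of *Citri Reticulatae
Pericarpium* (CRP, dried citrus peel) for R. Premium aged peel commands
prices an order of magnitude above young peel, and adulterated product is
routinely passed off as premium; `peelnet` implements a consumer-grade
authentication pipeline that works from plain photographs, aimed at
quality inspection, pricing and authenticity checks where laboratory
spectroscopy is impractical.

The pipeline has three stages:

1. **Region localization.** A pluggable detector proposes boxes for the
   whole specimen, the exocarp (outer surface) and the albedo (inner
   pith). Each box is tightened by *grayscale corner-deviation
   refinement*: with global image mean `mu` and threshold `tau`, any box
   corner whose gray value deviates from `mu` by more than `tau` pulls
   its two coordinates inward by a step `s`, until all four corners
   agree. The threshold is half the specimen/background gray gap,
   `tau = |mu_CRP - mu_bg| / 2`, giving the operating value `tau = 20`
   at the calibrated gap of ~40 gray levels.
2. **Multi-stream classification.** Three bottleneck-residual branches
   (whole image, exocarp patch, albedo patch) with channel-level feature
   interaction at stage 2 — a shared random 10% of full-branch channels
   is injected into both local branches, then independent 5% sets are
   injected back — followed by per-branch 1x1 compression (2048 -> 512
   channels in the standard variant), global average pooling,
   concatenation into a 1536-dimensional fused vector, and a softmax
   head with per-branch auxiliary losses.
3. **Cross-device meta-learning.** MAML: inner loop
   `theta_i <- theta - alpha * grad L_support(theta)` (K = 5 steps,
   4-way 5-shot tasks), outer loop
   `theta <- theta - beta * grad sum_i L_query(theta_i)` with
   second-order gradients. Adaptation to a new capture device uses five
   labeled images per class.

A synthetic peel-image generator (elliptical specimens with textured
exocarp annulus and fibrous albedo core, four appearance classes, three
device-style photometric domains, exact ground-truth boxes) makes every
stage testable with no external data.

## Worked example

```r
library(peelnet)

## render one synthetic specimen and localize its regions
set.seed(42)
spec <- generatePeelImage(classProfiles()[["2800"]], size = 96)
round(spec$gap, 1)            # realized specimen/background gray gap
#> [1] 40

res <- localizeAndRefine(spec$image)
res[[1]]$box                  # refined whole-specimen box
#> BoundingBox (x1=20, y1=19) -- (x2=78, y2=78)  [59 x 60 px]
res[[1]]$converged
#> [1] TRUE

## threshold rule at the calibrated contrast
computeThreshold(185, 225)
#> [1] 20

## train the three-branch classifier on a small synthetic set
ds <- generateDataset(counts = c("190" = 25, "560" = 25,
                                 "2800" = 25, "3300" = 25),
                      size = 128, seed = 11,
                      devices = deviceProfiles()["deviceA"])
tr  <- prepareSamples(ds, "deviceA", "train", inputSize = 32)
va  <- prepareSamples(ds, "deviceA", "val",   inputSize = 32)
te  <- prepareSamples(ds, "deviceA", "test",  inputSize = 32)
m   <- multiStreamModel(inputSize = 32, seed = 11)
m   <- trainModel(m, tr, va, epochs = 20, batchSize = 8, lr = 2e-3,
                  seed = 11)
computeMetrics(predictClasses(m, te), te@labels)
#> MetricsReport: accuracy 1.0000 | macro recall 1.0000 | macro F1 1.0000
#> Confusion matrix (rows = truth):
#>       predicted
#> truth  190 560 2800 3300
#>   190    5   0    0    0
#>   560    0   5    0    0
#>   2800   0   0    5    0
#>   3300   0   0    0    5
```

`round(spec$gap, 1)` is the realized luma contrast between specimen and
background (the generator calibrates it to 40 +- 5); the refined box is
reported in 0-based inclusive pixel coordinates, and `converged = TRUE`
means all four corner deviations ended within `tau = 20`. The test-set
report shows the three-branch model solving this 20-image test split
exactly; its rows are true classes, its columns predictions.

For the cross-device protocol, `deviceShiftBenchmark(seed = 1)` trains
on the neutral device, meta-trains, and reports direct-transfer vs
5-shot-adapted accuracy on the two shifted devices.

A thin command-line wrapper ships in `inst/cli/peelnet.R`
(`generate`, `refine`, `localize`, `run` verbs).

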