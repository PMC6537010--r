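# lddscp

Dominant-direction texture descriptors for grayscale image classification.

`lddscp` implements the **local dominant directional symmetrical coding
pattern** (LDDSCP), a compact block-histogram texture descriptor in the
LBP/LDP family, together with the harness needed to evaluate it: baseline
descriptors (LBP, CS-LBP, LDP), leave-one-sample-out KNN classification,
noise-robustness sweeps, and synthetic oriented-texture generators so the
whole pipeline runs without any external image data. Its motivating use is
facial-expression texture classification, where class information lives in
the *orientation* of local texture deformations rather than in absolute
intensity.

## The coding scheme

The eight 3×3 Kirsch compass masks (weights +5/−3, zero sum; 0° = East,
counter-clockwise) are split into two symmetric groups, directions
{0°, 45°, 90°, 135°} and {180°, 225°, 270°, 315°}. At each pixel, the four
responses of group *j* are compared with their own mean:

    code_j = Σ_{i=0..3} S(M_ji − mean_j) · 2^i,   S(x) = 1 if x ≥ 0 else 0

A set bit marks a direction whose response dominates its group's average
strength. The all-zero and all-one codes carry no dominant-direction
information and are excluded, leaving 2⁴ − 2 = 14 informative values per
group — a 94.53 % per-block bin reduction relative to 256-bin LBP. The image
is partitioned into an 8×8 block grid, each block contributes a 14-bin
histogram per group, and the two histograms are **stacked** (summed
element-wise), giving an 8·8·14 = 896-dimensional feature for a 128×128
image. The codes are invariant under affine intensity maps `a·I + b`
(`a > 0`).

## Worked example

A 3×3 patch with a bright east column — an eastward intensity step:

```r
library(lddscp)
patch <- matrix(c(0, 0, 100,
                  0, 0, 100,
                  0, 0, 100), 3, byrow = TRUE)
sapply(directional_responses(patch)$responses, as.numeric)
#>    0   45   90  135  180  225  270  315
#> 1500  700 -100 -900 -900 -900 -100  700
codes <- lddscp_codes(patch)
code_to_binary(codes$code1)   # "0011": masks 0 and 45 degrees dominate
code_to_binary(codes$code2)   # "1100": masks 270 and 315 degrees
```

The group-1 mean response is 300, so only the 0° (1500) and 45° (700) bits
are set — the code reads the step's orientation directly.

End to end on a synthetic six-class oriented-texture set (60 images,
128×128), with a salt-and-pepper robustness sweep against basic LBP:

```r
ds <- make_dataset(seed = 0)                 # 6 classes x 10 samples
feats <- dataset_features(ds, "lddscp")      # 60 x 896 count matrix
loso_knn_evaluate(feats, k = 1)$accuracy
#> [1] 1

grid <- lapply(c(0, 0.1, 0.2), function(l) noise_spec("salt_pepper", l, seed = 11))
noise_sweep(ds, c("lddscp", "lbp"), grid)
#>    noise_kind level seed descriptor  accuracy
#> 1 salt_pepper   0.0   11     lddscp 1.0000000
#> 2 salt_pepper   0.0   11        lbp 0.9833333
#> 3 salt_pepper   0.1   11     lddscp 0.9833333
#> 4 salt_pepper   0.1   11        lbp 0.8500000
#> 5 salt_pepper   0.2   11     lddscp 0.8666667
#> 6 salt_pepper   0.2   11        lbp 0.6500000
```

Accuracy is the fraction of leave-one-sample-out folds whose nearest
neighbor has the correct class. Both descriptors degrade as corruption
density rises; the stacked dominant-direction feature degrades more slowly —
the robustness ordering the coding scheme is designed to deliver.

## Command line

A thin CLI over the same functions lives at `inst/cli/lddscp.R`
(after installation: `system.file("cli", "lddscp.R", package = "lddscp")`):

```sh
Rscript inst/cli/lddscp.R synth --out data/ --classes 6 --per-class 10 --seed 1
Rscript inst/cli/lddscp.R extract --data data/ --out features.tsv --descriptor lddscp
Rscript inst/cli/lddscp.R evaluate --features features.tsv --out report.tsv --k 1
Rscript inst/cli/lddscp.R noise-sweep --data data/ --out sweep.tsv --noise sp --levels 0,0.05,0.1,0.2
```

Datasets are directory trees (one subdirectory per class; PNG/PGM/TIFF);
feature files are self-describing tab-separated text.

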