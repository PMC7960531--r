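# ramanmargin

Image-guided Raman spectroscopic probe tracking and tumor margin
delineation, as a simulation-backed R package.

## The problem

During tumor resection a surgeon needs to know, point by point, whether
tissue at the probe tip is diseased — and to assemble those point
diagnoses into a resection boundary. A fiber-optic Raman probe provides
the per-point diagnosis; `ramanmargin` implements the surrounding system:
video tracking of the handheld probe via two colored fiducial markers,
real-time-style spectral classification, accumulation of spatially pinned
diagnoses into a lesion boundary with adjustable safety margins, and
quantitative evaluation against ground truth. A fluorescence-imaging
comparison arm (thresholded wide-field images of a PPIX-like fluorophore)
is included, and every input — spectra, probe videos, fluorescence
phantoms — can be generated synthetically with exact ground truth, so the
whole workflow runs on a desk.

It is aimed at researchers prototyping image-guided spectroscopic
diagnostics who need a tested, reproducible reference implementation of
the tracking, preprocessing, modelling and evaluation chain.

## The core methods

**Tracking.** Markers are segmented per frame in HSV space (circular hue
tolerance, saturation/value minima, 3×3 morphological cleanup, largest
connected component). With marker centroids `p` (proximal) and `d`
(distal), physical separation `s` and tip offset `o`:

    mm_per_px = s / ||d − p||
    tip       = d + (d − p) · o / s

Each frame is processed independently, so tracking recovers instantly
after occlusion.

**Spectroscopy.** Every spectrum is cropped to 600–1800 cm⁻¹, background-
subtracted with an asymmetric Whittaker penalized-least-squares baseline
(λ = 100 000), area-normalized, and Savitzky–Golay filtered (order 1,
frame 7). Classification is PLS-DA (NIPALS PLS2 on one-hot labels, mean-
centered features, 2 latent variables by default) with Venetian-blinds
cross-validation (fold of sample *i* is `(i − 1) mod k + 1`) and an
adjustable decision threshold on the positive class.

**Delineation.** Positive diagnoses are connected as a convex hull and
buffered outward by `margin_mm + tip_diameter_mm / 2`, at the median
per-acquisition scale. Accuracy is reported as TP/FN/FP areas relative to
the ground-truth area (TP + FN = 100 by construction).

## Worked example

```r
library(ramanmargin)

cfg <- run_config(seed = 42, n_frames = 60, acquisition_stride = 3)
res <- run_experiment(cfg)
print(res$tracking_stats)
print(res$metrics)
```

which logs each acquisition as it is classified and pinned,

```
acquisition 9 @ frame 25 (398, 227): phantom [positive]
acquisition 10 @ frame 28 (357, 292): phantom [positive]
acquisition 11 @ frame 31 (313, 337): muscle
...
delineation: 4 positives, tp at margins [0, 1.5, 3] = [29.0, 33.4, 38.0]%
```

and prints

```
<tracking_error_stats> mean 0.129 +/- 0.062 mm over 60 valid frames (0 invalid)
  margin_mm   tp_pct   fn_pct fp_pct   tp_mm2   fn_mm2 fp_mm2
1       0.0 28.96534 71.03466      0 1944.810 4769.458      0
2       1.5 33.36816 66.63184      0 2240.428 4473.840      0
3       3.0 37.96127 62.03873      0 2548.821 4165.447      0
```

Read: the tracker localized the tip to 0.13 mm on average against the
known trajectory; a 60-frame sweep yielded 20 acquisitions of which 4 fell
inside the lesion and were classified positive; the four-point hull covers
29% of the ground-truth lesion at margin 0, growing monotonically (with
zero false-positive area) as the safety margin widens. Denser acquisition
(`acquisition_stride = 1`, more frames) drives TP toward 100%.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/ramanmargin.R` (subcommands `simulate`, `run`, `track`, `cv`,
`evaluate`).

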