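# hsderm

Hyperspectral dermatology image analysis for pigmented skin lesions (PSLs).

Snapshot VNIR hyperspectral cameras capture a 50 × 50 pixel skin scene in
125 contiguous bands between 450 and 950 nm, giving every pixel a full
reflectance spectrum. `hsderm` implements the complete processing chain
that turns such a capture into a clinical-support answer — *benign*,
*malignant*, or *reacquire* — for dermatologists and researchers working
with spectral imaging of skin:

1. **Pre-processing.** Radiometric calibration against white/dark
   reference frames, `CI = (RI − DI)/(WI − DI)`; removal of the 4 + 5
   low-response edge bands (125 → 116); moving-average spectral smoothing;
   per-signature min–max normalization so only spectral shape matters.
2. **Unsupervised lesion segmentation.** Seeded K-means (default K = 7)
   over pixel spectra; each cluster labeled skin or lesion by the Spectral
   Angle Mapper, `θ = acos(⟨s₁,s₂⟩ / (‖s₁‖‖s₂‖))`, against a five-entry
   reference library (three normal-skin cluster means + benign and
   malignant class means); morphological closing and small-component
   removal.
3. **Supervised pixel classification.** SVM (linear/RBF/sigmoid), random
   forest or a four-hidden-layer neural network, each exposing a malignant
   probability; a real-coded genetic algorithm tunes hyperparameters by
   maximizing validation AUC on a patient-disjoint split.
4. **Lesion-level decision.** A lesion is malignant when its
   malignant-pixel fraction strictly exceeds the 40 % risk threshold; a
   capture with no segmented lesion pixels requests reacquisition.

The clinical database behind this design is not public, so the package
includes a seeded synthetic scene generator (phenomenological VNIR skin
spectra: logistic rise, hemoglobin dips at 542/576 nm, melanin
attenuation; three skin phototypes; compact jittered lesions; illumination
gradients; sensor noise; paired white/dark frames) with known ground
truth. Every stage is validated against it. See the methods vignette
(`vignettes/hsderm-methods.Rmd`) for the full model description and design
rationale.

## Worked example

```r
library(hsderm)

# a synthetic labeling campaign: 12 patients, one capture each
ds <- make_dataset(n_patients = 12, seed = 3)
ds
#> <hs_dataset> 12 images from 12 patients, 2400 labeled spectra

# how many normal-skin groups? all three indices agree
evaluate_k(ds$labeled$spectra[ds$labeled$class == "skin", ], 2:7, seed = 5)
#> <k_selection> consensus K = 3 (silhouette=3, calinski_harabasz=3, davies_bouldin=3)

# the five-signature reference library (3 skin + benign + malignant means)
lib <- build_reference_library(ds$labeled, k_skin = 3, seed = 7)
lib
#> <spectral_library> 5 entries x 116 bands: skin_1 (skin), skin_2 (skin),
#>   skin_3 (skin), benign (benign), malignant (malignant)

# train the pixel classifier and process a new capture end-to-end
model <- train_classifier(ds$labeled, hyperparameter_set("svm_linear"),
                          seed = 2)
sc <- make_scene(scene_config(lesion_class = "malignant", seed = 71))
dec <- run_framework(sc$raw, sc$refs, lib, model,
                     seg_cfg = segmentation_config(seed = 6))
dec
#> <lesion_decision> malignant (malignant fraction 1.00 > threshold 0.40, 206 pixels)

# segmentation quality against the generator's ground truth
map <- attr(dec, "two_class_map")
jaccard(confusion(map$values == "psl", sc$gt_mask))
#> [1] 1
```

The decision record reports the lesion class, the malignant-pixel fraction
compared against the risk threshold, the number of segmented lesion
pixels, and per-pixel labels/scores. A pure-skin capture returns
`status = "reacquire"` instead of a class.

A thin command-line front end over the same functions is provided at
`inst/scripts/hsderm-cli.R` (subcommands: `simulate`, `preprocess`,
`repeatability`, `label`, `evaluate-k`, `build-library`, `segment`,
`evaluate`, `optimize`, `run`). Cubes travel as ENVI header/binary pairs
(BSQ, little-endian float32), masks as 8-bit PNG, spectra tables and
libraries as CSV, reports as JSON.

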