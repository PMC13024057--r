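# cephsal

Annotation-free quantification of craniofacial growth patterns and sexual
dimorphism from lateral-cephalogram-like images.

Orthodontic growth assessment classically reduces a radiograph to a few
manually placed landmarks. `cephsal` implements the opposite strategy: train
convolutional networks on two proxy tasks that encode development —
chronological-age regression and sex classification — and then ask the
trained networks *where they looked*. Gradient-weighted class activation
mapping (Grad-CAM) provides per-subject saliency maps; averaging them per
age (or age-by-sex) group and scoring them over anatomical regions yields
two interpretable statistics:

- **ASI** (age-related saliency index) of region *C* at age *a*:
  the mean of the age-task saliency values `S_ij` over the pixels of *C*
  with `S_ij >= t`, where *t* is the 75th percentile of the group's pooled
  saliency distribution (regions wholly below threshold score 0);
- **SSI** (sex-related saliency index): the same statistic computed from
  the sex-task saliency maps.

Regional scores are ensembled over k = 20 simulated annotator masks per
age-sex group (their majority vote is the consensus mask), mirroring how
ROI templates are built from repeated manual segmentations.

Clinical cephalograms cannot be distributed, so the package ships a
first-class synthetic **phantom** module: stylized lateral-skull images
whose six regions (orbit, zygoma, maxilla, sphenoid, temporal, mandible)
grow on region-specific logistic schedules, carry age-scheduled trabecular
texture and per-individual size variation, and hide a mandible-only
dimorphism signal that strengthens toward age 18. The planted importance of
a region at age *a* is the magnitude of its size-signal derivative, so the
whole pipeline can be validated by recovery: the networks must find the
signal, and the indices must rank the regions the way the generator planted
them.

The CNN engine (stride-2 convolution blocks, ReLU, global average pooling,
gated head; Adam, exponential learning-rate decay, early stopping) is
implemented in RcppArmadillo and is exact-gradient and fully deterministic.

## A worked example

```r
library(cephsal)

spec <- phantom_spec(canvas_side = 128)       # the default phantom cohort
co   <- sample_cohort(spec, 2000, seed = 1)
co$images <- preprocess_images(co$images)     # CLAHE, as in the protocol
for (i in seq_len(nrow(co$metadata)))         # align mirrored subjects
  co$images[,,i] <- align_orientation(co$images[,,i],
                                      co$metadata$orientation[i])
co$metadata$orientation <- "standard"

sp  <- stratified_split(co$metadata, seed = 2)     # 7 : 1.5 : 1.5
spl <- sp$split
fit <- ceph_cnn(co$images[,, spl == "train"], co$metadata$age[spl == "train"],
                task = "age",
                x_val = co$images[,, spl == "val"],
                y_val = co$metadata$age[spl == "val"],
                seed = 3)

pred <- predict(fit, co$images[,, spl == "test"])
regression_metrics(co$metadata$age[spl == "test"], pred)
#> Age estimation on 294 subjects: MAE 0.9705 y, RMSE 1.3513 y, R2 0.9043

tab <- saliency_index_table(fit, co$images[,, spl == "test"],
                            co$metadata[spl == "test", ], spec, seed = 4)
planted_recovery(tab, spec)$mean              # rank agreement with the truth
#> [1] 0.432381
```

Reading the numbers: a mean absolute error of 0.97 years against a
predict-the-mean baseline of about 3.75 years says the network extracted
most of the planted age signal. In the ASI table from this run, temporal
saliency in the youngest bins (0.78) exceeds its late-adolescent value
(0.58), and the late-age regional maximum is the maxilla (3.60) — the
planted "cranial base first, midface last" chronology. Training a sex
model on an age-18 cohort and computing the SSI localizes dimorphism to
the mandible (regional maximum, about 1.6x the runner-up; see
`scripts/acceptance.R`). `plot(fit)` draws the
training history; `summary(fit)`, `coef(fit)` and `residuals(fit)` behave
as for any fitted model.

`run_pipeline(config, out_dir)` performs all of the above (phantom,
preprocessing, splits, per-sex age models, per-age-subset sex models,
metrics, saliency, index tables) with a YAML/list configuration, a JSON
manifest, stage caching and full seed provenance; `export_reports()`
renders average-saliency overlays and the planted-vs-recovered comparison
chart.

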