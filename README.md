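# pigback

Non-contact estimation of sow body measurements and body weight from
overhead depth-camera point clouds, in pure R.

Weighing pigs on a scale is slow and stresses the animals. An overhead
depth camera looking down at a sow in a weighing chute captures the back
surface as a 3D point cloud; from that cloud the shoulder, abdominal and
hip widths can be measured without contact, and body weight can be
regressed directly from the point set. `pigback` implements the full
chain:

1. **PLY I/O** — hand-written reader/writer for ASCII and binary
   little-endian PLY files with optional per-point RGB
   (`read_ply()`, `write_ply()`).
2. **Voxel-grid filtering** — each occupied cube of side `edgelength` is
   replaced by the centroid of its points, equalizing density and cutting
   noise (`voxel_downsample()`).
3. **Scene segmentation** — seeded Lloyd K-means with restarts separates
   animal, floor and fencing; the cluster count can be selected
   automatically from the bend of the SSE-vs-K curve
   (`kmeans_cluster()`, `elbow_select_k()`); the animal is the cluster
   nearest the overhead camera (`extract_pig_cluster()`).
4. **Head/tail removal** — the cloud is cut into 2 cm blocks; a weighted
   local density (mean distance to the block center with the farthest
   point discounted) is high on the steep head and tail bulges; DBSCAN
   over the high-density blocks locates the two endpoints and a fixed
   0.4 m span beyond each is removed (`remove_head_tail()`).
5. **Pose correction** — a PCA oriented bounding box gives the body axis;
   if it deviates from x by more than 1° the cloud is rotated flat
   (`correct_pose()`).
6. **Three-section width measurement** — the torso is split into three
   equal sections along the body axis; each section's width is the
   largest cross-chord over its bins, giving shoulder, abdominal and hip
   widths (`measure_widths()`).
7. **MACNN weight regression** — a multi-head-attention convolutional
   network (five pointwise convolution layers, k-head scaled-dot-product
   attention, global max pooling, dropout, one linear output) trained
   with SGD + L2 on MSE, implemented with hand-written forward and
   backward passes in base R (`train_macnn()`, `predict()`); per-point
   RGB can be appended to the xyz features.

A parametric synthetic sow generator with per-point ground-truth labels
(`pig_spec()`, `make_pig()`, `make_scene()`, `make_cohort()`) supports
end-to-end testing without farm recordings, and a CLI (`pigback_cli()`,
launcher in `inst/cli/pigback.R`) exposes every stage as a subcommand.

## Worked example

```r
library(pigback)

spec  <- sample_pig_spec(23)        # one random sow
scene <- make_scene(spec)           # sow + platform + floor + rail
print(scene$cloud)
#> point_cloud: 5968 points, with RGB [synthetic scene]
#>   extent (m): x -1.149..1.149  y -0.806..0.686  z -0.017..1.517

report <- run_pipeline(scene$cloud,
                       pipeline_config(k = 3, seed = 5, log_level = "quiet"))
print(report)
#> pipeline_report [synthetic scene]
#>   points: input=5968 filter=3267 segment=1023 trim=731
#>   widths (m): shoulder 0.403, abdomen 0.402, hip 0.385
#>   total time: 0.220 s

round(scene$truth$widths, 3)        # generator ground truth
#> shoulder  abdomen      hip
#>    0.412    0.413    0.393
```

Training the weight regressor on a synthetic cohort (about 45 s):

```r
cohort <- make_cohort(120, seed = 8, color_mode = "size",
                      points_per_m2 = 800)
ds  <- cohort_features(cohort, mode = "xyzrgb", n_points = 64L, seed = 1)
cfg <- macnn_config(feature_mode = "xyzrgb", n_points = 64L,
                    conv_channels = c(8L, 16L, 24L, 32L, 40L),
                    n_heads = 2L, dropout_rate = 0.2, learning_rate = 0.005,
                    batch_size = 32L, epochs = 120L, seed = 3L)
model <- train_macnn(ds, cfg)

w    <- vapply(ds, `[[`, numeric(1), "weight")
pred <- predict(model, lapply(ds, `[[`, "features"))
round(unlist(regression_metrics(w[model$val_idx], pred[model$val_idx])), 2)
#>  mae mape rmse
#> 7.12 3.06 9.89   # held-out validation animals, kg / % / kg
```

The shipped reference table of tape-measured vs point-cloud-extracted
widths reproduces the published accuracies:

```r
ref <- reference_body_measurements()
mean_relative_error(ref$true_shoulder, ref$extracted_shoulder)  # 3.144 %
mean_relative_error(ref$true_hip,      ref$extracted_hip)       # 3.820 %
```

## Command line

```sh
Rscript inst/cli/pigback.R simulate --n 5 --out scenes/ --scenes
Rscript inst/cli/pigback.R pipeline --in scenes/pig_001.ply --out report.json
Rscript inst/cli/pigback.R --help
```

Exit codes: 0 ok, 2 usage error, 3 data error, 4 model error.

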