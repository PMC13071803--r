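# radiopose

Model-based 2D–3D bone pose estimation from biplanar x-ray images is
driven by bone *edges*: a CT-derived attenuation volume is posed in the
calibrated scene, digitally reconstructed radiographs (DRRs) are
rendered into both views, and an optimiser refines the 6-DOF pose by
maximising image similarity. Image resolution enters this pipeline in a
counter-intuitive way — full-resolution high-speed captures are
photon-starved, so their fine edges drown in noise, while downsampling
averages that noise away and *strengthens* edges. `radiopose` is a
self-contained R framework for studying this effect end to end with no
external data: it generates synthetic ankle-like phantom scenes with
exactly known gold-standard poses, registers perturbed poses back to
noisy synthetic radiographs, and quantifies how accuracy depends on the
resolution treatment (full resolution vs bicubic vs nearest-neighbour
4× downsampling).

It is aimed at researchers working with biplanar videoradiography
(BVR / XROMM-style workflows) who want a controlled sandbox for image
processing choices, and at anyone needing well-tested R building blocks
for DRR rendering, rigid 2D–3D registration, screw-axis error metrics
and robust nonparametric error summaries.

## What is inside

| Area | Functions |
| --- | --- |
| Rigid geometry | `rigid_transform()`, `rt_compose()`, `rt_rotation()`, transform CSV I/O |
| Inertial frames & perturbations | `inertial_frame()`, `perturbation_axes()`, `generate_perturbations()` |
| Synthetic phantoms | `make_bone_volume()`, `make_camera_rig()`, `make_trajectory()`, `make_trial_scene()`, `render_trial()` |
| DRR rendering | `render_drr()` (Rcpp trilinear ray marching), `project_point()`, calibration I/O |
| Image operators | `downsample_bicubic()` (Keys a = −0.5, antialiased), `downsample_nearest()`, `sobel_edges()`, `ncc()`, `preprocess()` |
| Registration | `registration_cost()`, `optimize_pose()` (global-best PSO) |
| Error metric | `helical_decompose()`, `pose_error()` (Chasles screw decomposition) |
| Statistics | `loa()`, `mad_unscaled()`, `cumulative_error()`, `hampel_outliers()`, `kruskal_wallis()`, `dunn_posthoc()` |
| Orchestration | `experiment_config()`, `run_experiment()`, `generate_fixtures()`, `load_fixtures()` |

The error metric is the helical (screw) decomposition of
`estimated ∘ gold⁻¹`: the rotation φ about the screw axis (degrees) and
the translation along it (mm), both reported as absolute values.
Error distributions are summarised by median, limits of agreement
(median ± 1.45 × IQR, lower bound truncated at 0), cumulative error,
unscaled MAD and Hampel outlier counts (modified z-score, threshold
3.5); conditions are compared with Kruskal–Wallis and, when
significant, Dunn's post-hoc test with Bonferroni correction.

A thin command-line wrapper lives at `inst/cli/phantom.R`
(`phantom.R make | fixtures | run | summarize | stats`).

## A worked example

Register a ±2°-perturbed pose of a noiseless synthetic talus back to
its own biplanar radiographs:

```r
library(radiopose)

scene <- make_trial_scene(image_size = 64, grid_size = 32, n_frames = 1,
                          bones = "talus", targets = "talus",
                          noise = noise_spec(enabled = FALSE),
                          seed = 1, exit_fov = FALSE)
gold    <- scene$trajectory$talus[[1]]
targets <- render_trial(scene)[[1]]          # two 64x64 count images

frame <- frame_at_pose(inertial_frame(scene$bones$talus), gold)
pert  <- generate_perturbations(gold, frame, perturbation_spec(2))  # 14 poses

res <- optimize_pose(pert$pose[[1]], scene$bones$talus, scene$cameras,
                     targets, pso = pso_config(seed = 42))
pose_error(gold, res$pose)
#> helical_error: phi = 0.109027 deg, translation = 0.00948783 mm
```

The printed numbers are the residual rotational error about the screw
axis and the residual translation along it after refinement: the 2°
initial-guess error has been reduced to about 0.1°.

The full factorial experiment — every bone × frame × perturbation ×
resolution condition, with summaries and tests written to disk — is one
call:

```r
cfg <- experiment_config(scene_seed = 1)   # desk-scale defaults
res <- run_experiment(cfg, outdir = "out")
head(res$summaries)   # median / LOA / cumulative / MAD / outliers per cell
res$tests             # Kruskal-Wallis + gated Dunn z-tests
```

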