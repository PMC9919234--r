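# gaitfuse

Indoor monitoring of walking persons — for example elderly persons in
ambient-assisted-living settings — can be done non-intrusively with
impulse-radar sensors (2-D position fixes at 10 Hz) and Kinect-class depth
cameras (positions at 30 Hz that see only the body side facing the
sensor). Each modality alone is flawed: radar fixes drift with strongly
autocorrelated ("red") noise, while depth tracks are biased toward the
sensor-facing side of the body and vanish whenever furniture occludes the
person. `gaitfuse` fuses the two asynchronous position streams and
extracts the gait parameters that clinicians actually use: the number of
turns, the travelled distance, the time spent in motion, and the mean
walking speed.

Three data-point fusion methods are provided, each fusing whenever a new
observation from either sensor arrives:

* **KF** — a Kalman filter on the nearly-constant-velocity model
  x&#8342; = F&#8342;x&#8342;&#8331;&#8321; + Γ&#8342;α&#8342; with random
  acceleration α&#8342; ~ N(0, diag(σ²_αx, σ²_αy)) and position
  observations z&#8342; = Hx&#8342; + η&#8342;, each weighted by its own
  noise covariance Σ_η,n;
* **MLP** — a multilayer perceptron (4 inputs x_r, y_r, x_d, y_d; 8 tanh
  hidden neurons; 2 linear outputs) mapping each time-aligned sample pair
  independently;
* **NARX** — a nonlinear autoregressive network with exogenous inputs
  (6 hidden neurons) whose two outputs are fed back to the hidden layer at
  lags {1, 2}, so the fused estimate depends on the movement history —
  which lets it coast through occlusion gaps.

Both networks are trained **entirely on synthetic data** from the built-in
simulator (red-noise radar model; ellipse-silhouette depth model with
visible-side bias, sinusoidal sway, and geometric line-of-sight
occlusion), so no recordings of real persons are needed for training. The
position accuracy is summarised by the empirical CDF of the pooled
position errors and the scalar indicators MEAE/MEDE/MAXE/STDE and AECDF
(area under the ECDF over [0, 1] m; 1 is perfect); gait-parameter accuracy
by the mean error (ME) and its standard deviation (SE) across walks.

## Worked example

```r
library(gaitfuse)

# a serpentine walk among two obstacles, radar at 10 Hz, depth at 30 Hz
scenario <- scenario_config(
  waypoints = rbind(c(0.5, 0.5), c(3.5, 0.5), c(3.5, 1.5), c(0.5, 1.5),
                    c(0.5, 2.5), c(3.5, 2.5), c(3.5, 3.5), c(0.5, 3.5)),
  walking_speed = 0.5,
  sensor_rates = c(radar = 10, depth = 30),
  obstacle_regions = list(c(1.2, 1.8, 1.0, 1.4), c(2.2, 2.8, 2.2, 2.6)),
  depth_sensor_position = c(2, -1))

reference <- build_reference_trajectory(scenario, rate = 10)
radar <- simulate_radar_track(reference, seed = 1)
depth <- simulate_depth_track(reference, depth_model_config(), scenario,
                              fragment = TRUE, seed = 2)

fused <- kf_fuse_tracks(radar, depth)
print(ecdf_and_indicators(position_errors(fused, reference)))
#> Position-error indicators (n = 721)
#>   MEAE  0.1485 m
#>   MEDE  0.1523 m
#>   MAXE  0.2842 m
#>   STDE  0.0605 m
#>   AECDF 0.8515

gait_summary(smooth_track(fused, 0.5))
#> Gait summary
#>   turns          : 6
#>   distance       : 14.632 m
#>   time in motion : 30.00 s
#>   mean speed     : 0.488 m/s
```

The serpentine reference has six 90° corners, a 15 m path, and a scripted
speed of 0.5 m/s: the fused track recovers all six turns and the speed to
within 3 %. The Kalman filter cannot remove the depth camera's systematic
near-side bias, which is what its MEAE mostly consists of; the neural
fusers learn that bias from the synthetic training set and typically halve
the fused position error (train with `train_network()`, or run the whole
protocol as below). A full pipeline —
simulate → train → fuse → smooth → extract → evaluate, with every artefact
written to disk and a manifest — is one call:

```r
run_pipeline(pipeline_config(scenario, methods = c("kf", "mlp", "narx"),
                             out_dir = "run1", seed = 1))
```

A thin command-line wrapper with the same stages is installed at
`inst/cli/gaitfuse.R`
(`gaitfuse.R simulate|train|fuse|extract|evaluate|run`).

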