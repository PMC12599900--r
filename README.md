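# pcgatoms

Interpretable detection of coronary-artery-occlusion acoustic biomarkers in
multichannel heart-sound recordings (phonocardiograms).

Partially occluded coronary arteries shed turbulent flow that is audible as a
faint, band-limited diastolic murmur. Relieving the occlusion (e.g. by stent
placement) changes that acoustic signature, so a recording taken before and
one taken after intervention form a natural within-patient classification
task — and a model that solves it must have learned *which* sounds the
occlusion contributed. `pcgatoms` implements that whole chain for 4-channel,
4000 Hz, 15-second recordings:

1. **Beamforming** — per-channel delays estimated by cross-correlation
   (±25 ms), channels aligned and averaged (delay-and-sum; ~6 dB SNR gain at
   4 channels).
2. **Segmentation** — 1.5 s sliding windows with 50% overlap (full cycle)
   and 128 ms diastolic windows starting 100 ms after each S2 onset; S2 comes
   from a simplified envelope detector or an annotation sidecar.
3. **Matching pursuit** — each segment is greedily decomposed into 100 Gabor
   atoms `g(t) = K·exp(-π((t-u)/s)²)·cos(2πf(t-u)/fs + φ)` with dyadic
   scales `s = 2^j`, `j ∈ [2, 12]`, frequencies `k·fs/2^j ≤ 1000 Hz`, all
   integer translations (searched via FFT), and analytically optimal phase.
   Energy conservation `‖x‖² = Σc_i² + ‖r‖²` holds to machine precision.
4. **Atom features** — per atom: scaled coefficient magnitude, phase
   (sin, cos), scaled frequency and octave, four *atomic influence* counts
   (temporally overlapping atoms extracted earlier/later and of lower/higher
   octave), plus an encoded patient ID.
5. **Set classification** — a permutation-invariant set network (per-atom
   encoder → shared MLP → mean/max/sum/attention pooling → output head)
   labels each atom set pre- vs post-intervention; hyperparameters are
   searched over latent/hidden dims [4, 512], pooling, dropout [0, 0.5],
   None/LayerNorm/BatchNorm, log-uniform learning rate [1e-4, 1e-2] and
   weight decay. A random-forest baseline on flattened set statistics is
   included.
6. **Attribution** — atom latents (encoder outputs) are embedded with UMAP,
   clustered with DBSCAN (ε = 0.5, min 5 points), and each cluster is
   selectively reconstructed (Gaussian smoothing σ = 5 samples, zero-phase
   5th-order 65–400 Hz Butterworth), then scored by cardiac-cycle power and
   by spectral-power change in eight 50 Hz bands (0–400 Hz) with monotonic
   increase/decrease/mixed grouping at ±1e-6 tolerance.

No patient recordings ship with the package; a synthetic generator plants a
controllable 150–400 Hz diastolic murmur in "pre" recordings so that every
stage — including the final attribution — can be validated against ground
truth.

## Worked example

```r
library(pcgatoms)

wd <- tempfile("pcg")
cfg <- pipeline_config(workdir = wd, seed = 11, n_subjects = 2,
                       duration = 6, n_atoms = 40, n_trials = 2,
                       max_epochs = 30, patience = 6)
run_pipeline("all", cfg)

read.csv(file.path(wd, "leaderboard.csv"))[, c("code_name", "pooling",
                                               "val_acc", "test_acc")]
#>             code_name   pooling   val_acc  test_acc
#> 1 wobbly-lumpy-avocet       max 1.0000000 0.6666667
#> 2    rustic-spry-sora attention 0.6666667 0.3333333

head(read.csv(file.path(wd, "cluster_report.csv"))[, c("subject_id",
     "cluster_id", "group", "band", "delta")], 4)
#>   subject_id cluster_id group      band delta
#> 1        S01         -1 mixed    0-50Hz     0
#> 2        S01         -1 mixed  50-100Hz     0
#> 3        S01         -1 mixed 100-150Hz     0
#> 4        S01         -1 mixed 150-200Hz     0
```

The leaderboard ranks hyperparameter-search trials (random code names, one
row per trial) by validation accuracy; at this miniature scale (2 subjects,
~20 samples) accuracy is weak — at the 12-subject scale used in the
acceptance suite the selected model reaches test accuracy 1.0 on the
synthetic task against a label-shuffled null of ≈ 0.56 (95th percentile).
The cluster report gives, per subject and DBSCAN cluster, the change
(post − pre) in band power for each 50 Hz band and the resulting monotonic
group; cluster −1 is DBSCAN noise, and its near-zero deltas land it in
"mixed". Clusters dominated by planted murmur atoms come out "decrease" —
the murmur disappeared after the simulated intervention.

Individual stages are ordinary functions:

```r
g <- generate_recording(synth_config(seed = 1), "pre")
sig <- beamform(g$recording)
dw <- extract_diastolic_windows(sig, detect_s2(sig))
d <- decompose(dw[[1]])            # 100 Gabor atoms
head(as.data.frame(d), 3)
#>   iteration octave frequency_hz translation      phase coefficient_magnitude
#> 1         0      6        250.0         103  0.9258106              2.626135
#> 2         1      6        312.5         166  3.1081278              2.419322
#> 3         2      4        250.0         472 -2.5771783              2.295009
```

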