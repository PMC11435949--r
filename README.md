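# radarposture

Contactless sleep-posture classification from single-antenna FMCW
millimetre-wave radar, in R.

Sleep posture matters clinically — supine sleep worsens obstructive sleep
apnea, and prolonged fixed postures are a pressure-ulcer risk — but
cameras raise privacy concerns and pressure mats disturb sleep. A
wall-mounted 58 GHz FMCW radar senses chest micro-motion (respiration,
heartbeat) through bedding, and the *statistics* of that micro-motion
differ between supine, lateral and prone lying. `radarposture` implements
the full chain from raw intermediate-frequency (IF) samples to a
three-class posture decision, plus a physics-based synthetic bed-scene
simulator so the entire pipeline is reproducible without human-subject
data.

## The method

For a target at distance $D$, each chirp yields the IF tone
$x(m) = A\sin(2\pi f_0 T_s m + \phi_0)$ with beat frequency
$f_0 = 2Ds/c$ (chirp slope $s = B/T_c$) and phase
$\phi_0 = 4\pi D/\lambda$. The pipeline:

1. **Preprocessing** — two consecutive mean subtractions on the
   fast-time × slow-time cube (per-row slow-time mean, then per-column
   fast-time mean) remove DC and static clutter exactly.
2. **Range FFT** — per-chirp 128-point DFT, one-sided 64 bins, giving the
   range spectrogram $F_{k n}$.
3. **Motion features** — sliding-window standard deviation of $|F|$ along
   slow time (window 0.5 s, step 0.1 s), cropped to the 40-bin range
   window with maximal total deviation: one 40 × 60 feature image per 6 s.
4. **Augmentation** — circular time shifts (±[0.5, 1] s), zero-fill range
   shifts (±[5, 10] bins), and cross-class mix-up with
   $\lambda \sim \mathrm{Beta}(0.4, 0.4)$.
5. **ResTCN** — a residual convolutional backbone (conv–BN–ReLU blocks,
   striding over range only) producing a per-time-step embedding, followed
   by a causal dilated temporal convolution network whose last time step
   is classified; trained with AdamW (lr 0.005, weight decay 0.001, lr
   ÷10 every 10 epochs), evaluated subject-wise with one-vs-rest
   macro-averaged precision/recall/F1. The network, including exact
   backward passes, is implemented in this package (R + C++ im2col).

Ablation variants (`resnet_only`, `tcn_only`, raw range-FFT input,
augmentation off) are first-class citizens of the pipeline.

## Worked example

Simulate one breathing scene, run the chain, and estimate the vital sign:

```r
library(radarposture)

cfg   <- radar_config()               # 5 GHz BW, 58 GHz, 128 x 640/s
scene <- scene_config(torso_distance_m = 0.9, respiration_rate_hz = 0.27,
                      respiration_amplitude_m = 6e-3, seed = 5)
cube  <- synthesize_cube(scene, cfg, duration_s = 64)
spec  <- range_fft(preprocess_cube(cube))

torso_bin(spec)                       # 28   (0.9 m at ~3.1 cm per bin)
estimate_breathing_rate(spec)         # 0.27025 Hz  (programmed: 0.27)

imgs <- extract_feature_images(spec, feature_params(), posture = "supine")
imgs[[1]]
#> <motion_feature_image> 40 x 60, offset 5, subject S0, label (1, 0, 0)
```

End-to-end benchmark (9 simulated subjects × 4 postures × 1 min,
subject-wise 6/1/2 split, 30 epochs — about 4 minutes on one core):

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$report
#> <eval_report> n = 80, accuracy 0.9250, macro P/R/F1 0.9413/0.9083/0.9206
#>          predicted
#> true      supine lateral prone
#>   supine      20       0     0
#>   lateral      0      39     1
#>   prone        0       5    15
glance(res)      # one-row tibble; tidy(res$report) gives per-class metrics
autoplot(res$report)
```

The 80 test images are the 2 held-out subjects' 4 postures × 10 images
(lateral contributes two recordings, hence 40). The residual confusion is
prone versus lateral, the genuinely overlapping preset pair. Accuracy here
reflects the synthetic benchmark's by-construction separability, not
real-world performance; see the methods vignette
(`vignettes/radarposture-methods.Rmd`) for what the simulator does and
does not emulate.

A thin CLI over the same functions lives at `inst/cli/radarposture.R`
(subcommands `simulate`, `features`, `run`, `sweep`).

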