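# cineRAKI

Scan-specific k-space reconstruction for uniformly undersampled multi-slice,
multi-phase (cine) cardiac MRI, in R.

Parallel imaging accelerates cine MRI by acquiring only one of every *R*
phase-encode lines plus a small fully sampled central block (the
autocalibration signal, ACS). This package implements the k-space
interpolation family of reconstructions for that setting:

* **GRAPPA** — linear interpolation kernel fit to the ACS by regularized
  least squares and applied to fill the missing lines;
* **RAKI** — scan-specific convolutional network (conv 2N→64 [5×5] + ReLU,
  conv 64→32 [1×1] + ReLU, conv 32→2N [3×3]) trained on the ACS alone;
* **rRAKI** — RAKI plus a parallel single linear convolution, trained with
  the combined loss `MAE(sum, target) + λ·MAE(linear, target)`, λ = 1;
* **SRAKI** — the simplified model: one linear 5×5 convolution over the
  `2N` real/imaginary channels, trained by the same gradient-descent recipe
  (MAE, 600 epochs of full-batch Adam at lr 0.01, reduce-on-plateau
  factor 0.1 / patience 10 / threshold 0.001).

At 15 coils the three networks have 58 814 (RAKI), 81 344 (rRAKI) and
22 530 (SRAKI) trainable parameters.

Because scan-specific training is the bottleneck of a cine stack
(9 slices × 23 phases = 207 trainings), the package implements
weight-sharing strategies that exploit the stability of coil sensitivities
across the cardiac cycle and their smooth drift across slices:
`per_frame`, `mp` (one trained phase per slice), `ms(1/B)` (train the
middle slice of each group of *B* slices), and the combined `mp_ms`
(3 trainings for a 9-slice stack). Trained-weight stability is quantified
with the absolute-covariance Pearson coefficient
ρ(X, Y) = |Cov(X, Y)| / (σ_X σ_Y) against a reference slice/phase, and
image quality with PSNR / SSIM / NMSE on a 70×70 heart region of interest.

A synthetic multi-coil cine phantom with known ground truth (beating-heart
disc, static torso, ring of smooth complex coil profiles that are constant
across phases and rotate across slices, complex Gaussian k-space noise)
makes every method and both redundancy assumptions testable without any
data download.

## Worked example

```r
library(cineRAKI)

cfg   <- phantomConfig(ny = 64, nx = 64, nSlices = 1, nPhases = 2,
                       nCoils = 8, seed = 42)
truth <- generateCineTruth(cfg)
mask  <- buildMask(samplingScheme(R = 4, nACS = 26, ny = 64))
mask
#> SamplingMask: ny=64, R=4, ACS [19,45) (26 lines), 35/64 rows acquired

res <- runStrategy(truth, mask, method = "sraki",
                   spec  = strategySpec("mp", phaseSelection = "fixed"),
                   hyper = trainingHyper(seed = 1))
res
#> ReconResult (sraki): 1 slice(s) x 2 phase(s), 64 x 64; 1 training(s), total train 6.06s

evaluateStack(res, truth)
#> MetricsReport: 2 frame(s)
#>   psnr: 31.83 +/- 0.3343
#>   ssim: 0.855 +/- 0.001343
#>   nmse: 0.003624 +/- 0.0001709
```

One SRAKI training (the `mp` strategy reuses its weights for both cardiac
phases) reconstructs the 4-fold undersampled frames at ~31.8 dB on the
heart ROI — on par with per-frame GRAPPA (31.78 dB on the same frame) and
about 6 dB above the zero-filled reconstruction (25.65 dB). NMSE is the
mean squared error normalized by the reference energy (lower is better);
SSIM is structural similarity on the ROI (1 = identical).

A thin command-line wrapper over the same functions is installed at
`inst/cli/cineraki.R`, with subcommands `simulate`, `undersample`, `recon`,
`evaluate` and `corrweights`:

```sh
Rscript inst/cli/cineraki.R simulate --out cine.rds --slices 3 --phases 4 --coils 8 --seed 7
Rscript inst/cli/cineraki.R recon --in cine.rds --out rec.rds --method sraki \
        --strategy mp_ms --R 4 --acs 26 --seed 7
Rscript inst/cli/cineraki.R evaluate --in rec.rds --out metrics.tsv
```

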