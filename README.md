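# mcadenoise

Hybrid denoising of grayscale MR images by **morphological component
analysis (MCA)**. A noisy image is decomposed into three additive parts —

* **cartoon**: piecewise-smooth structure (flat tissue regions, contours),
  sparse in an undecimated starlet wavelet;
* **texture**: locally periodic oscillation, sparse in an overlapping
  windowed block DCT;
* **residual**: everything neither dictionary codes sparsely (mostly
  noise), kept explicitly rather than discarded —

and each part is denoised by the classical filter suited to it before the
three filtered parts are superimposed. The proposed assignment is **WHS**:
adaptive **W**iener filtering on the cartoon part, wavelet **h**ard
thresholding on the texture part, wavelet **s**oft thresholding on the
residual.

The decomposition solves the sparse separation problem

```
min ||a_c||_1 + ||a_t||_1   s.t.  || s − Φ_c a_c − Φ_t a_t ||_2 ≤ ε,
s = Φ_c a_c + Φ_t a_t + R
```

by block-coordinate relaxation with a linearly descending hard threshold;
for denoising, the schedule stops at `3·σ̂` (MAD noise estimate), which is
what leaves the noise in `R`. Quality is scored by byte-scale
`MSE = mean((f − f̂)²)` and `PSNR = 10·log10(255²/MSE)` dB.

The package ships the full evaluation harness — a seeded phantom generator
with known cartoon/texture ground-truth layers (real MR slices cannot be
redistributed), the 0.01–0.09 noise-variance sweep, and the six-permutation
ablation of filter-to-part assignments — for anyone studying hybrid
denoising pipelines or needing a reproducible MCA baseline.

## Worked example

```r
library(mcadenoise)

# a 128-pixel phantom: smoothed nested ellipses + a windowed cosine grating
ph <- make_phantom(phantom_spec(size = 128, seed = 101, texture_frequency = 16))
noisy <- add_gaussian_noise(ph$clean, noise_spec(variance = 0.05, seed = 42))

denoised <- denoise_hybrid(noisy, "WHS")
cat(sprintf("PSNR noisy: %.2f dB\n", psnr(ph$clean, noisy)))
cat(sprintf("PSNR WHS:   %.2f dB\n", psnr(ph$clean, denoised)))
#> PSNR noisy: 14.27 dB
#> PSNR WHS:   21.24 dB
```

The hybrid recovers about 7 dB on this phantom. The decomposition itself:

```r
dec <- mca_decompose(noisy, mca_config(lambda_min = 3 * estimate_noise_sigma(noisy)))
tidy(dec)
#> # A tibble: 3 × 5
#>   part     energy energy_fraction    min   max
#>   <chr>     <dbl>           <dbl>  <dbl> <dbl>
#> 1 cartoon  2073.           0.665  -0.182 1.08
#> 2 texture    77.0          0.0247 -0.312 0.306
#> 3 residual  597.           0.192  -0.564 0.665
```

Two thirds of the noisy image's energy lands in the cartoon part, the
grating in the texture part, and ~19% — dominated by noise below the
`3σ̂` stop — stays in the residual, where the soft threshold removes it.
`plot_image(dec)` shows the three parts side by side. The sweep harness
compares methods on identical noisy realizations:

```r
bm <- run_benchmark(list(phantom1 = ph$clean), variances = c(0.03, 0.05),
                    methods = c("noisy", "wiener", "WHS"), seeds = 1L)
bm$averages
#> # A tibble: 6 × 4
#>   variance method_label   mse  psnr
#>      <dbl> <chr>        <dbl> <dbl>
#> 1     0.03 WHS           322.  23.0
#> 2     0.03 noisy        1494.  16.4
#> 3     0.03 wiener        448.  21.6
#> 4     0.05 WHS           472.  21.4
#> 5     0.05 noisy        2402.  14.3
#> 6     0.05 wiener        712.  19.6
```

`autoplot(bm)` draws the PSNR-against-variance lines;
`run_ablation()` scores all six assignments (SHW … WHS) and reports the
per-cell best. A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mcadenoise.R phantom   --out phantoms --size 256
Rscript inst/cli/mcadenoise.R denoise   --in phantoms/phantom1_noisy_v0.05_s1.png \
                                        --out denoised.png --clean phantoms/phantom1_clean.png
Rscript inst/cli/mcadenoise.R benchmark --out report.csv --ablation
```

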