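# speckleseg

Segmentation of organ-like regions in B-mode ultrasound-style images, with
the full chain needed to develop and validate it without clinical data:

* **Speckle phantoms** — a synthetic generator producing a smooth dark
  organ ("bean") on a brighter background, corrupted by multiplicative
  Rayleigh-envelope speckle (`M = sqrt(Mr² + Mi²)`, `Mr, Mi ~ N(0, σ²)`;
  `P' = P · N`), with the true mask retained.
* **Homomorphic Perona–Malik denoising** — anisotropic diffusion
  `Î(x) = I(x) + λ Σ_p c(|∇I_{x,p}|) ∇I_{x,p}` on the log-transformed
  image (multiplicative noise becomes additive), with the rational
  `1/(1+(g/k)²)` or exponential `exp(-(g/k)²)` coefficient.
* **PCNN initial contours** — a pulse-coupled neural network
  (`F ← d_F F + S + V_F(M∗Y)`, `L ← d_L L + V_L(W∗Y)`, `U = F(1+βL)`,
  fire when `U > θ`, `θ ← d_θ θ + V_θ Y`) whose synchronous firing waves
  separate intensity classes in time; an Otsu split of the first-fire
  iterations yields the organ mask, and its traced boundary the initial
  contour.
* **Classical Snake** — the discrete contour energy
  `Σ ½(α|v_{i+1}-v_i|² + β|v_{i+1}-2v_i+v_{i-1}|²) + κ Σ E_ext(v_i)` with
  `E_ext = −|∇(G_σ∗I)|²`, evolved semi-implicitly:
  `x' = (A + γI)⁻¹(γx + κF_x)`.
* **Cloud-model ACM** — a differential-evolution refinement of the same
  Snake energy over radial contour displacements, perturbed by a normal
  cloud generator (`En' ~ N(En, He²)`, `x ~ N(Ex, En'²)`) with annealed
  entropy.
* **Metrics & benchmark** — PSNR/MSE for denoising, Dice, Matthews
  correlation and pixel error rate for segmentation, plus a paired
  phantom benchmark comparing both contour methods from identical
  initializations.

## Worked example

```r
library(speckleseg)

ph <- generate_phantom(sigma = 0.8, seed = 1)
ph
#> speckle_phantom 96x96  sigma=0.8  seed=1  object area=1786 px

res <- segment_image(ph$noisy, method = "cloud-acm", seed = 1)
res
#> segmentation_result: 100 points, 150 iterations, converged, energy -142.1

metrics_report(res$mask, ph$truth_mask,
               reference = ph$clean, processed = res$denoised)
#> DSC 0.9759  MCC 0.9703  error rate 0.0095  PSNR 19.45 dB  MSE 0.0114

psnr(ph$clean, ph$noisy)   # before denoising: 9.48 dB
```

The phantom is a 96×96 frame with a 1786-pixel bean-shaped "organ" under
heavy speckle (9.5 dB against the clean image). The pipeline denoises it
to 19.5 dB, the PCNN isolates the dark region, and the refined contour
overlaps the true mask with Dice 0.976 while misclassifying 0.95% of the
frame's pixels.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/speckleseg.R simulate --shape 96x96 --sigma 0.8 --seed 7 --out ph/
Rscript inst/cli/speckleseg.R segment  --in ph/noisy.png --method cloud-acm --out mask.png --seed 3
Rscript inst/cli/speckleseg.R evaluate --pred mask.png --truth ph/mask.png --report report.json
```

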