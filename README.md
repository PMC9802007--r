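# hibnoddi

Estimation of **intra-axonal axial diffusivity** and **fibre orientation
dispersion** from high b-value diffusion MRI, for researchers modelling
white-matter microstructure who do not want to assume the axial
diffusivity a priori.

Classic NODDI-style analyses fix the intra-axonal axial diffusivity
(typically d&#8741; = 1.7 &mu;m&sup2;/ms) and estimate signal fractions and
dispersion around that assumption; much of the recent literature instead
estimates d&#8741; ≈ 2–2.5 &mu;m&sup2;/ms, and the fitted parameters shift
substantially with the assumed value.  At high diffusion weighting
(b ≳ 6 ms/&mu;m&sup2;) the extra-axonal signal is suppressed and the
remaining intra-axonal signal can be modelled as a Watson-dispersed stick:

$$S_{b,g} = f_{in} S_0\,
\frac{{}_1F_1(\tfrac12;\tfrac32;\,\kappa\mu\mu^\top - b d_\parallel gg^\top)}
     {{}_1F_1(\tfrac12;\tfrac32;\,\kappa\mu\mu^\top)},\qquad
ODI = \tfrac{2}{\pi}\arctan(1/\kappa).$$

Dividing by the per-shell powder average
$\bar S_b = f_{in} S_0 \sqrt{\pi}\,\mathrm{erf}(\sqrt{bd_\parallel})/(2\sqrt{bd_\parallel})$
leaves a two-parameter model in (ODI, d&#8741;), fitted jointly with an
explicit signal offset c and (for magnitude data) a rectified Rician noise
floor &epsilon; by a grid-search-initialised Metropolis–Hastings sampler.
Getting c or &epsilon; wrong — e.g. assuming Gaussian noise on magnitude
images — biases d&#8741; and ODI upward; the package's simulation drivers
reproduce and quantify this.

The package provides:

* the forward models (`predictSignalFull`, `predictSignalRatio`,
  `powderAverageModel`) built on a deterministic evaluator of the
  matrix-argument confluent hypergeometric function (`hyp1f1Sym3`);
* noise handling: offset / Rician-floor forward models, noise-corrected
  powder averaging, pure-noise (ventricle) characterisation
  (`fitPureNoise`);
* a synthetic multi-shell simulator with matched real-valued and magnitude
  datasets (`simulateVoxels`), voxel averaging and rotation-based
  concatenation;
* the fit itself (`gridSearchInit`, `mhFit`, `fixedNoiseSweep`) plus a
  diffusion-tensor utility (`dtiFit`) and single-fibre voxel selection;
* the classic three-compartment NODDI forward model with a user-settable
  axial diffusivity (`noddiForward`, `noddiFitFixedDpar`,
  `sensitivityReport`);
* reproducible experiment drivers (`runRecoveryExperiment`,
  `runPosteriorExperiment`, `runSnrSweep`, `runMisspecificationSweep`)
  and a command-line front end (`inst/scripts/hibnoddi`).

## Worked example

Simulate 100 voxels at the default ground truth (d&#8741; = 2.2
&mu;m&sup2;/ms, ODI = 0.03, f_in = 0.6, c = 10, per-voxel SNR 16.5; three
shells at b = 6.75/9.85/13.5 ms/&mu;m&sup2; × 64 directions), average them
(SNR ≈ 165) and fit the real-valued variant:

```r
library(hibnoddi)
cfg <- SimulationConfig(nVoxels = 100, seed = 42)
sim <- simulateVoxels(cfg)
avg <- averageVoxels(sim$real)
fit <- mhFit(avg, FibreOrientation(0, 0),
             FitConfig("real", nSamples = 4000, burnIn = 1500, seed = 7))
posteriorSummary(fit)
#>   parameter       mean         std       q025        q50        q975
#> 1       odi 0.02982714 0.001177417 0.02768883 0.02978215  0.03197609
#> 2      dPar 2.21964080 0.085147010 2.06801711 2.21268074  2.38428128
#> 3         c 9.98880933 0.048801107 9.88554248 9.98988452 10.07901757
```

The posterior means sit on the generating values: d&#8741; = 2.22 ± 0.09
&mu;m&sup2;/ms (truth 2.2), ODI = 0.0298 ± 0.0012 (truth 0.03) and offset
c = 9.99 ± 0.05 (truth 10).  Fitting the matched magnitude dataset instead
adds the noise-floor parameter &epsilon; and exposes its strong posterior
correlation with c; clamping &epsilon; to 0 on magnitude data (a Gaussian
noise assumption) drives d&#8741; toward ~3.7 and ODI toward ~0.11 — the
bias the explicit noise model exists to remove.

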