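---
title: "Water and lipid nuisance removal for 1H-MRSI: models and methods"
author: "mrsiclean authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water and lipid nuisance removal for 1H-MRSI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsiclean)
```

## The problem

Whole-brain proton MR spectroscopic imaging acquires a spectrum in every
voxel of a spatial grid. Two nuisance signals dwarf the metabolite
resonances of interest: residual water at 4.68 ppm, with amplitudes three to
four orders of magnitude above the metabolites and an asymmetric lineshape
after suppression pulses, and subcutaneous (scalp) lipids, one to two orders
of magnitude stronger than metabolites, whose broad resonances (0.9-5.3 ppm)
overlap the entire aliphatic region. Because the lipid sources sit in the
scalp, the limited k-space coverage of MRSI spreads their signal into brain
voxels as Gibbs ringing. Both nuisances must be removed before metabolite
quantification.

`mrsiclean` implements three removal routes behind one consistent API:

* a dual-encoder 1D convolutional network (Y-Net) that *identifies* the
  combined lipid+water signal `y` in a spectrum and removes it by
  subtraction, `m = x1 - y` (modes `walinet` for lipid+water and `lipnet`
  for lipid only);
* the conventional lipid L2-regularization operator
  `L_op = (1 + beta * L L^H)^-1` built from scalp-voxel spectra `L`;
* HLSVD water removal by damped-sinusoid decomposition of the FID.

## The network and its two inputs

The network receives the contaminated spectrum `x1 = m + l + w` and its
lipid-subspace projection `x2 = (1 - L_op) x1`. The second input already
isolates most of the nuisance signal, so the network only has to learn the
residual discrepancy between the linear-subspace estimate and the true
nuisance; this is what makes the two-input strategy markedly easier to train
than a single-input denoiser.

Each of the two encoders and the decoder has four convolutional blocks (two
convolution layers per block, kernel size 7, PReLU activations, dropout
0.01), with max-pooling by 2 after every encoder block and linear
upsampling before every decoder block. Channels start at 16 and double with
each pooling level (16/32/64/128); an extra block sits at the bottleneck on
the concatenated encoder outputs and another one after the decoder. Skip
connections from *both* encoders are channel-concatenated into the decoder
at matching scales. Real and imaginary parts are separate channels, so the
network maps two 2-channel inputs to one 2-channel output of the same
length.

Two published recipe elements are reproduced exactly:

* **Phase augmentation.** Every training triplet is multiplied by a common
  random phase `exp(i*omega)`, `omega ~ U[0, 2*pi]`, making the network
  phase-equivariant rather than requiring phased input.
* **Energy normalization.** Inputs and target are divided by
  `E = ||x1 - x2||`, the root-sum-squared difference of the two inputs.
  Since `x1 - x2 = L_op x1` is the lipid-suppressed spectrum, `E`
  approximates the energy of the underlying metabolite signal and makes
  training and inference invariant to the absolute scale of the data. The
  same per-spectrum `E` de-normalizes the prediction at inference.

Training minimizes the MSE of the separated real/imaginary channels with
Adam (`beta1 = 0.9`, `beta2 = 0.999`), learning rate 0.01 quartered every 50
epochs in the full 400-epoch schedule. The implementation is a from-scratch
RcppArmadillo backend (im2col + GEMM convolutions with exact analytic
gradients, verified against finite differences in the test suite), so the
package has no deep-learning framework dependency and the training loop is
bit-reproducible from a single seed.

### Architectural choices the publication left open

* Input length 453 is zero-padded to 464 (the next multiple of
  `2^depth = 16`) and the pad is cropped after the last layer; the pad
  region is excluded from the loss.
* Upsampling uses linear interpolation.
* Convolutions use same-(zero)padding.
* The final output block is a linear convolution (no activation), since the
  target is a signed spectrum.

## Synthetic training data

The published training corpus combined simulated metabolite spectra with
lipid/water signal *measured* in vivo from 19 subjects. No such data ship
with this package; instead, a parametric nuisance generator takes the place
of the measurement, and everything else follows the published construction.
What the generator emulates, and what it cannot:

* **Metabolite spectra** are simulated from first principles: the isotropic
  chemical-shift + J-coupling Hamiltonian of each proton system is
  diagonalized exactly on the spin product space (no weak-coupling
  approximation; coupled components capped at 8 spins, larger systems are
  split into independent coupling components). The bundled plain-text
  catalog covers 12 major brain metabolites (NAA, NAAG, Cr, Cho, Glu, Gln,
  Ins, Lac, GABA, Tau, Gly, Asp) with shifts and couplings from standard
  published tables; the exact 25-metabolite list of the original corpus is
  not public, so the catalog is a documented superset-ready stand-in (any
  user catalog in the same TSV format is accepted).
* **Randomization ranges** (the original supplement is not public; these
  are recorded in configuration, chosen once as physiologically sensible):
  concentrations uniform on [0, 1] scaled by physiological ratios relative
  to NAA; extra Voigt-like broadening uniform on [4, 20] Hz; smooth
  baselines as 3-6 very broad (>100 Hz) Gaussian bumps with random signed
  amplitudes; complex noise with sigma spanning two orders of magnitude
  (10^-3 to 10^-1 of the reference metabolite peak).
* **Lipid spectra** are sums of broad Lorentzians at 0.9, 1.3, 1.6, 2.0,
  2.25, 2.8, 4.4, 5.1 and 5.3 ppm with per-component random amplitude,
  linewidth (25-120 Hz, always broader than metabolite lines), phase jitter
  around a common phase, and small frequency jitter; total amplitude 1-2
  orders of magnitude above the metabolite reference.
* **Residual water** is a superposition of narrow and broad components with
  independent phases and offsets near 4.68 ppm, which produces the
  characteristic asymmetric heavy-tailed lineshape. Raw water artifacts are
  3-4 orders of magnitude above the metabolites, but MRSI acquisitions use
  WET water suppression, so the water that reaches post-processing is the
  suppressed residual; the generator draws it 1.5-2.5 orders above the
  metabolite reference (raw scale minus a typical ~1.5-order suppression),
  which keeps it the strongest signal in every spectrum. Acquisition
  sidebands are off by default (configurable harmonics).
* All nuisance components are synthesized in the time domain as damped
  complex exponentials, so every generated FID is physically realizable and
  the damped-sinusoid model underlying HLSVD is exact rather than
  approximate for them.
* **Synthetic subjects** replace the in vivo subject pool: each subject is
  one draw of nuisance hyper-parameters with its own lipid basis `L` (50
  scalp spectra) and its own beta-calibrated projection operator, mirroring
  the per-subject operator of the in vivo pipeline. Train/validation splits
  are subject-wise, so no subject leaks across partitions.

What passing tests on these data do **not** show: robustness to B0
inhomogeneity, eddy-current lineshape distortions, coil-combination
artifacts, out-of-catalog macromolecule baselines, or any other in vivo
effect the generator does not model. Results on synthetic data transfer to
real data only to the extent that the generator is realistic; this is the
main limitation inherited from replacing the measured nuisance corpus.

## The spatial phantom

The 2D phantom exists to exercise the *spatial* mechanism of lipid
contamination: a high-resolution elliptical brain (textured concentration
maps) and scalp annulus (lipid + water amplitude maps) are synthesized
spatio-spectrally, then k-space is truncated to the acquisition matrix with
no apodization (worst-case ringing; optional Hamming flag). Brain voxels of
the result are contaminated by scalp-lipid ringing exactly as in vivo, and
the pre-truncation metabolite-only volume provides voxel-wise ground truth.
The truncation operator is validated against a direct DFT point-spread
oracle in the tests.

## Baselines

* **Lipid L2 regularization.** The operator is kept in factored SVD form,
  `L_op = I - U diag(beta*s^2/(1+beta*s^2)) U^H`, applied in the frequency
  domain at O(n_freq x rank) cost; the dense inverse is never formed
  (equivalence to the dense inverse is tested to 1e-8). `beta` is
  calibrated by bisection on log10(beta), exploiting the strict
  monotonicity of `mean(|diag(L_op)|)` in beta, to the standard setpoint
  0.938 +/- 1e-3 -- the published trade-off between lipid suppression and
  metabolite preservation. The operator acts on the full spectral grid; a
  ppm-window option exists.
* **HLSVD.** Kung's state-space method on a near-square Hankel matrix
  (ceil(N/2) rows; the aspect ratio is not specified in the literature,
  near-square is standard practice): truncated SVD to 32 components, poles
  from the shift-invariance of the left singular vectors, amplitudes by
  linear least squares (SVD pseudo-inverse, robust to coalescing poles).
  Components with poles inside 4.7 +/- 0.5 ppm are reconstructed and
  subtracted. Growing poles (|z| > 1) are kept for subtraction but flagged,
  with magnitudes clamped at 1.05 for numerical safety; a rejection option
  exists.
* **Low-rank denoising.** Casorati-matrix truncated SVD at rank K = 40
  (Eckart-Young optimal, verified against a full-SVD oracle).

## Evaluation metrics

Range-restricted NRMSE is reported in percent over the whole spectrum
(9.0-0.0 ppm), the metabolite range (4.2-1.9 ppm) and the lipid range
(1.9-0.7 ppm). The literature does not define the NRMSE denominator; this
package uses the L2 norm of the ground-truth metabolite spectrum over
4.2-1.9 ppm as one common denominator for all three ranges, so lipid-range
residuals are expressed relative to metabolite signal strength (the
per-range truth norm is available as an option). The suppression factor is
likewise implementation-defined here: the mean over mask voxels of the
ratio of in-range L2 magnitudes before/after processing (lipid range
1.9-0.7 ppm; water range 4.2-5.2 ppm, matching the HLSVD window). SNR and
FWHM proxies use the maximum real-part peak against a second-difference
detrended noise estimate from the signal-free 9.0-8.0 ppm range.

## Scaled experiments and problem sizes

The published model was trained on 1.9 million spectra for 400 epochs on
GPUs; this package is built to run end-to-end on a desktop CPU, so the
shipped presets are deliberately scaled down, as the package's own choice
of desk-scale study size:

* scaled simulation study: 3 000 training spectra from 3 synthetic
  subjects, 2 000 held-out evaluation spectra from a disjoint subject,
  base 8 channels, batch 16, 8 epochs at learning rate 3e-3 with the
  quartering compressed to every `ceil(epochs/4)` epochs and a global
  gradient-norm clip of 10 (the aggressive full-preset rate of 0.01 is
  stable at the publication's scale but diverges in short small-batch
  runs); the full preset -- 16 channels, 400 epochs, lr 0.01 quartered
  every 50 -- mirrors the publication and is available through the same
  configs;
* the test suite uses still smaller instances (tens to hundreds of
  spectra) chosen to exercise every code path quickly.

A scaled run of this size leaves the network visibly undertrained relative
to the published training volume (about four orders of magnitude fewer
example presentations): its validation loss is still decreasing when the
budget ends, and on synthetic evaluation sets the network does not yet
overtake the conventional HLSVD+L2 chain, whose subspace operator receives
the evaluation subject's lipid basis as side information. The comparative
numbers produced at desk scale therefore characterize the *scaled* model,
not the method at its published operating point.

Numerical conventions worth knowing: ppm intervals are closed on both ends;
index 1 of a spectrum is the highest ppm; voxels are stored row-major;
energy normalization floors its divisor at 1e-12 to handle the degenerate
`x1 == x2` case; singular values below 1e-8 (operator) / 1e-10 (Hankel) of
the largest are truncated; all stochastic components (sampling, init,
shuffling, dropout, augmentation) derive from a single user seed and
restore the caller's RNG state.

## Known limitations

* The nuisance generator is a stand-in for measured lipid/water signal;
  absolute NRMSE levels on synthetic data are not in vivo performance.
* Lactate's 1.3 ppm doublet overlaps the lipid range and can be attenuated
  together with lipids -- an intrinsic property of lipid-removal methods in
  this family, inherited by the network.
* Only 2D grids are implemented for the spatial phantom and volume
  containers (sufficient to exercise every algorithm; the spectral modules
  are dimension-agnostic).
* Non-Cartesian reconstruction, B0 correction, and spectral fitting
  (LCModel-style quantification) are out of scope; the package slots in
  between reconstruction and fitting in an MRSI pipeline.
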