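---
title: "Statistical wiring models of orientation maps: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical wiring models of orientation maps: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moiremap)
```

## The model

`moiremap` implements the random feedforward ("statistical") wiring model of
orientation preference maps in primary visual cortex.  Retinal ganglion
cells (RGCs) of ON and OFF polarity tile the retina in semi-regular
mosaics; a model V1 neuron at cortical position $y$ sums its afferents with
Gaussian weights,

$$ RF_y(x) \;=\; \sum_j \pm\, w_j(y)\,
   e^{-(x_j - x)^2 / 2\sigma_r^2}, \qquad
   w_j(y) = e^{-(x_j - y)^2 / 2\sigma_s^2} , $$

with the sign set by the polarity of cell $j$.  $\sigma_r$ (default 70 um)
is the width of a single RGC receptive field and $\sigma_s$ (default 20 um)
the afferent sampling range; for $\sigma_s$ well below the mosaic spacing a
neuron is dominated by one neighbouring ON/OFF pair (an *RGC dipole*) and
acquires a simple-cell receptive field tuned to the edge orientation
perpendicular to the dipole axis.  Responses are linear (no output
nonlinearity); preferred orientation, preferred spatial frequency and the
orientation selectivity index (OSI) are read off the receptive-field
amplitude spectrum exactly as one would from grating responses.  The map of
preferred orientations across $y$ is the model's orientation-domain layout,
represented throughout as the complex field $z = \mathrm{OSI}\,
e^{2i\vartheta}$.

For perfectly hexagonal ON/OFF mosaics with lattice constants $r, r'$ and
relative angle $\Delta\alpha$, the afferent sums have closed forms as
products of Jacobi theta functions, and the layout is a Moiré interference
pattern: its dominant modes share the wavenumber
$k_c = \tfrac{4\pi}{\sqrt3\, r r'}\sqrt{r^2 + r'^2 - 2 r r'\cos\Delta\alpha}$,
giving a column spacing $\Lambda_c = 2\pi/k_c = \tfrac{\sqrt3}{2} S r$ with
the classical Moiré scaling factor $S$.  At the standard parameters
($r = r' = 170$ um, $\Delta\alpha = 7^\circ$) $S \approx 8.2$ and
$\Lambda_c \approx 1.21$ mm.

```{r geometry}
p <- moire_params()
moire_geometry(p)
```

Three analytic layouts are available: the theta-function receptive fields
and spectra themselves (`analytic_rf()`, `analytic_spectrum()`), the
unfiltered orientation layout from the quadratic (Hessian) expansion of the
receptive-field power spectrum (`hessian_orientation_map()`), and the
low-frequency limit of the smoothed layout, a sum of six planar waves of
magnitude $k_c$ with fixed phase factors (`six_mode_map()`).  The six-mode
layout is a pinwheel crystal: one multiplicity-2 (charge $\pm1$) phase
singularity per superlattice cell, counted as two pinwheels, plus two
charge $\mp\tfrac12$ singularities, giving a pinwheel density of exactly
$2\sqrt3 \approx 3.46$ per $\Lambda_c^2$ and nearest-neighbour distances of
$\tfrac23\Lambda_c$.

## Orientation conventions

All containers store the *preferred edge orientation*
$\vartheta \in [0,\pi)$, which is perpendicular to the resultant preferred
grating wavevector.  The closed-form layouts apply the same convention (a
global $90^\circ$ rotation relative to the raw spectral-moment angle, i.e.
a sign flip of $z$), so maps from every stage can be compared directly.
Pinwheel charge is the winding of $\arg z$ around the singularity divided
by two and is convention-independent.

## The analysis pipeline

The statistics stage is applied identically to model layouts and to any
user-supplied complex map:

* **Spectra** (`amplitude_spectrum()`, `marginal_spectrum()`): modulus of
  the Fourier transform of $z = e^{2i\vartheta}$; the marginal spectrum is
  radially averaged and max-normalized.
* **Fermi band-pass** (`fermi_bandpass()`): product of two Fermi steps in
  wavelength (defaults 0.3 and 1.2 mm, steepness 5% of each cutoff), DC
  removed.
* **Column spacing** (`local_column_spacing()`): complex Morlet wavelets
  with carrier $k_\phi = 2\pi/\Lambda$ and envelope
  $\sigma = \xi\Lambda/2\pi$ ($\xi = 7$), averaged over 16 orientations in
  $[0,\pi)$; the local spacing is the scale with the largest
  orientation-averaged coefficient modulus, over 24 log-spaced scales
  spanning $[\Lambda_{exp}/3,\, 3\Lambda_{exp}]$ by default.  Coefficients
  are evaluated in the Fourier domain; the `coarse` mode inverse-transforms
  only the spectral neighbourhood of the carrier, which is exact for the
  coefficient modulus on a reduced spatial grid and makes parameter sweeps
  cheap.  The estimator's accuracy is limited by the scale-grid
  quantization plus a $\approx 1/\xi^2$ large-scale bias from the
  $1/\sigma$ wavelet normalization; plane-wave inputs are recovered to a
  few percent.
* **Pinwheels** (`find_pinwheels()`): candidate singularities from the
  discrete winding number on small grid loops; sub-pixel positions by
  Newton iteration on the bilinear interpolant, with a quadratic
  $|z|$-surface fit for multiplicity-2 zeros (where Newton converges only
  linearly); charges from the winding on a 2-pixel sampling circle.
  Detections closer than 0.6 px are merged.  Two nearby singularities of
  opposite sign that fall inside the same sampling circle cancel and are
  dropped, so pair separations below roughly two pixels are unresolved --
  the same resolution limit any finite-grid analysis has.
* **Layout statistics**: density per $\Lambda^2$ with weight $2|q|$
  (degenerate $\pm1$ pinwheels count twice), nearest-neighbour distance
  distributions by charge class (bins of $0.05\Lambda$ up to $1.5\Lambda$),
  and the density-variability power law $SD(A) = c\rho A^{-\gamma}$ fitted
  by least squares on log-log axes over 12 areas in $[1, 64]\,\Lambda^2$
  (100 circular subregions per area, seeded).  A Poisson pattern gives
  $\gamma = \tfrac12$, $c = 1/\sqrt\rho$; the pinwheel crystal gives
  $\gamma = \tfrac34$.
* **Benchmark** (`assess_consistency()`): the six layout parameters are
  scored against embedded reference intervals (closed at the endpoints):
  the common-design range (pooled bootstrap CI) nested inside the
  one-species range (union of single-species CIs).

## Synthetic mosaics: what they emulate

`hexagonal_mosaic()` plus `apply_uncorrelated_jitter()` reproduce the
classical noisy-lattice ensemble (per-cell Gaussian offsets of SD
$\eta r$, independent between ON and OFF lattices).
`apply_correlated_jitter()` displaces cells by a sampled Gaussian random
field (`sample_displacement_field()`) with unit component variance and
Gaussian autocorrelation of length $\sigma_{corr}$ (in lattice constants),
independently for ON and OFF; its Jacobian determinant maps local mosaic
compression/dilation.  `pipp_mosaic()` generates regularly-spaced mosaics
with a pairwise-interaction point process: hard exclusion $\delta$ and soft
interaction $h(d) = 1 - e^{-((d-\delta)/\phi)^\alpha}$, simulated by
Metropolis single-cell moves at fixed cell number.  The published
parameterizations of this process are fits to specific data sets that are
not reproduced here; the package defaults ($\delta = 30$ um, $\phi = 80$
um, $\alpha = 3$, 40 cells/mm$^2$ per polarity -- the same density as the
$r = 170$ um lattices) were chosen once to give regularity indices around
4, typical of measured RGC mosaics, and are exposed as arguments.

None of these generators models LGN-stage transformations, cross-polarity
interactions, retinal eccentricity gradients, or measurement noise of
imaging experiments; passing tests therefore validate the model pipeline,
not the realism of any particular retina.

## Numerical choices

* **Theta functions** are summed directly with a truncation bound that
  accounts for complex arguments; doubling the truncation changes results
  by $<10^{-12}$ over the nome range used.  All closed forms are validated
  against brute-force lattice sums to $10^{-8}$ relative error -- this
  oracle also fixed the sign/prefactor ambiguities in the published
  auxiliary expressions.
* **Map resolution.**  Pipeline drivers default to 48 px per $\Lambda_c$.
  At 32 px/$\Lambda$ the OSI-thresholded layout degenerates into
  single-pixel spikes whose broadband shot noise biases the wavelet
  spacing estimate upward by tens of percent; between 48 and 64
  px/$\Lambda$ measured densities agree within 3%.  Crystalline-layout
  densities are resolution-stable to $<1\%$ from 32 to 128 px/$\Lambda$.
* **Smoothing width.**  The Gaussian kernel applied after OSI thresholding
  is not uniquely determined by the literature; the pipeline default is
  $0.15\Lambda_c$, about the smallest width at which the smoothed
  layout's spectrum is dominated by the six $k_c$ modes.  The correlation
  between the smoothed numerical layout and the six-mode field is
  non-monotone in this width (peaking near $0.12\Lambda$) and stays above
  0.75 for any six-mode-dominated choice, while the *unfiltered* layout
  correlates about 0.6 with the six-mode field.
* **Counting windows.**  Densities of crystalline layouts are measured
  over an exact integer number of superlattice cells (grid axes aligned
  with a superlattice vector, `sixmode_layout_density()`); for disordered
  layouts a $0.5\Lambda$ boundary strip is excluded before counting.
* **Column-spacing normalization.**  Disordered and broadband layouts are
  normalized by the wavelet-measured mean spacing, crystalline layouts by
  $\Lambda_c$.  For the GRF filter family the spacing is fixed by the
  filter normalization ($\int d^2k\, f = 2\pi$ and power-weighted mean
  wavenumber 1, with $b = [\Gamma((\beta+2)/2)/\Gamma((\beta+3)/2)]^2$ in
  closed form); the measured GRF densities agree with the independent
  zero-density prediction $\pi\langle k^2\rangle/\bar k^2$ for this
  normalization, which declines from 4 at $\beta = 0$ towards $\pi$ and
  crosses the one-species bound around $\beta \approx 5$.  Normalizing by a
  wavelet-measured spacing instead shifts this crossing to much larger
  $\beta$; both modes are available (`lambda_mode` in
  `grf_density_surface()`), the filter-defined one being the default.
* **Degenerate inputs.**  Pixels whose receptive field vanishes
  identically (e.g. when the only afferents are a coincident ON/OFF pair)
  carry `NA` orientation and are treated as untuned downstream; $\eta = 0$
  jitter and zero smoothing width are exact identities; filters reject
  cutoffs outside the grid's resolvable band.

## Quasi-periodicity of the unfiltered layout

Only the low-frequency (six-mode) layout is exactly periodic under the
Moiré superlattice.  The unfiltered layout's fine parcellation lives on the
two RGC lattice scales, which are incommensurate with the superlattice at
generic $\Delta\alpha$; a superlattice translation changes unfiltered
orientations by tens of degrees at typical positions.  Tests therefore
assert exact periodicity for the six-mode field only.

## Problem sizes

Default test and acceptance runs use: $4\Lambda$ windows at 64
px/$\Lambda$ for the analytic-vs-numerical comparisons; $6\times4$
superlattice cells at 96 px/$\Lambda$ for crystalline counts; $30\times30$
cells for the crystalline $SD(A)$ fit; 20 realizations of $512^2$ GRFs
($22\Lambda$ across) per filter exponent; and $10\Lambda$ windows at 48
px/$\Lambda$ with 5 realizations per grid point for the correlated-disorder
sweep.  These sizes were chosen so that the Monte-Carlo error of every
stochastic quantity is small against the tolerance of the check that
consumes it.

## Known limitations

* The pinwheel detector's close-pair resolution (~2 px) slightly
  undercounts broadband (GRF/PIPP) layouts relative to an infinite-
  resolution analysis; crystalline and weakly disordered layouts are
  unaffected.
* The PIPP sampler is a straightforward Metropolis implementation intended
  for windows of a few mm; it is not optimized for very dense mosaics.
* The wavelet spacing estimator inherits the classical method's
  large-scale bias ($\approx 2\%$ for $\xi = 7$) and scale-grid
  quantization; sweep-level conclusions are insensitive to this, but
  absolute spacings carry that uncertainty.
* Retino-cortical magnification is a global scalar (default 1 mm/mm);
  spatially varying magnification is outside scope.
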