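---
title: "Simulating x-ray dark-field lung radiography with a random-sphere phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating x-ray dark-field lung radiography with a random-sphere phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkfieldsim)
```

## The physical model

Grating (Talbot) interferometry measures, besides attenuation and
differential phase, a *dark-field* signal: the loss of visibility of the
interferometer's self-image fringe caused by small-angle scattering from
structure well below the detector pixel size. For lungs that structure is
the air–tissue interface network of the alveoli, which makes dark-field
radiography a sensitive probe of alveolar integrity.

`darkfieldsim` implements the full monochromatic wave-optics chain of such
a measurement:

1. **Phantom.** A lung slab of thickness $t$ is modelled as muscle tissue
   containing randomly placed, overlapping air spheres of a single diameter
   $S$ and nominal volume fraction $f = 0.56$ (slightly below random close
   packing, 0.64). Spheres have zero wall thickness. The slab is projected
   along the beam into per-ray air path lengths (see *Projection semantics*
   below).
2. **Object and G1.** A unit plane wave acquires the complex transmission
   $O(x,y) = \exp\!\big(i\tfrac{2\pi}{\lambda}\!\int\!\delta\,dz -
   \tfrac{2\pi}{\lambda}\!\int\!\beta\,dz\big)$ of the projected slab, then
   the binary $\pi$-shift phase grating G1 (pitch $p_1 = 2 p_2$, duty 0.5).
3. **Propagation.** Angular-spectrum (Fresnel) propagation over the
   fractional Talbot distance $d = m\,p_2^2/(2\lambda)$ (odd order $m$),
   where the grating self-image forms a fringe of period $p_2$.
   An optional Gaussian source-aperture blur can be applied to the complex
   amplitude.
4. **Detection.** The analyzer grating G2 (pitch $p_2$) masks the intensity
   at each of $N$ uniform step positions over one period; the fine-grid
   intensity is binned into detector pixels, exposure-scaled, optionally
   blurred with a measured MTF / Gaussian focal spot, and optionally noised
   with an NPS-shaped, Poisson-scaled noise field.
5. **Retrieval.** Per pixel, discrete Fourier analysis of intensity versus
   step gives mean $a_0$, first-harmonic amplitude $a_1$, visibility
   $v = 2a_1/a_0$ and fringe phase. Relative to a no-object reference
   acquisition this yields transmission $T = a_0^{obj}/a_0^{ref}$,
   dark field $df = v^{obj}/v^{ref}$ and differential phase.

The material dark-field response is summarized by the **linear diffusion
coefficient** $\epsilon$ through

$$-\log(df) \;=\; \frac{2\pi^2 d^2}{p_2^2}\,\epsilon\, t ,$$

fitted over a series of slab thicknesses by least squares through the
origin (the law forces $-\log df = 0$ at $t = 0$), inverse-variance
weighted when repetitions are available; a free-intercept fit is kept as a
diagnostic. `fit_epsilon()` returns a classed object with `coef`,
`summary`, `confint`, `predict` and `plot` methods.

The setup's structural sensitivity scale is the autocorrelation length
$d_{auto} = \lambda d/p_2$, which equals $m\,p_2/2 \approx 1\,\mu$m for
both presets — far below all alveolar diameters considered, so $\epsilon$
decreases with increasing $S$.

## Presets

Two presets reproduce the murine and human lung study conditions:

| | murine | human |
|---|---|---|
| alveolar diameters $S$ | 39 / 60 / 80 um | 200 / 300 / 400 um |
| slab thicknesses | 1.8 – 10.8 mm (6 steps) | 25 – 150 mm (6 steps) |
| pixel pitch | 100 um | 150 um |
| design energy | 27.7 keV | 64.5 keV |
| $d$ (first Talbot) | 4.47 cm | 10.4 cm |
| field of view | 5 x 5 px | 10 x 10 px |
| repetitions | 10 | 10 |

with tabulated $\delta, \beta$ for air and muscle tissue at each energy.
These counts give on average 325/89/38 spheres per 100-um pixel per 1.8 mm
of murine lung and 75/22/9 spheres per 150-um pixel per 25 mm of human
lung. The smallest murine diameter is variously reported as 39 or 40 um;
the preset uses 39.

## Design choices

**Projection semantics.** Overlapping spheres can be projected in two
ways. The geometric *union* of the chord intervals (interval merge, no
double counting) is available and is validated against a voxel z-marching
oracle in the tests. The presets however use the *sum* of the individual
clipped chords. The reason is statistical: with summed chords an
overlapping pack projects exactly like a non-overlapping pack of the same
nominal volume fraction (the justification for allowing overlap in the
first place), whereas union merging systematically erases interface
structure at high packing fraction — at $f = 0.56$ the union air fraction
is only $1 - e^{-0.56} \approx 0.43$ and the fitted $\epsilon$ drops by
about a factor two. The sum semantics reproduces the murine reference
values; both modes are exposed via the `overlap` argument.

**G1 pitch in a plane-wave model.** A physical Talbot–Lau bench with a
diverging beam uses a G1 pitch slightly below $2 p_2$ (e.g. 3.901 um for
$p_2 = 2.000$ um) because beam magnification stretches the self-image onto
the analyzer. In a plane-wave simulation there is no magnification: using
the physical pitch directly produces a 1.95-um fringe sampled by a 2.00-um
analyzer, i.e. a 79-um moiré beat across the field. The retrieved
visibility then hinges on a pixel-window leakage term that shrinks with
pixel size and does not converge with sampling. The geometry therefore
defaults to the design ratio $p_1 = 2p_2$, which is the plane-wave
equivalent of the magnified bench; the physical pitch remains available as
an argument.

**Fine sampling.** The transverse grid spacing is $p_2/\texttt{fine\_sampling}$.
Phase structure at the sphere edges (a square-root singularity of the
projected chord) converges slowly, so the default is 16 samples per $p_2$
period (0.125 um); values below 8 are refused. A murine convergence check
(same phantom, 8/12/16/24 samples per period) moves the fitted $\epsilon$
by under 10% between 12 and 24; the human presets are converged already at
8 samples per period because their per-edge phase steps are smaller
relative to the total per-sphere phase.

**Grid layout and boundaries.** The propagation grid covers the field of
view plus a guard band of 32 $p_2$ periods per side, padded to an
FFT-friendly size; boundaries are periodic. The phantom's lateral extent
exceeds the whole grid by one sphere diameter per side, so no object edge
exists anywhere on the grid and wrap-around artifacts are limited to the
~1–4 um diffraction displacement, far inside the guard band. The phantom
is regenerated per repetition with seed `base_seed + repetition - 1`.

**Reference acquisition.** Without an object the field is uniform along
$y$; the reference stack is computed on a single $y$-line and broadcast,
which is exact and keeps the reference cost negligible. Since G2 is applied
after propagation, one propagated field serves all step positions.

**Detector defaults.** The detector is ideal by default (MTF $\equiv$ 1,
flat NPS, noise off, focal spot 0): the study conditions use an exposure of
$10^3$ mGy precisely so that noise is negligible, and the dark-field
*ratio* is insensitive to the absolute exposure calibration. Measured MTF
and NPS curves (two-column text, cycles/mm) are opt-in. The noise model
filters a unit normal field by the square root of the NPS — the verbal
description of the noise construction, which we follow rather than the
symbolic form that omits the square root — rescales it to unit empirical
variance and scales pointwise by $\sqrt{I}$ (Poisson magnitude).

**Numerical details.** Visibility is defined as twice the first stepping
harmonic over the mean; for a pure sinusoid the discrete retrieval is exact
for any $N \ge 3$ (default $N = 8$). Differential phase is wrapped to
$(-\pi, \pi]$ and not unwrapped. Dark-field values marginally above 1 are
kept so that field-of-view averages stay unbiased. Grating edges are
classified after snapping the phase to $10^{-9}$ of a period so that
whole-period shifts are exact identities. The chord projection is exact
(analytic chords; for union semantics an interval merge per ray processed
in centre-z order), implemented in C++; a voxel oracle exists only in the
tests.

## What the generator does and does not emulate

The phantom captures the alveolar length scale, volume fraction and the
air–tissue refractive contrast — the drivers of the dark-field signal. It
does **not** model polydisperse or non-spherical alveoli, alveolar walls,
ribs, skin, fur, scatter, beam polychromaticity (beam hardening shifts the
effective energy away from the design energy), cone-beam magnification or
grating imperfections. Passing tests therefore demonstrate the fidelity of
the wave chain and estimator for this idealized phantom, not agreement
with any particular animal or patient measurement.

## Reduced problem sizes

Full study conditions (5x5 or 10x10 pixel fields of view, 10 repetitions)
are expensive. The package's reduced profile — `scale_configuration()`:
2x2 pixels, 12–16 samples per period, 3 repetitions — changes only the
stochastic precision of the estimates, not the estimand, and is what the
test suite and the acceptance script use. A murine 60-um series at the
reduced profile completes in about three minutes on one CPU and fits
$\epsilon$ with $r^2 > 0.999$.

## Known limitations

* The murine arm of the study reproduces well at the reduced profile
  (fitted $\epsilon$ within ~5% of the reference value, dark field at
  maximum thickness ~0.27). The human arm does not: this implementation —
  cross-checked against an independent statistical-optics model of the
  same phase screen and converged in sampling — yields a human
  $\epsilon$ about 2.6 times the reported value, and correspondingly a
  murine/human ratio of ~45 rather than ~120. Our values follow the
  theoretical scaling $\epsilon \propto (\Delta\delta)^2/S$ across both
  presets; no wave-optics mechanism we tested (union projection, face
  clipping, sampling, moiré of the physical G1 pitch, alternative
  inter-grating distances) moves one preset without the other. The
  package reports what the model computes.
* The projection approximation treats the whole slab as a single phase
  screen at the G1 plane; for the human 150-mm slab, intra-slab
  diffraction at micrometre scales is not strictly negligible.
* Only monochromatic plane-wave illumination is modelled.
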