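# darkfieldsim

Wave-optics simulation of grating-interferometry x-ray **dark-field (DF)
lung radiography** with a random-sphere alveolar phantom, and estimation of
the lung tissue **linear diffusion coefficient** from simulated thickness
series.

## The problem

X-ray dark-field imaging visualizes small-angle scattering from structure
far below the pixel size — in lungs, the millions of air–tissue interfaces
of the alveoli. It is well established in mice; whether it translates to
humans is not obvious, because human alveoli (200–400 µm) are about five
times larger than murine ones (39–80 µm) while the human thorax is an order
of magnitude thicker. This package provides the simulation machinery to
study that translation quantitatively: a Talbot interferometer is modelled
end to end (object transmission, π-shift phase grating G1, Fresnel
propagation to the analyzer G2, phase stepping, pixel binning, detector
blur and noise, Fourier retrieval), a lung slab is modelled as muscle
tissue filled with overlapping air spheres, and the dark-field signal

    df = v_obj / v_ref          (visibility ratio, per pixel)

is related to slab thickness t through the diffusion law

    -log(df) = (2 π² d² / p2²) · ε · t

whose slope yields the material linear diffusion coefficient ε (in 1/mm)
for a given sphere diameter. Presets reproduce a murine imaging geometry
(27.7 keV, 100 µm pixels, d = 4.47 cm) and a hypothetical clinical chest
geometry (64.5 keV, 150 µm pixels, d = 10.4 cm).

Intended users: imaging physicists exploring grating-interferometer designs
and anyone needing a reproducible, tested reference implementation of the
phase-stepping dark-field simulation chain.

## Worked example

A desk-scale murine run (2×2-pixel field of view, 12 fine samples per
fringe period, 3 phantom repetitions, three of the six standard
thicknesses):

```r
library(darkfieldsim)
cfg <- scale_configuration(load_preset("murine"))   # S = 60 um default
cfg$phantom$thicknesses <- c(1.8e-3, 5.4e-3, 10.8e-3)
series <- run_thickness_series(cfg, base_seed = 1)
print(series)
#> Dark-field thickness series (murine, S = 60 um, 3 repetitions)
#>  thickness_mm mean_df   sd_df
#>           1.8  0.7788 0.00344
#>           5.4  0.4996 0.01620
#>          10.8  0.2706 0.03080
summary(fit_epsilon(series))
#> Linear diffusion coefficient fit (zero-intercept weighted LS)
#>   epsilon      = 1.343e-11 1/mm  (se 5.4e-13; 95% CI 1.109e-11 .. 1.577e-11)
#>   r^2          = 0.99673
#>   slope factor = 9.853e+09 (2*pi^2*d^2/p2^2)
#>   free-intercept diagnostic: intercept 0.0352, epsilon 1.213e-11 1/mm
```

The dark field decays from 0.78 at 1.8 mm of lung to 0.27 at 10.8 mm, and
the fitted ε ≈ 1.3·10⁻¹¹ mm⁻¹ characterizes murine lung at this geometry.
Single ROI measurements invert the same law: a dark field of 0.44 over
5.7 mm of lung gives

```r
epsilon_from_roi(0.44, 5.7e-3, cfg$geometry)
#> [1] 1.461845e-11
```

`fit_epsilon()` returns a classed model object with `coef`, `confint`,
`predict`, `plot` and `residuals` methods. A command-line front end with
`simulate` / `series` / `compare` / `validate` subcommands is installed at
`inst/cli/dfsim.R`.

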