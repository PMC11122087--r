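# spectralct

One-step material decomposition for multispectral (photon-counting) CT in R.

Conventional CT inverts the linear Radon transform; multispectral CT measures
each line integral through `B` energy bins of a polychromatic beam and asks
for the density maps of `M` base materials directly. That turns reconstruction
into a nonlinear inverse problem: the discrete forward model is

    F(X) = exp(-A X Mᵀ) Sᵀ,        H(X) = log(F(X) ⊘ F(0)),

where `X` (`Nx × M`) holds the material images, `A` is the discrete Radon
transform applied per channel, `M` (`E × M`) the tabulated attenuation curves,
`S` (`B × E`) the effective spectra, and `H` the recalibrated log-domain model.
Reconstruction minimizes `D(X) = ½‖H(X) − Y_H‖²` over nonnegative images.

The package is built around the factorization `H(X) = Φ(AX)` into a linear
spatial part and a per-ray nonlinear channel mixing `Φ`, and provides:

* a sparse parallel-beam Radon projector with an **exactly matched adjoint**
  (the transpose of the assembled intersection-length matrix);
* the full derivative calculus: `H'[X]`, its adjoint, `∇D`, the channel
  derivative `Φ'[Z]` and its adjoint, and the zero-linearization matrix
  `U[b,m] = ⟨S_b, M_m⟩ / ⟨S_b, 1⟩` of spectrum-weighted mean attenuations;
* four solvers on the common preconditioned fixed-point iteration with
  positivity projection: nonlinear **Landweber**, a small-scale
  **Gauss–Newton** oracle, **CP-full** (Gauss–Newton in the channel dimension
  only — `Ny` independent `M × M` solves per step, linear in `Ny`), and the
  derivative-free **CP-fast** (channel preconditioning by the pseudoinverse
  `U‡`, computed once);
* a synthetic workbench: parametric phantoms, filtered tube spectra with
  K-edge contrast materials, Poisson noise at a configurable photon budget,
  and inverse-crime avoidance via a finer data energy grid;
* a simulate → recalibrate → reconstruct → evaluate pipeline with YAML
  configuration, CSV outputs, broom-style `tidy()`/`glance()` and ggplot2
  `autoplot()` methods, and a thin CLI (`inst/cli/spectralct`).

For the model, the step-size rule, the sign analysis of the derivative-free
update, and the generator's design, see the methods vignette in
`vignettes/channel-preconditioned-msct.Rmd`.

## A worked example

```r
library(spectralct)

n <- 64
geometry  <- ct_geometry(n, pixel_size = 1 / n)     # 101 angles x 96 bins
projector <- build_projector(geometry)
model     <- make_spectral_model(M = 3, B = 5, E = 20, seed = 1)
truth     <- make_phantom(default_phantom_spec(n))

Y   <- simulate_data(truth, model, projector,
                     acquisition_spec(I0 = 1e6, E_data = 40), seed = 11)
Y_H <- log_rescale_data(model, Y)

fit <- run_solver(model, projector, Y_H,
                  solver_config("cp_fast", max_iterations = 500,
                                stop_tolerance = 0),
                  truth = truth)
fit
#> <ct_recon> cp_fast: 500 iteration(s), omega = 0.6561, final objective 0.99017
#>   best iterate: 473 (relative error 0.05007)

relative_error(fit$X_best, truth, per_material = TRUE)
#> material_1 material_2 material_3
#>     0.0502     0.0591     0.0313
```

The printed numbers say: with the automatic step size `ω = 0.656`
(one over a power-iteration estimate of the linearized normal operator's
norm), the derivative-free iteration brings the relative ℓ2 reconstruction
error `‖X_k − X★‖/‖X★‖` down to 5.0% at its best iterate (number 473) under
Poisson noise of 10⁶ expected counts per ray and bin; the per-material split
shows the contrast channels (iodine-like 5.9%, gadolinium-like 3.1%)
alongside water. `autoplot(fit)` plots the objective and error histories;
`plot_material_image(fit$X_best, n)` renders the three density maps. The same
run is reproduced by `run_reconstruct(default_run_config(n = 64, E = 20))`.

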