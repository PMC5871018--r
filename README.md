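# imbalnet

Simulation and mean-field analysis of **imbalanced amplification** in
strongly coupled cortical network models.

Cortical neurons receive far more feedforward excitation than their
firing rates would suggest; in balanced-network models this excitation
is cancelled, on average, by net-inhibitory recurrent input. The
cancellation has an arithmetic: writing the mean input to each
population as

```
I = (1/eps) * (W r + X),        eps = 1 / (K_EX * J_EX),
```

with `W` the dimensionless recurrent connectivity (`w_ab = K_ab J_ab /
(K_EX J_EX)`), `X` the rescaled external drive and `eps` small, bounded
currents require `W r + X = 0`, giving the balanced rates `r =
-solve(W, X)`. When `W` is singular — as it is whenever an optogenetic
stimulus targets only a fraction `q` of the excitatory neurons, because
local connectivity cannot distinguish expressing from non-expressing
cells — no such solution exists. The component of the drive in the
nullspace of `t(W)` cannot be cancelled, and the rectified-linear
correction `r = solve(eps*D - W, X)` (with `D = diag(1/g)` built from
the fitted f-I gain `g`) shows the rates acquire an amplified component
`r0/eps` lying in the nullspace of `W`:

```
r0 = (v2.X / v2.D.v0) * v0  =  g s [1-q, -q, 0]
```

so stimulating *fewer* neurons amplifies the response of the targeted
cells while suppressing the others. The same mechanism, carried to
continuously indexed networks with wrapped-Gaussian connectivity over
space and orientation (solved mode-by-mode in the Fourier domain),
produces surround suppression, non-monotonic size tuning, and the
sharpening ("deconvolution") of blurred feedforward input.

The package is aimed at computational neuroscientists who want to
compute every one of these predictions — and check them against direct
simulation of the underlying spiking network (adaptive exponential
integrate-and-fire neurons, current-based exponential synapses, Poisson
external drive; compiled forward-Euler core) — at desk scale.

## Worked example

Partial stimulation of 20% of the excitatory population, at the
reference parameter set:

```r
library(imbalnet)
cp <- coupling_table(); sz <- population_sizes()   # q = 0.2
compute_epsilon(cp, sz)
#> [1] 0.002659574

mf <- build_meanfield(cp, sz, "expressing")
X  <- external_drive(mf, r_X = 5, S = 2)           # stimulus in mV/ms
corrected_rates(mf$W, X, mf$epsilon, gain = 15)
#> Rate solution (corrected)
#>     exp    nexp       I
#> 32.1581  2.1581  9.1061
#> balance residual 5.938e+00
```

Without stimulation all excitatory neurons sit near 5.9 Hz; during
stimulation the expressing 20% jump to ~32 Hz while the non-expressing
majority are *suppressed* to ~2.2 Hz — the classical balanced solution
does not even exist here (`balanced_rates` raises an informative error
because `W` is singular). A full spiking simulation of the same
protocol reproduces these numbers within a few percent:

```r
fig2 <- run_figure(2, scale = 1, seed = 1, duration = 5000)
fig2$summary[, c("population", "rate_pre", "rate_stim")]
#>      population rate_pre rate_stim
#> exp         exp     5.97     32.04
#> nexp       nexp     5.86      2.72
#> I             I     6.71      9.05
```

and `fig2$gain_fit` supplies the rectified-linear gain (g ≈ 15.8
Hz/(mV/ms)) that closes the loop between simulation and theory.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the
printed unitary postsynaptic-potential amplitudes of the weakest and
strongest connections (closed-form double-exponential peak,
cross-checked against a 0.001 ms-step membrane integration) and writes
them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/imbalnet.R`:

```sh
Rscript inst/cli/imbalnet.R meanfield --partition expressing --gain 15
Rscript inst/cli/imbalnet.R size-tuning --variant disc --alpha-e 0.02
Rscript inst/cli/imbalnet.R run-figure --figure 1 --scale 0.2 --duration 2000 --out out/
```

See the methods vignette (`vignettes/imbalanced-amplification.Rmd`) for
the model equations, parameter conventions, numerical choices and known
limitations.
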