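# amariepr

Entropy production and irreversibility diagnostics for the stochastic,
linearized Amari neural field model.

## The problem

Coarse-grained neural field models describe the average activity `u(x, t)` of
large neuronal populations with an integro-differential equation

    du/dt = -u/tau + (1/tau) * Int w(x, y) f[u(y, t)] dy + xi(x, t)

where `tau` is a relaxation time, `w(x, y)` the synaptic coupling kernel,
`f[u] = 1 / (exp(beta (u* - u)) + 1)` a sigmoid firing-rate nonlinearity, and
`xi` an additive Gaussian forcing, white in time with spatial covariance
`gamma(x, y)`. Brain dynamics are empirically irreversible, and the canonical
model-based measure of irreversibility is the **entropy production rate**
`sigma`: the long-time rate of the log-ratio of forward to backward path
probabilities, zero exactly at thermal equilibrium (detailed balance).

`amariepr` linearizes the field around its homogeneous fixed point `u0`
(solving `f[u0] = u0 / w_tilde`), yielding a linear Langevin equation
`deta/dt = Lambda eta + xi` for the fluctuations, with drift kernel
`lambda(x, y) = -delta(x - y)/tau + f'(u0) w(x, y)/tau`, and computes `sigma`
by three mutually validating routes:

1. **Trace formula** (`entropy_production_trace`): with `C` the stationary
   covariance solving the Lyapunov equation `Lambda C + C Lambda' = -Gamma`,

       sigma = Tr[(Lambda' Gamma^-1 - Gamma^-1 Lambda) Lambda C]

2. **Path estimator** (`lebowitz_spohn_estimate`): the trajectory functional
   `Sigma(t) = log P[forward] / P[backward]`, evaluated on Euler-Maruyama
   trajectories through the Onsager-Machlup action, equivalently the
   Stratonovich (midpoint) sum
   `2 * sum_n (Delta eta_n)' Gamma^-1 Lambda etabar_n`; `sigma_hat =
   Sigma(t)/t` with block-bootstrap errors.

3. **Spectral closed form** (`spectral_entropy_production`): for
   translation-invariant kernels the dynamics decouple into Fourier modes
   with eigenvalues `lambda_k = (-1 + f'(u0) w_k)/tau` and

       sigma = sum_k sigma_k,   sigma_k = -Im^2(lambda_k) / Re(lambda_k)

   — nonzero only for complex `lambda_k`, i.e. only when the coupling kernel
   is asymmetric, and independent of the noise spectrum `gamma_k`.

The package also provides the detailed-balance criterion
(`equilibrium_check`: symmetry of `h = Lambda Gamma`, equivalently
`Lambda Gamma = Gamma Lambda'`), the Shannon/reservoir entropy-rate
decomposition for the stationary Gaussian state
(`shannon_entropy_rate_decomposition`, `reservoir_entropy_rate_mc`),
parametric kernel/noise generators (`kernel_spec`, `noise_spec`), and a
JSON-configured pipeline (`run_pipeline`, with a thin CLI at
`inst/cli/amari-epr.R`).

## Worked example

An asymmetric (shifted-Gaussian) coupling on a ring of 32 sites with
spatially white noise:

```r
library(amariepr)
grid  <- discrete_grid(32)                      # ring of 32 sites, L = 2*pi
act   <- sigmoid(beta = 2, u_star = 0.5)
kern  <- kernel_spec("shifted_gaussian", width = 0.5,
                     shift = grid$length / 8, normalization = 1)
model <- build_model(grid, tau = 1, act, kern)
noise <- build_noise(noise_spec("white", amplitude = 1), grid)
model
#> Linearized stochastic neural field model
#>   grid: 32 points, L = 6.28319; tau = 1
#>   w_tilde = 1, u0 = 0.5, f'(u0) = 0.5
#>   drift spectrum: Re in [-1.11478, -0.5], max |Im| = 0.31201

entropy_production_trace(model$drift_matrix, noise$covariance)
#> [1] 0.4911131

spec <- spectral_entropy_production(model, noise)
subset(spec$modes, m >= 0 & m <= 3)
#>    m k                   w_k              lambda_k gamma_k    sigma_k
#> 17 0 0  1.0000000+0.0000000i -0.5000000+0.0000000i       1 0.00000000
#> 18 1 1  0.6240195-0.6240195i -0.6879902-0.3120098i       1 0.14149925
#> 19 2 2  0.0000000-0.6065307i -1.0000000-0.3032653i       1 0.09196986
#> 20 3 3 -0.2295640-0.2295640i -1.1147820-0.1147820i       1 0.01181837

traj <- simulate_field(model, noise,
                       simulation_config(dt = 2e-3, n_steps = 5e5,
                                         burn_in = 5000, seed = 42))
lebowitz_spohn_estimate(traj, model$drift_matrix, noise$covariance)
#> Path entropy production: sigma_hat = 0.468005 +/- 0.0584 (t = 989.998, 49 blocks)
#>   Onsager-Machlup identity gap: 4.09e-12

equilibrium_check(model$drift_matrix, noise$covariance)
#> Detailed-balance check: asymmetry 0.227 -> NON-equilibrium (sigma = 0.491113)
```

The three routes agree: the analytic rate 0.4911 nats per unit time, its
per-mode decomposition summing to the same value (here concentrated in the
low-`|k|` travelling modes induced by the kernel shift), and the trajectory
estimate covering it within one standard error. Replacing the kernel by its
unshifted (even) version drives all three to zero: with spatially white
noise, a symmetric synaptic kernel is in detailed balance, and all
irreversibility originates from coupling asymmetry — never from the spatial
correlations of the noise.

Shipped demo configurations
(`system.file("extdata", "config-equilibrium.json", package = "amariepr")`
and `config-asymmetric.json`) run both branches end to end via
`run_pipeline()`.

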