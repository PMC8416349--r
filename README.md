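# narxgait

Continuous, simultaneous prediction of **future ankle angle and ankle
moment** from surface EMG with a single multiple-input multiple-output
feedforward (open-loop) NARX network, across level walking (LW), stair
ascent (AS) and stair descent (DS), including terrain transitions.

Active powered ankle-foot prostheses must commit to an actuation roughly
50 ms before the mechanical event it serves; muscle activity leads limb
mechanics, so the linear envelopes of the two antagonist lower-leg muscles
(tibialis anterior — dorsiflexor; gastrocnemius medialis — plantarflexor)
carry the information needed to predict ahead. The package is aimed at
researchers in myoelectric control and neuromechanical modelling who want
the full method — signal conditioning, network, training protocol,
hyperparameter characterization, evaluation statistics — as inspectable,
tested R code, exercised end-to-end on a bundled synthetic gait generator.

## The model

With sample period Δt = 1/120 s, prediction interval τ = mΔt and sampling
window D = dΔt, hidden units n = 1..N and outputs j ∈ {angle, moment}:

    v_n(t+m)  = tanh( Σ_{q=0..d} Σ_{i=1,2} a_ni(q) x_i(t−q)
                      − Σ_{q=1..d} Σ_{j=1,2} c_nj(q) y_j(t−q) + b1_n )
    ŷ_j(t+m)  = Σ_n w_jn v_n(t+m) + b2_j

where x_i are the EMG linear envelopes and y_j the *measured* past targets
(open loop). Networks are trained by full-batch Levenberg–Marquardt on
min–max-normalized channels, with a trial-blocked protocol: per fold and
condition, 8 whole trials train, 2 validate, and 1 held-back novel trial is
scored; 10 restarts per fold, best selected by MSE averaged across
conditions. Hyperparameters (τ, D, N) are characterized on a grid, the
optimal (D, N) is picked at a fixed τ = 58 ms (7 steps), and the final
network is re-trained at a zero error goal.

## Worked example

```r
library(narxgait)

pl <- run_pipeline(seed = 42)   # generate -> preprocess -> sweep (D, N) at
                                # tau = 58 ms -> finalize -> evaluate; ~4 min
pl$settings[c("D_ms", "N")]
#> $D_ms
#> [1] 83
#>
#> $N
#> [1] 12

print(pl$report$summary[, 1:7], digits = 4)
#>   condition output rmse_mean  rmse_sd r2_mean     r2_sd lag_mode
#> 1        AS  angle   0.56618 0.056627  0.9957 0.0002836        0
#> 2        DS  angle   0.56053 0.042607  0.9961 0.0005861        0
#> 3        LW  angle   0.67715 0.030257  0.9919 0.0002884        0
#> 4        AS moment   0.02115 0.002315  0.9980 0.0004839        0
#> 5        DS moment   0.02310 0.004169  0.9975 0.0006910        0
#> 6        LW moment   0.02595 0.006221  0.9979 0.0007445        0
```

Reading the output: on held-out (novel) test trials at a 58 ms prediction
interval the network tracks ankle angle to well under 1 degree RMSE and
ankle moment to under 0.04 N·m/kg in every ambulation condition, with
squared cross-correlation peaks above 0.99 occurring at zero lag — the
operating point the method is built around. The same report contains the
constant-EMG ablation (each test trial's EMG replaced by its temporal mean):

```r
mean(pl$report$metrics$rmse_constant_emg[pl$report$metrics$output == "angle"])
#> [1] 1.984338
```

Destroying the time-varying EMG information roughly triples the angle error
(and quadruples the moment error), which is the evidence that the
predictions use the myoelectric signal rather than merely extrapolating the
autoregressive history.

A command-line interface to the individual stages (simulate, preprocess,
train, sweep, pipeline) is in `inst/cli/narxgait.R`:

```sh
Rscript inst/cli/narxgait.R simulate --n-trials 11 --seed 42 --coupling 0.6 --out session/
Rscript inst/cli/narxgait.R pipeline --seed 42 --out artifacts/
```

## Package layout

| Area | Files |
| --- | --- |
| Synthetic gait generator (templates, variability, teacher network) | `R/synthetic.R` |
| Signal conditioning (envelope, kinetic/kinematic filters, truncation) | `R/filters.R`, `R/sigproc.R` |
| NARX core (forward pass, normalization, serialization) | `R/narx.R` |
| Training (Levenberg–Marquardt, folds, restarts) | `R/training.R` |
| Hyperparameter sweep and finalization | `R/sweep.R` |
| Evaluation and statistics (RMSE, R², ablation, critical points, B–H) | `R/evaluation.R` |
| I/O and pipeline | `R/io.R`, `R/pipeline.R` |

The methods vignette (`vignettes/narxgait-methods.Rmd`) documents the model
assumptions, the training and evaluation protocol, every tunable parameter
with units and defaults, what the synthetic generator does and does not
emulate, and the package's numerical choices.
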