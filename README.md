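# tumanet

Simulation and analysis of synchronous bursting in cultured cortical
networks with astrocytic glutamate recycling.

Networks grown on multielectrode arrays fire in *synchronous bursts*
(SBs): array-wide epochs of dense spiking separated by long dormant
periods. Astrocytes clear most synaptic glutamate through GLT-1/EAAT2
transporters and return it to the presynaptic terminal only slowly, via
the glutamate–glutamine cycle. `tumanet` is for computational
neuroscientists who want to explore how those two astrocytic timescales
shape network bursting, and for experimentalists who need the matching
spike-train analysis (burst detection and statistics) for MEA-style
recordings.

## The model

Each synapse tracks the fractions of a conserved glutamate pool in four
states — ready `X`, active `Y`, recovered `Z`, astrocytic `A`
(`X + Y + Z + A = 1`):

    dX/dt = Z/τ_r − u·X·δ(t − t_spk) − ξ̄·X·δ(t − t_a)
    dY/dt = u·X·δ(t − t_spk) + ξ̄·X·δ(t − t_a) − Y/τ_nu − Y/τ_au
    dZ/dt = Y/τ_nu + A/τ_g − Z/τ_r
    dA/dt = Y/τ_au − A/τ_g

Spikes release the fraction `u = 0.2` of the ready pool; asynchronous
events (a Poisson process per efferent synapse whose rate is a Hill
function of presynaptic residual calcium, after Volman-style calcium
dynamics) release `ξ̄ = 0.02`. Cleft glutamate is cleared by the neuron
(`τ_nu = 50` ms) and the astrocyte (`τ_au = 250` ms); the astrocytic pool
returns it slowly (`τ_g = 30` s). Dropping the astrocytic pathway
recovers the classical three-state short-term-depression model.

One hundred Morris–Lecar neurons (20 inhibitory) are coupled through
these synapses on a random directed graph (connection probability 0.1,
weights 4 ± 20%), with conductances `G_i = Σ_j w_ij Y_ji (1 − b Y_ji)`.
The analysis layer implements the two-threshold SB detector on the
firing-rate time histogram (lower threshold `0.04·R_max`, upper
`0.2·R_max`, 1-s quiescence rule), the SB index, ISI return maps, and
ΔF/F fluorescence utilities.

## Worked example

```r
library(tumanet)

cfg <- sim_config(duration = 300000,            # 300 s at dt = 0.05 ms
                  seeds = list(topology = 1002, dynamics = 2))
sim <- run_simulation(cfg)
sim
#> <tuma_sim> tuma mode: 6674 spikes from 100 neurons over 300 s (22.25 spikes/s array-wide)

sim_burst_stats(sim)                            # discards the first 20 s
#> $firing_rate
#> [1] 8.328571
#> $sb_rate
#> [1] 3.857143
#> $mean_sb_duration
#> [1] 0.3483333
#> $sb_index
#> [1] 0.8923671
#> $n_bursts
#> [1] 18
#> $mean_A
#> [1] 0.7199094
```

The network settles into dormant phases broken by ~0.35-s synchronous
bursts about four times a minute; 89% of all spikes occur inside bursts,
and 72% of the glutamate sits in the astrocytic pool, which acts as the
reservoir that throttles the ready supply. Sweeping the astrocytic
uptake time reproduces the transporter-block phenomenology: slower
uptake (larger `τ_au`) raises the burst rate and drains the astrocytic
reservoir:

```r
tab <- run_sweep(tau_au_values = c(200, 250, 300), tau_g_values = 30000,
                 n_seeds = 3)
aggregate(cbind(sb_rate, sb_duration, mean_A) ~ tau_au, tab, mean)
#>   tau_au   sb_rate sb_duration    mean_A
#> 1    200 0.4285714   0.3475000 0.7502759
#> 2    250 3.1428571   0.2799020 0.7196166
#> 3    300 7.7857143   0.3679548 0.6951785
```

(The duration column is noisy at 200 ms, where this seed set produces
only a handful of bursts; the rate and astrocytic-level trends are the
robust ones at this problem size.)

Clamping the astrocytic fraction at its free-run mean
(`run_fixed_a(cfg)`) leaves the burst patterns essentially unchanged —
the model's demonstration that a *constant* astrocytic reservoir level,
not its fast dynamics, sets the network's operating point.

A thin command-line driver with `simulate`, `detect-bursts`, `stats`,
`sweep`, `fixed-a` and `fixture` subcommands is installed at
`inst/scripts/tuma_cli.R`.

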