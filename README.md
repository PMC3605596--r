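# tirftrack

Simulation and analysis of single-molecule TIRF microscopy recordings of
membrane receptors.

In total internal reflection fluorescence (TIRF) microscopy, a
fluorescently labeled membrane receptor — the motivating system is the M2
muscarinic acetylcholine receptor on cardiac cells — appears as a
diffraction-limited spot (~300 nm FWHM) that can be localized to tens of
nanometers, tracked while it diffuses in the membrane, and watched until
it photobleaches in discrete steps. Three biophysical quantities fall out
of such movies and together set how fast receptor signaling can possibly
be:

* **surface density** ρ (spots per µm², directly at low density, by
  photobleaching-rate extrapolation above the countable limit of
  0.8 µm⁻²);
* **lateral mobility** D_lat from the slope of the mean-squared
  displacement, MSD(Δt) = 4 · D_lat · Δt for free 2-d Brownian motion,
  with the MSD shape discriminating free, directed and confined motion,
  and a Q10 ≈ 2 temperature dependence;
* **oligomeric state** from stepwise photobleaching of per-spot intensity
  traces (one drop = monomer, two sequential drops = dimer, a rise from
  one to two units = a dimer forming mid-track).

Given ρ and D_lat, a 2-d Monte Carlo collision simulation predicts how
often a receptor encounters an effector channel (capture radius 6 nm) and
the diffusion-limited latency to the first encounter — the physical floor
under the delay between agonist binding and channel response.

The package is built for parameter-recovery validation: a synthetic-movie
generator (`simulate_movie()`) renders ground-truth-annotated TIRF movies
with Brownian motion, Poisson shot noise, single-step photobleaching and a
reversible monomer–dimer equilibrium, and every analysis stage is tested
by recovering what went in.

## Worked example

```r
library(tirftrack)

cfg <- movie_config(field_width = 18, field_height = 18,
                    receptor_density = 0.3,   # um^-2
                    d_lat = 0.15,             # um^2/s
                    frame_interval = 0.02,    # 50 frames/s
                    n_frames = 60, bleach_rate = 0.4, rng_seed = 42)
rep <- pipeline_run(cfg)
print(rep)
#> TIRF pipeline report
#>   5292 spots -> 158 tracks
#>   D_lat = 0.1549 +/- 0.00011 um^2/s (free)
#>   rho = 0.311 +/- 0.031 um^-2
```

The pipeline detected and linked the spots, recovered the generating
mobility (0.155 vs 0.15 µm²/s) and density (0.31 vs 0.3 µm⁻²), and
classified the motion as free diffusion. The same report carries the
photobleaching-type census (96.6% single-drop "type 1" traces here — no
dimer kinetics were enabled, so almost every track is a monomer bleaching
in one step).

The collision module, at the densities and 37 °C mobility estimated for
cardiac tissue:

```r
cc <- collision_config(receptor_density = 3, channel_density = 3,
                       d_r = 1, d_g = 1, duration = 2, seed = 7)
simulate_collisions(cc)
#> collision_result: 9.2 +/- 0.26 encounters/receptor/s
#>   first-encounter latency 0.143 +/- 0.014 s (0 censored)
#>   101 receptors, 101 channels, 2 s simulated
```

A receptor meets a channel several times per second, and the first
encounter takes ~150 ms — the same order as the measured latency of the
acetylcholine-to-GIRK-current response.

Binding arithmetic behind the labeling protocol:

```r
100 * fractional_occupancy(10e-9, log_affinity_to_kd(10.35))
#> [1] 99.5553
```

See `vignettes/receptor-tirf-methods.Rmd` for the models, parameter
defaults, numerical choices and known limitations.

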