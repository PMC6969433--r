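# tirfdwell

Single-molecule TIRF microscopy can watch individual fluorophore-labeled
enzymes bind to and release from an immobilized substrate — the motivating
system is the processive cellobiohydrolase Cel7A on cellulose fibrils. Each
bound molecule is a diffraction-limited spot in a 1 frame/s movie; the
length of its stay is a *residence (dwell) time*. `tirfdwell` turns such
image stacks (or pre-localized spot tables) into per-molecule binding
events and resolves the dwell-time distribution into 1–3 kinetic
populations, for people who need dissociation kinetics out of TIRFM movies
without hand-tuned, per-movie analysis.

The dwell-time histogram with counts $y_i$ is fit by a window-renormalized
multi-exponential,

$$\mu_i = \sum_{j=1}^{m} N_j\,
  \frac{e^{-t_i^{\mathrm{left}}/\tau_j} - e^{-t_i^{\mathrm{right}}/\tau_j}}
       {e^{-t_{\min}/\tau_j} - e^{-t_{\max}/\tau_j}}, \qquad m \le 3,$$

minimizing the Poisson deviance
$D = 2\sum_i\left[y_i\ln(y_i/\mu_i) - (y_i-\mu_i)\right]$
by differential evolution over $(\log\tau_j, N_j)$ with a Nelder–Mead
polish. Components are selected by BIC after discarding indistinct ones,
fractions are event-count fractions $f_j = N_j/\sum_k N_k$, and components
whose $\tau_j$ matches a photobleach lifetime of the label (Cy5:
bi-exponential, ~195 s / 1100 s under oxygen scavenging) are flagged
*bleach-limited*: their molecules are effectively immobilized and their
$\tau_j$ is only a lower bound. For a genuine short-lived population,
$k_\mathrm{off} = 1/\tau$, intrinsic processivity $= k_\mathrm{cat}\tau$,
and translation distance follows at ~1 nm per catalytic turnover.

Upstream of the fit the package provides sub-pixel Gaussian localization
with iterative subtraction and joint refitting of overlapping emitters,
drift correction by cross-correlating super-resolution block histograms,
greedy nearest-neighbor linking with blink-gap tolerance, first/last-frame
censoring, and automated fibril segmentation from the super-resolution
summed image (or a user-drawn mask) to split events into on-fibril vs
background. A synthetic-data module generates event lists and rendered
movies with known ground truth, so every stage is validated by parameter
recovery. See the vignette `vignettes/dwell-time-analysis.Rmd` for the
model, assumptions, and design choices.

## Worked example

Simulate the two-population structure of an intact processive cellulase —
81% short-lived with $\tau = 15$ s plus 19% immobilized molecules observed
only until their dye bleaches — over a 2500-frame window, censor events
touching either end, and fit three components:

```r
library(tirfdwell)

truth <- simulation_truth(
  populations = list(population_spec(0.81, 15),
                     population_spec(0.19, Inf, immobilized = TRUE)),
  arrival_rate_fibril = 0, arrival_rate_bg = 2, n_frames = 2500,
  bleach = bleach_model(c(195, 1100)), bleach_scope = "immobilized",
  seed = 42)
events <- simulate_event_list(truth)

end  <- events$start_frame + events$dwell_frames - 1L
kept <- events$start_frame >= 1 & end <= 2498          # censor window edges
fit  <- fit_dwell_times(events$dwell_frames[kept], m = 3, t_max_s = 2500,
                        bleach = bleach_model(c(195, 1100)), seed = 1)
fit
#> dwell_fit: 3 component(s), deviance 1211 (reduced 0.538)
#>   tau_1 =     14.9 s   f_1 =  84.4%   N_1 = 4096
#>   tau_2 =      103 s   f_2 =   6.6%   N_2 = 320.7
#>   tau_3 =      494 s   f_3 =   9.0%   N_3 = 438.5
#>   immobilized fraction: 0.0%
```

The short population comes back at 14.9 s with an 84% kept-event fraction
(censoring removes proportionally more long events, so the short fraction
sits a few points above the 81% arrival fraction). Components 2 and 3 are
the bleach mixture as seen through the censored window: excluding events
that touch the last frame thins long dwells, so their fitted time
constants sit well below the nominal 195/1100 s lifetimes — which is why
they escape the automatic bleach flags here. A control fit of the
uncensored Cy5 survival itself recovers and flags both lifetimes:

```r
truth_b <- simulation_truth(
  populations = list(population_spec(1, Inf, immobilized = TRUE)),
  arrival_rate_fibril = 0, arrival_rate_bg = 4, n_frames = 2500,
  bleach = bleach_model(c(195, 1100)), seed = 11)
surv <- simulate_event_list(truth_b)
fit_dwell_times(head(surv$dwell_frames, 10000), m = 2,
                bleach = bleach_model(c(195, 1100)), seed = 2)
#> dwell_fit: 2 component(s), deviance 4677 (reduced 0.394)
#>   tau_1 =      189 s   f_1 =  49.7%   N_1 = 4941   (bleach-limited)
#>   tau_2 =  1.1e+03 s   f_2 =  50.3%   N_2 = 4999   (bleach-limited)
#>   immobilized fraction: 100.0%
```

Kinetics for the short-lived population:

```r
kinetics_summary(fit$model$tau[1])
#> kinetics: tau = 14.9163 s -> k_off = 0.067 s^-1
#>   processivity 30-164 turnovers (kcat 2-11 s^-1)
#>   translation 30-164 nm at 1 nm/turnover
```

A dissociation rate of 0.067 s⁻¹ and an intrinsic processivity of a few
tens to ~160 turnovers per binding run: if such an enzyme hydrolyzed
throughout its stay it would advance tens to ~160 nm along its substrate.

For whole movies, `run_pipeline(pipeline_config(input = "movie.tif"))`
chains localization → drift correction → linking → censoring → masking →
per-region fits → kinetics, writing every intermediate table, a JSON
report, and a log with a conservation ledger (localizations consumed =
event support; events = kept + censored; kept = fibril + background +
unassigned). `inst/scripts/tirfdwell.R` wraps `run_pipeline()` and the
simulator for shell use.

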