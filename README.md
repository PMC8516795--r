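# gazematch

Elastic consensus matching of recall fixations onto encoding fixations for
the **looking-at-nothing** paradigm.

## What problem does this solve?

In looking-at-nothing experiments, participants view a scene (*encoding*,
fixations *p<sub>i</sub>*) and then recall it in front of a blank screen
while their eyes are tracked (*recall*, fixations *r<sub>j</sub>*).  Recall
fixations roughly re-enact the scene layout but are distorted: the whole
configuration drifts, rotates and shrinks toward the centre (no reference
frame), each fixation carries accumulating local error, and some fixations
are unrelated to remembered content.  Nearest-neighbour matching fails
because it ignores the relative structure of the recall configuration.

`gazematch` relocates recall fixations with a smoothly varying rigid
mapping *D*(x) = *R*<sub>x</sub> x + *t*<sub>x</sub>, fit by
moving-least-squares over handle pairs (*r<sub>j</sub>* →
*q<sub>j</sub>*) with Gaussian weights θ<sub>d</sub>(d) =
exp(−d²/w<sub>d</sub>²), where each target *q<sub>j</sub>* is the
Gaussian-distance-weighted **consensus centroid** of the encoding
fixations around the current relocated position,

q<sub>j</sub> = Σ<sub>i</sub> θ<sub>p</sub>(‖D(r<sub>j</sub>) − p<sub>i</sub>‖) p<sub>i</sub> / Σ<sub>i</sub> θ<sub>p</sub>(‖D(r<sub>j</sub>) − p<sub>i</sub>‖).

Targets and mapping are alternated from the identity until convergence
(typically 5–12 iterations).  Encoding fixations within an inclusive
radius ε of a relocated recall fixation count as *matched*
("remembered"); the rest are *leftover* ("forgotten").  Defaults
w<sub>p</sub> = 2°, w<sub>d</sub> = 10°, ε = 1° of visual angle; all
degree↔pixel conversion goes through a `screen_geometry` (default: a
0.52 m × 0.32 m, 1920 × 1200 px display at 0.7 m; 1° = 45.11 px).

The package also provides gaze/clicking density maps (Gaussian-smoothed
spatial histograms), peak-shift analysis, 2-D fixation entropy, validation
metrics (Judd-style AUC against point positives, pixelwise Pearson CC),
a fully ground-truthed synthetic trial generator, and a CLI.

## Worked example

```r
library(gazematch)
geom <- default_geometry()

# one synthetic trial: 16 encoding fixations, 10 recalled (shrunk, rotated,
# translated, smoothly deformed, jittered) + 1 spurious fixation
tr <- generate_trial(16, distortion_spec(seed = 1))
tr
#> <synthetic_trial> 16 encoding, 11 recall fixations (1 spurious)

res <- relocate(tr$encoding, tr$recall, algorithm_params(), geom)
res
#> <relocation_result> 11 fixations relocated in 5 iteration(s) (converged)

m <- match_fixations(tr$encoding, res$relocated, epsilon_deg = 1, geom)
m
#> <match_result> eps=1 deg: 13/16 encoding fixations matched (reduction rate 0.188)

# against ground truth, and against matching the raw (unrelocated) recall
ok  <- !is.na(tr$truth)
err <- sqrt(rowSums((res$relocated[ok, ] - tr$true_positions[ok, ])^2))
mean(px_to_deg(err, geom))
#> [1] 1.101
reduction_rate(match_fixations(tr$encoding, positions(tr$recall), 1, geom))
#> [1] 0.688

epsilon_sweep(tr$encoding, res$relocated, c(1, 2, 4, 8), geom)
#>   epsilon_deg reduction_rate matched_fraction
#> 1           1         0.1875           0.8125
#> 2           2         0.0000           1.0000
#> 3           4         0.0000           1.0000
#> 4           8         0.0000           1.0000
```

Reading: after relocation, 13 of 16 encoding fixations have a relocated
recall fixation within 1° (reduction rate 0.19), versus only 5 of 16
(reduction rate 0.69) for the raw recall positions — the relocation
recovers most of the global distortion.  The mean distance between each
relocated fixation and the encoding fixation it truly came from is ~1.1°
on this trial (suite average ~0.65°); by ε = 2° every encoding fixation is
matched.

Density maps and validation against click data:

```r
enc_map <- make_density_map(tr$encoding, c(1024, 768), sigma_deg = 1, geom)
mm      <- matched_maps(tr$encoding, m, c(1024, 768), 1, geom)   # matched + leftover
peak_shifted(enc_map, mm$matched, threshold_deg = 4, geom)
val <- validation_experiment(n_images = 8, base_seed = 7)        # AUC / CC vs clicks
val$aggregate
```

## Command line

```sh
Rscript inst/cli/gazematch simulate --out data    --config cfg.json --n-trials 10 --seed 1
Rscript inst/cli/gazematch relocate --fixations data/fixations.csv --config cfg.json --out out
Rscript inst/cli/gazematch sweep    --fixations data/fixations.csv --config cfg.json --out out --epsilon-sweep 1:10
Rscript inst/cli/gazematch metrics  --fixations data/fixations.csv --clicks clicks.csv --config cfg.json --out out
```

`cfg.json` holds the algorithm parameters and screen geometry, e.g.
`{"epsilon_deg": 1, "w_p_deg": 2, "w_d_deg": 10, "geometry": {"width_m":
0.52, "height_m": 0.32, "res_x": 1920, "res_y": 1200, "distance_m": 0.7}}`.
Flags override config keys; every run writes a JSON log with parameters,
seed and input MD5 hashes.  Fixation files are delimited text
(`participant,image,phase,x,y,duration[,onset]`); an EyeLink
fixation-report dialect is built in (`eyelink_dialect()`).

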