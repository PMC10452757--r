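# crashtriage

Occupant injury risk estimation for full-frontal vehicle crashes.

## What this solves

When a modern vehicle crashes, its event data recorder (EDR) captures a
handful of crash parameters — the velocity change of the vehicle
(delta-v), whether the driver's seatbelt was buckled, and the time the
airbag took to deploy. Those three numbers, transmitted automatically,
could let emergency dispatch estimate how badly the occupant is hurt
*before* anyone reaches the scene. `crashtriage` implements that
estimation chain end to end for researchers in injury biomechanics and
automatic crash notification:

1. **Simulate** occupant loading across a designed grid of frontal-crash
   conditions (collision speed × airbag deployment time × belt use)
   using an idealized haversine crash pulse and a lumped-parameter
   occupant surrogate.
2. **Score** each simulated response with the two standard injury
   criteria — the Head Injury Criterion over 36 ms windows (HIC36) and
   the Combined Thoracic Index (CTI).
3. **Band** the criteria on the Abbreviated Injury Scale (AIS),
   producing head and chest severity labels from AIS 0–1 (none/minor)
   to AIS 5–6 (critical).
4. **Learn** the direct mapping from crash parameters to head and chest
   AIS with a small feedforward neural network, so predictions no longer
   require running a simulation.
5. **Validate** the network against EDR-style crash records with
   confusion matrices at the serious-injury threshold (maximum AIS ≥ 3)
   and ROC/AUC analysis.

### The science, briefly

The head criterion is

```
HIC = max over windows t1 < t2, t2 - t1 <= 36 ms of
      [ (1/(t2-t1)) * integral of a(t) dt from t1 to t2 ]^2.5 * (t2-t1)
```

with resultant head acceleration `a` in g, and the chest criterion is

```
CTI = Amax / 85 g  +  Dmax / 102 mm
```

(peak chest acceleration and deflection over their 50th-percentile-male
intercepts). Both are mapped to five AIS bands — {0–1, 2, 3, 4, 5–6} —
by a published threshold table (HIC bounds 250 / 750 / 1250 / 1750; CTI
bounds 0.80 / 1.15 / 1.39 / 2.16, half-open on the left). A 3-input /
8-hidden / 2-output sigmoid network trained by incremental
backpropagation (learning rate 0.3, up to 10,000 epochs) learns the
condition-to-band mapping from an 84-condition full factorial; overall
injury is summarized as MAIS = max(head AIS, chest AIS) and judged
against the AUC grades > 0.9 high, 0.7–0.9 medium, 0.5–0.7 low.

See the methods vignette (`vignettes/crash-injury-pipeline.Rmd`) for
the surrogate model, all numerical choices, and known limitations.

## Worked example

Simulate one crash — 56 km/h, belted, airbag at 20 ms — and score it:

```r
library(crashtriage)

pulse <- generate_vehicle_pulse(delta_v = 56)
pulse
#> <vehicle_pulse> delta-v 56.0 km/h, duration 100 ms, 1001 samples, peak 31.7 g

resp <- simulate_occupant(pulse, belted = TRUE, deploy_time = 20)
crit <- compute_injury_criteria(resp)
crit
#>     hic36   t1_s   t2_s      cti  a_max_g d_max_mm
#> 1 486.399 0.0472 0.0832 1.025884 39.17644 57.62845

band_for_hic(crit$hic36)   # head severity:  AIS "2" (moderate)
band_for_cti(crit$cti)     # chest severity: AIS "2" (moderate)
```

Build the full training set, train the network, predict a new
condition, and validate on synthetic EDR records:

```r
training <- generate_training_set(build_design())   # 84 conditions
model <- train_ais_net(training, net_config())
model
#> <ais_net> 3-8-2 sigmoid network; stopped at epoch 10000, MSE 0.01774

predict_ais(model, data.frame(delta_v = 65, belted = FALSE, deploy_time = 45))
#>   head_score chest_score head_ais chest_ais
#> 1  0.9999493   0.9996056        5         5

edr <- generate_edr_cases(200, noise = 0.25, seed = 2)
validate_predictions(model, edr)
#> <validation_result> n = 200, AUC = 0.977 (high accuracy)
#>   confusion TP 43 / FN 9 / FP 1 / TN 147; consistency 122 equal / 15 over / 63 under
```

The same pipeline is available stage by stage from the command line via
`inst/cli/crashtriage.R` (subcommands `simulate`, `criteria`, `train`,
`predict`, `validate`), driven by a YAML configuration
(`inst/extdata/default_config.yaml`) with every stage seeded and logged.

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "crashtriage",
                               load_package = "installed")'
```

The suite checks the numerical kernels against independent oracles
(exhaustive-window HIC search, pairwise Mann–Whitney AUC, an external
ROC library), closed-form cases, conservation and scaling laws, the
qualitative crash-physics trends of the surrogate, and file round-trips
for every I/O format.

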