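# hsmax

Presence-only habitat suitability modelling with maximum entropy, for
fine-scale (protected-area) studies of sessile species — the situation a
field botanist faces with a few dozen GPS records of a rare orchid and a
stack of co-registered environmental rasters, asking where the species
could persist today and under future climate scenarios.

`hsmax` implements the complete per-species pipeline as tested, reusable
R functions:

* **Occurrence preparation** — deduplication, study-area clipping, and
  spatial thinning to a minimum nearest-neighbour distance (default 1 km,
  haversine, best of 100 randomized runs).
* **Maximum-entropy model** — a Gibbs distribution over study-area cells
  with linear/quadratic/product/hinge/threshold features, fitted by
  coordinate descent on the L1-regularized objective
  `J(λ) = −mean_presence λ'f(x) + ln Z(λ) + Σ β_j |λ_j|`,
  with cloglog output `1 − exp(−e^H · raw(x))`.
* **Variable selection** — replicate screening runs ranked by permutation
  importance, a <1% contribution cut, Pearson pair filtering
  (`|r| ≥ 0.8`), iterative VIF elimination (`VIF > 5`), top-5 selection.
* **Tuning and evaluation** — the 8 × 6 = 48-combination grid over
  regularization multipliers (0.5–4 by 0.5) and feature classes
  (L, LQ, H, LQH, LQHP, LQHPT), ranked by sample-size-corrected AIC
  (`ΔAICc = 0` wins); bootstrap replicates give AUC, AUC_DIFF and the 10%
  omission rate.
* **Classification and range change** — maximum test sensitivity plus
  specificity (MTSPS) thresholding, four-class equal-interval suitability
  maps, binary maps, and loss/stable/gain accounting with
  `%Loss = 100·L/(L+S)`, `%Gain = 100·G/(L+S)`, `SRC = %Gain − %Loss`,
  and km² conversion (default cell area 25/36 km²).
* **Synthetic landscapes** — spatially autocorrelated raster stacks with
  known true suitability surfaces, presence sampling, and future-scenario
  perturbation of the climate layers only, so the whole pipeline runs and
  is tested without any external data. ESRI ASCII grid I/O throughout.

## Worked example

A self-contained demo builds a synthetic landscape (14 layers, 25 × 25
cells), samples 45 presence records of a virtual species from a known
suitability surface, and runs the full analysis across one current and
four future scenario stacks:

```r
library(hsmax)
d <- "hsmax_demo"
make_demo(seed = 1, dir = d)
cfg <- read_config(file.path(d, "config.yaml"))
man <- run_species(cfg, "synthetic_orchid", base_dir = d)
```

With seed 1 this prints/records:

```
n_occurrences_used: 29          # 45 raw records -> 29 after 1-km thinning
selected: SOIL1, BIO15, ELV, BIO1, LC1
best combo: FC = LQHP, RM = 2   # ΔAICc = 0 row of the 48-combination grid
AUC 0.913 ± 0.014 (perfect or excellent), AUC_DIFF 0.018, OR10 0.187
MTSPS threshold: 0.4460
```

The true surface behind the demo is driven by `BIO15` (+) and `SOIL1`
(−); both are recovered in the selected set, the training AUC lands in
the 0.9+ band expected for a sharply defined niche, and the small
AUC_DIFF says the bootstrap replicates do not overfit. The range-change
table (`run/synthetic_orchid/range_change.csv`) then quantifies habitat
loss as the climate shifts intensify:

```
     scenario loss stable gain pct_loss pct_gain    src crs_km2
 2030s-SSP245   16    114    3    12.31     2.31 -10.00   90.28
 2030s-SSP585   21    109    0    16.15     0.00 -16.15   90.28
 2050s-SSP245   31     99    0    23.85     0.00 -23.85   90.28
 2050s-SSP585   58     72    0    44.62     0.00 -44.62   90.28
```

Reading the first row: of the 130 currently suitable cells (90.28 km²),
16 are predicted lost and 3 gained by the 2030s under the intermediate
scenario, a species range change of −10%. Losses grow monotonically with
scenario severity, the pattern this kind of analysis exists to surface.

Every artifact (suitability, class and binary maps as `.asc`, selection
and tuning tables as CSV, the serialized model, a manifest with MD5
hashes) lands under `run/synthetic_orchid/`; rerunning with the same seed
reproduces all of them bit-identically.

A thin CLI wraps the same functions
(`inst/cli/hsmax demo|thin|select-vars|tune|fit|predict|classify|range-change|run`).

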