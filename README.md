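# gwannSRMD

Delineating the **spatial range of mining disturbance (SRMD)** on vegetation
around open-pit mines, for researchers in environmental remote sensing and
mine-site rehabilitation planning who need to separate the mining signal from
the climatic, topographic and urban drivers that change vegetation at the
same time.

## The method

Fractional vegetation cover is inverted from red/NIR reflectance by the pixel
dichotomy model on harmonized, maximum-value-composited NDVI,

    FVC = (NDVI − NDVI_min) / (NDVI_max − NDVI_min),

and related to five min–max-normalized driving factors — precipitation
X_pre, temperature X_temp, topography X_dem, urban activity X_urban and
mining activity X_mine, the activities quantified as `magnitude / (D + 1)`
with D the distance (km) to the urban/mining boundary — by a
**geographically weighted artificial neural network** (GWANN): a tanh
network with one output neuron per anchor location, trained on the
kernel-weighted loss

    E = 1/(2n) Σ_s Σ_j exp(−d(s,j)² / 2b²) (r_s − p_sj)².

On the trained surface, a finite-difference scheme perturbs one factor at a
time (ΔX = 0.001·X) and forms per-pixel partial derivatives
`C_i = (Y_perturbed − Y) / ΔX_i` and contribution shares
`W_i = C_i / Σ_k C_k`. Running the same attribution over a pre-mining
period with an *assumed* mining factor yields the "virtual contribution"
V-W_mine — the attribution noise — and the disturbance mask is the one-sided
significance test

    SRMD = { pixels : W_mine > V_0.95 },

with V_0.95 the empirical 95% cumulative-frequency point of the pooled
virtual contributions (α = 0.05). The mask is summarised by disturbance
distances (km from the SRMD boundary to the mining area), the fraction
inside a 3 km buffer, and eight-sector directional ranges.

A seeded synthetic-scene generator (`generateScene()`) emulates the study
setting — eleven years, 90 m cells, a central mine beside an urban block,
station meteorology, known generative coefficients and a known true
disturbance radius — so the whole pipeline can be exercised and its error
rates measured without the (unavailable) satellite record.

## Worked example

```r
library(gwannSRMD)
scene <- generateScene(sceneConfig(seed = 1))   # synthetic 60x60, 11 years
cfg <- srmdConfig(anchorBudget = 64L, maxEpochs = 100L, eta = 0.35, seed = 1)
run <- runAll(cfg, scene = scene)
print(run)
```

```
SRMD pipeline run
  tested year: 2020; 36000 noise samples; V_0.95 = 1.165
  mean RMSE 0.0659, mean MRE 0.0858 over 11 years
  SRMD: 335 pixels
SRMD: 335 pixels, 149 boundary pixels
  disturbance distance (km): mean 2.24, median 2.26, IQR [1.85, 2.56], max 3.31
  fraction inside the 3 km buffer: 0.949
```

Reading this: the ten no-mining years contribute 36 000 virtual-contribution
samples whose empirical 95% point (1.165) becomes the significance
threshold; the per-year GWANN fits reach a mean RMSE of 0.066 against the
observed FVC; 335 pixels of the 2020 scene exceed the threshold, 94.9% of
them inside the 3 km buffer, with boundary-to-mine distances around 2.2 km
(mean 2.24 km). On
synthetic worlds the flagged region tracks where the *mining contribution
share* dominates — which, as the methods vignette derives, is not an isoline
of absolute vegetation loss; see the vignette's "Known limitations" before
interpreting the mask's outer edge as a suppression radius.

The same run from the shell:

```sh
Rscript inst/scripts/srmd-cli.R simulate --out-dir scene/ --seed 1
Rscript inst/scripts/srmd-cli.R run-all --input-dir scene/ --out-dir results/
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
generates the seeded synthetic scene, inverts FVC through the real
reflectance path, builds the drivers, trains the per-year networks,
calibrates the virtual-contribution noise, applies the significance test and
summarises the disturbance geometry — and writes its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
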