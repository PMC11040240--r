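# roostfinder

Estimate the location of a bat roost from static acoustic detector
surveys.

Ecologists looking for roosts — greater horseshoe bat maternity roosts
especially — face days of labour-intensive searching. An array of static
ultrasound detectors offers an indirect signal: as bats disperse from the
roost after sunset, the spatial pattern of recorded passes encodes where
the dispersal began. `roostfinder` inverts that pattern into a point
prediction and, more usefully, a ranked map of search regions.

## The method

Dispersal in the first 90 minutes after sunset is modelled as planar
diffusion: a bat from a roost at *z* has position density

φ(x, y, z, t) = exp(−((x−z_x)² + (y−z_y)²) / 4Dt) / (4πDt),

with D ≈ 80 m²/s. Integrating φ over a detector's 15 m acoustic
footprint and over the 90-minute window gives the expected passes
E_i(z) at detector i; normalizing across the array gives expected call
proportions F_i(z) = E_i / Σ_j E_j, in which colony size cancels. A fast
algebraic approximation, P̃_i(t) = (r²/4Dt)·exp(−d_i²/4Dt) (centre
density × footprint area), makes landscape-scale evaluation cheap.

Observed proportions C_i (per-detector calls per active night,
normalized) are compared with F(z) at the centre of every cell of a grid
spanning the detector array:

ρ(z) = Σ_i (F_i(z) − C_i)² / max_z′ Σ_i (F_i(z′) − C_i)² ∈ [0, 1].

Low ρ marks likely roost positions. The argmin is the point prediction
z_p; the level sets {ρ ≤ τ} are optimal search regions. A baseline
estimator, the centre of calls CC = Σ_i C_i X_i, is reported alongside —
it is strong when the detectors surround the roost but is confined to
their convex hull, while the ρ surface can point beyond the array. A
stochastic Brownian-agent simulator generates synthetic surveys for
validation and survey planning.

## Worked example

The packaged survey `synthetic_ring_survey.csv` was generated with the
package's own simulator (300 bats/night from a roost at (150, −100),
12 detectors on a 1 km ring, 7 nights with detector failures — see
`inst/extdata/synthetic_ring_survey.md`):

```r
library(roostfinder)
sv <- load_survey(system.file("extdata", "synthetic_ring_survey.csv",
                              package = "roostfinder"),
                  roost = c(150, -100))   # known truth, for evaluation
surf <- build_rho_surface(sv, grid_from_survey(sv, n_x = 100))
est <- search_statistics(surf)
est
#> Roost estimate
#>   zp (argmin rho) : (110.0, -130.0)
#>   centre of calls : (221.8, -91.6)
#>   |zp - CC|       : 0.12 km
#>   |zR - zp|       : 0.05 km
#>   |zR - CC|       : 0.07 km
#>   rho at roost    : 0.01
#>   % of mapped area below rho thresholds:
#>     rho <= 0.1   :  14.31 % (0.57 km^2)
#>     rho <= 0.2   :  29.90 % (1.20 km^2)
#>     rho <= 0.3   :  46.99 % (1.88 km^2)
#>     rho <= rho_c :   0.19 % (0.01 km^2)
confidence_heuristic(est)
#> [1] "high"
```

Reading: the model's point prediction lands 50 m from the true roost
(the centre of calls 70 m); searching cells in order of increasing ρ
would have visited only 0.19 % of the mapped area (0.01 km²) before
reaching the roost; and the close agreement between z_p and CC flags the
prediction as high-confidence. `plot(surf)` draws the surface with
contours, detectors, z_p, CC and the roost.

A shell interface wrapping the same functions is installed at
`exec/roostfinder`:

```sh
roostfinder estimate --survey survey.csv --grid 500 --D 80 --out out/
roostfinder simulate --scenario scenario.yaml --out sim/
roostfinder validate-approx
```

`estimate` writes `rho.csv`, `summary.json` (point estimates, distances
in km, and search-area percentages) and optionally an ESRI ASCII grid or
PNG heatmap.

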