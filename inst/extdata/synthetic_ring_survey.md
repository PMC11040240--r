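# synthetic_ring_survey.csv

Synthetic survey generated with the package's own agent simulator (it is
not field data): 300 Brownian agents per night dispersing for 90 min from
a roost at easting 150, northing -100, with D = 81.7 m^2/s, recorded by 12
detectors on a ring of radius 1000 m, over 7 nights with a per-night
detector survival probability of 0.9 (one detector failed before night 1
and is absent from the table). Regenerate with:

```r
library(roostfinder)
sc <- sim_scenario(roost = c(150, -100),
                   detectors = detector_ring(12, radius = 1000),
                   n_agents = 300, n_nights = 7, seed = 2026)
res <- apply_failures(simulate_survey(sc), survival = 0.9, seed = 2026)
save_survey(as_survey(res), "synthetic_ring_survey.csv")
```
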