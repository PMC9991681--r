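#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study city.
#
# Emulated study conditions: 1100 screened patients with ~31% food
# insecurity concentrated in three spatial hotspots, 75 full-line grocery
# stores with total NEMS-S targeting mean 27 / sd 5 / range 16-35, and a
# 12 x 10 grid of census-tract analogues whose socio-economic profile tracks
# the hotspots (lower income, higher poverty / unemployment / no-vehicle /
# public-assistance rates). Writes patients.csv, stores.csv, tracts.csv and
# the config under results/city/.

suppressMessages(library(foodaccess))

cfg <- city_config(seed = 20260924)
city <- generate_city(cfg)
write_city(city, "results/city")
points_to_geojson(city$patients[, c("id", "x", "y", "food_insecure")],
                  "results/city/patients.geojson")
points_to_geojson(city$stores[, c("id", "x", "y", "total")],
                  "results/city/stores.geojson")

cat(sprintf("patients: %d, food insecure: %d (%.1f%%)\n",
            nrow(city$patients), sum(city$patients$food_insecure),
            100 * mean(city$patients$food_insecure)))
cat(sprintf("stores: %d, total NEMS-S mean %.1f sd %.1f range [%d, %d]\n",
            nrow(city$stores), mean(city$stores$total), sd(city$stores$total),
            min(city$stores$total), max(city$stores$total)))
cat(sprintf("tracts: %d, no-vehicle %% third quartile %.1f\n",
            nrow(city$tracts), quantile(city$tracts$pct_no_vehicle, 0.75)))
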