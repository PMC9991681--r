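#!/usr/bin/env Rscript
# Stage 2: score the store table from its NEMS-S item responses.
#
# Re-derives availability (0-30), price (-9-18), quality (0-6) sub-scores
# and the total (-9-54) from the raw item columns, so downstream stages
# depend only on the scorer, and reports the score distribution.

suppressMessages(library(foodaccess))

stores <- read.csv("results/city/stores.csv", stringsAsFactors = FALSE)
stores <- score_stores(stores)
write.csv(stores, "results/stores_scored.csv", row.names = FALSE)

cat(sprintf("scored %d stores\n", nrow(stores)))
for (v in c("availability", "price", "quality", "total")) {
  cat(sprintf("  %-12s mean %5.1f sd %4.1f range [%d, %d]\n", v,
              mean(stores[[v]]), sd(stores[[v]]),
              min(stores[[v]]), max(stores[[v]])))
}
cat(sprintf("stores with top quality score (6): %d of %d\n",
            sum(stores$quality == 6), nrow(stores)))
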