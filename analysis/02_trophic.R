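#!/usr/bin/env Rscript
# Convert d15N to trophic position against the moose-hair baseline
# (strict herbivore, trophic level 2; enrichment 3.4 permil per level)
# and validate the sample table.

library(dietspec)

baseline <- baseline_summary(read.csv("results/data/baseline.csv")$d15n)
print(baseline)

samples <- read_isotope_table("results/data/samples.csv",
                              baseline = baseline)
write_isotope_table(samples, "results/samples_tp.csv")

message(sprintf("%d samples converted; trophic position range %.2f-%.2f (median %.2f)",
                nrow(samples), min(samples$trophic_position),
                max(samples$trophic_position),
                median(samples$trophic_position)))
per_id <- tapply(samples$trophic_position, samples$bear_id, median)
message(sprintf("individual median trophic positions span %.2f-%.2f",
                min(per_id), max(per_id)))
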