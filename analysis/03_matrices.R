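#!/usr/bin/env Rscript
# Build the covariance structures for the animal model: the additive
# genetic relationship matrix A from the pedigree (pruned to phenotyped
# daughters), the environmental-similarity matrix E from home-range
# habitat composition, and the spatial-distance alternative S.

library(dietspec)

samples <- read.csv("results/samples_tp.csv")
ped <- read_pedigree("results/data/pedigree.csv")
hr <- read_home_ranges("results/data/home_ranges.csv")

daughters <- sort(unique(samples$bear_id[samples$sex == "female" &
                                           !is.na(samples$mother_id)]))
A <- phenotyped_amatrix(ped, daughters)
write_matrix_csv(A, "results/relationship_matrix.csv")
off <- A[lower.tri(A)]
message(sprintf("A over %d daughters: %d nonzero relationships, max %.2f",
                nrow(A), sum(off > 0), max(off)))

hr_d <- hr[hr$bear_id %in% daughters, ]
E <- env_similarity(hr_d)
write_matrix_csv(E, "results/env_similarity.csv")
message(sprintf("E: mean off-diagonal similarity %.2f",
                mean(E[lower.tri(E)])))

sp <- spatial_similarity(hr_d)
write_matrix_csv(sp$similarity, "results/spatial_similarity.csv")
message(sprintf("home-range centroids: %d pairwise distances, %.2f-%.0f km, median %.0f km",
                sp$summary["n_pairs"], sp$summary["min"],
                sp$summary["max"], sp$summary["median"]))

dam <- ped$dam[match(daughters, ped$id)]
settled <- daughters[dam %in% hr$bear_id]
dx <- hr$centroid_x_km[match(settled, hr$bear_id)] -
  hr$centroid_x_km[match(dam[dam %in% hr$bear_id], hr$bear_id)]
dy <- hr$centroid_y_km[match(settled, hr$bear_id)] -
  hr$centroid_y_km[match(dam[dam %in% hr$bear_id], hr$bear_id)]
message(sprintf("daughter natal dispersal: median %.2f km (range %.1f-%.1f)",
                median(sqrt(dx^2 + dy^2)), min(sqrt(dx^2 + dy^2)),
                max(sqrt(dx^2 + dy^2))))
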