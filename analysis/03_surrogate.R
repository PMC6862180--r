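#!/usr/bin/env Rscript
# Step 3 -- desirabilities and the neural-network surrogate.
#
# Maps the 36 cell-mean response pairs to desirabilities (d1: EDWIN-C,
# larger-the-better per the published equations; d2: system time,
# smaller-the-better), splits 29/7 train/test, and searches single-hidden-
# layer networks with 2..8 hidden nodes (momentum 0.65, bold-driver
# learning rate in [0.01, 0.5], 10000 iterations) for the minimal
# test-RMSE structure.
# Inputs: results/cell_means.csv. Outputs:
# results/surrogate_comparison.csv, results/surrogate_best.json,
# results/cells_desirability.csv.

suppressPackageStartupMessages(library(emsopt))

seed_split <- 2L
seed_nn <- 3L
cells <- read.csv("results/cell_means.csv")
cells <- add_desirabilities(cells)
write.csv(cells, "results/cells_desirability.csv", row.names = FALSE)

ttab <- build_training_table(cells, split = 0.8, seed = seed_split)
search <- architecture_search(ttab, hidden_range = 2:8,
                              iterations = 10000L, seed = seed_nn)
write.csv(search$comparison, "results/surrogate_comparison.csv",
          row.names = FALSE)
write_surrogate(search$best, "results/surrogate_best.json")

print(search$comparison)
best <- search$comparison[which.min(search$comparison$rmse_test), ]
cat(sprintf("selected structure %s (test RMSE %.4f)\n",
            best$structure, best$rmse_test))
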