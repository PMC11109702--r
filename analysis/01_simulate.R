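#!/usr/bin/env Rscript
# Stage 1: generate the synthetic HDSS register used by the whole analysis.
# The defaults emulate a rural northern-Malawi surveillance population:
# patrilocal clans of founder households, competing demographic hazards
# (fertility, mortality, marriage, divorce, fostering, relocation, external
# migration) over 2004-2017, and annual survey rounds.

suppressMessages(library(hdssmove))

seed <- 20040101
dir.create("results/register", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, n_founder_households = 150)
reg <- simulate_register(cfg)
write_register(reg, "results/register")
writeLines(as.character(cfg$period), "results/register/period.txt")

gt <- ground_truth_moves(reg)
cat(sprintf("register: %d persons, %d households, %d episodes\n",
            nrow(reg$persons), nrow(reg$households), nrow(reg$episodes)))
cat(sprintf("ground-truth relocation events: %d (%.1f%% leaving the area)\n",
            nrow(gt), 100 * mean(gt$direction == "out")))
cat("written to results/register/\n")
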