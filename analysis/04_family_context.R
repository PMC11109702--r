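#!/usr/bin/env Rscript
# Stage 4: kinship graph and family variables. Every person-quarter gets a
# household-composition category from the rule cascade, five kin-nearby
# flags (relatives within 250 m but outside the household) and seven
# household age-band counts.

suppressMessages(library(hdssmove))

reg <- read_register("results/register")
period <- as.Date(readLines("results/register/period.txt"))
panel <- build_panel(reg, period = period)

fc <- build_family_context(reg, panel, radius_m = 250)
write.csv(fc, "results/family_context.csv", row.names = FALSE, na = "")

cat(sprintf("family context: %d person-quarters\n", nrow(fc)))
cat("composition categories:\n")
print(sort(table(fc$composition), decreasing = TRUE))
cat("share with kin nearby (250 m):\n")
print(round(colMeans(fc[, grep("^nearby_", names(fc))]), 3))
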