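#!/usr/bin/env Rscript
# Stage 2: reduce the episodic register to one observation per person per
# quarter (15th of each quarter's middle month) and attach time-varying
# covariates: age, life stage, survey-derived education and marital fields,
# tarmac distance and the 250 m population-density tertiles.

suppressMessages(library(hdssmove))

reg <- read_register("results/register")
period <- as.Date(readLines("results/register/period.txt"))
panel <- build_panel(reg, period = period)
write.csv(panel, "results/panel.csv", row.names = FALSE, na = "")

cat(sprintf("panel: %d person-quarters over %d quarters, %d persons\n",
            nrow(panel), length(unique(panel$quarter_date)),
            length(unique(panel$person_id))))
print(table(panel$sex, panel$life_stage))
cat(sprintf("density tertile boundaries: %s residents within 250 m\n",
            paste(attr(population_density(panel), "breaks"),
                  collapse = " / ")))
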