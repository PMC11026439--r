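#!/usr/bin/env Rscript
# Build the synthetic study cohort: 30 stocks, half with a qualifying
# collapse-and-recovery trajectory, the rest cycling through the three
# non-qualifying archetypes (too short, no recovery after the minimum, no
# high biomass before it), plus a gridded monthly temperature field for the
# first stock's distribution square. Writes everything under results/.

library(collapseshift)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 2026L
out <- "results"
dir.create(out, showWarnings = FALSE)

cohort <- simulate_cohort(30, qualifying_fraction = 0.5, seed = seed)
write_cohort(cohort, file.path(out, "cohort"))

st1 <- cohort$stocks[[1]]
field <- simulate_sst_field(st1$bbox, st1$data$year, seed = seed + 1L,
                            annual_means = st1$data$sst_c)
write_sst_field(field, file.path(out, "sst"))

write.csv(cohort$truth, file.path(out, "truth_table.csv"), row.names = FALSE)

cat(sprintf("wrote %d stocks (%d intended qualifying) to %s/cohort\n",
            length(cohort$stocks), sum(cohort$truth$qualifies), out))
cat(sprintf("archetypes: %s\n",
            paste(names(table(cohort$truth$archetype)),
                  table(cohort$truth$archetype), sep = "=", collapse = ", ")))
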