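#!/usr/bin/env Rscript
# Apply the collapse-qualification screen to the simulated cohort and
# compare the verdicts with the generator's truth table.

library(collapseshift)

cohort <- read_cohort("results/cohort")
truth <- read.csv("results/truth_table.csv")

rows <- lapply(cohort$stocks, function(st) {
  cw <- check_collapse(st)
  data.frame(stock_id = st$stock_id, qualifies = cw$qualifies,
             min_year = cw$min_year, max_biomass = cw$max_biomass,
             threshold = cw$threshold,
             failure_reasons = paste(cw$failure_reasons, collapse = ";"))
})
verdicts <- do.call(rbind, rows)
write.csv(verdicts, "results/selection.csv", row.names = FALSE)

m <- merge(verdicts, truth[c("stock_id", "qualifies")], by = "stock_id",
           suffixes = c("", "_truth"))
agree <- sum(m$qualifies == m$qualifies_truth)
cat(sprintf("selected %d of %d stocks; verdicts agree with truth for %d/%d\n",
            sum(verdicts$qualifies), nrow(verdicts), agree, nrow(m)))
print(table(subset(verdicts, !qualifies)$failure_reasons))
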