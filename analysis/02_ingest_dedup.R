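#!/usr/bin/env Rscript
# Ingest the simulated quarterly extracts, deduplicate case versions (latest
# FDA acceptance date wins), build the all-of-three suspect-role cohort and
# export the descriptive characteristics table.

source(file.path("analysis", "00_common.R"))

cohort <- load_cohort()

cat(sprintf("deduplicated reports: %d (removed %d superseded versions)\n",
            cohort$n_total_db, cohort$n_removed))
cat(sprintf("pola+BR cohort: %d reports (%.2f%% of the database)\n",
            cohort$n_cohort, 100 * cohort$n_cohort / cohort$n_total_db))

chars <- demographics_summary(cohort)
readr::write_csv(chars, file.path("results", "characteristics.csv"))

serious <- chars[chars$block == "Outcome", ]
cat(sprintf("serious outcomes in cohort: %d/%d (%.1f%%)\n",
            serious$n[serious$category == "Serious outcome"],
            cohort$n_cohort,
            serious$pct[serious$category == "Serious outcome"]))
cat("wrote results/characteristics.csv\n")
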