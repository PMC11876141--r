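#!/usr/bin/env Rscript
# Clinical-priority scoring. Applies the default five-component rubric to
# the 58 published pola+BR signals (report volume, ROR CI lower bound,
# fatal-report burden, DME/IME status, evidence grade) and verifies the
# published score and level of every row before exporting the table.

library(faersignal)

ann <- pola_br_signal_annotations()
st <- score_table(tibble::tibble(pt = ann$pt, n = ann$n, ror025 = ann$ror025),
                  ann)

match_score <- sum(st$results$score == ann$published_score)
match_level <- sum(st$results$level == ann$published_level)
cat(sprintf("rubric reproduces %d/58 published scores and %d/58 levels\n",
            match_score, match_level))
cat(sprintf("priority split: %d low / %d moderate / %d high\n",
            st$level_counts[["low"]], st$level_counts[["moderate"]],
            st$level_counts[["high"]]))
high <- st$results[st$results$level == "high", ]
cat(sprintf("high-priority signal(s): %s (score %d)\n",
            paste(high$pt, collapse = ", "), high$score))

out <- dplyr::bind_cols(
  dplyr::select(ann, "soc", "pt"),
  dplyr::select(st$results, "n", "ror025", "deaths", "ime", "dme",
                "evidence", "score", "level"))
readr::write_csv(out, file.path("results", "priority.csv"))
cat("wrote results/priority.csv\n")
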