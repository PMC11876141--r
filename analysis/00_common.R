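# Shared loader for the analysis scripts: re-ingest the simulated quarterly
# extracts, deduplicate case versions and build the pola+BR cohort.

library(faersignal)

load_cohort <- function(root = file.path("results", "synthetic_faers")) {
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) == 0) {
    stop("no simulated quarters under ", root, "; run 01_simulate.R first")
  }
  bundles <- lapply(dirs, function(d) read_quarter(d, label = basename(d)))
  cases <- deduplicate(bundles)
  build_cohort(cases)
}
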