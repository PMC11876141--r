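# Hand-built micro-fixtures used across test files.

# Write a five-file quarterly extract from raw text lines and return the dir.
write_raw_quarter <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                              indi = NULL, label = "21Q3") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  defaults <- list(
    demo = "primaryid$caseid$caseversion$fda_dt$event_dt$age$age_cod$sex$wt$wt_cod$occr_country",
    drug = "primaryid$drug_seq$role_cod$drugname$prod_ai",
    reac = "primaryid$pt",
    outc = "primaryid$outc_cod",
    indi = "primaryid$indi_drug_seq$indi_pt"
  )
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi)
  for (tab in names(tabs)) {
    lines <- c(defaults[[tab]], tabs[[tab]])
    writeLines(lines, file.path(dir, sprintf("%s%s.txt", toupper(tab), label)))
  }
  dir
}

demo_line <- function(primaryid, caseid = primaryid, caseversion = 1,
                      fda_dt = "20220301", age = "", age_cod = "",
                      sex = "F", wt = "", wt_cod = "", country = "US") {
  paste(primaryid, caseid, caseversion, fda_dt, "", age, age_cod, sex,
        wt, wt_cod, country, sep = "$")
}

drug_line <- function(primaryid, seq = 1, role = "PS",
                      name = "polatuzumab vedotin", ai = toupper(name)) {
  paste(primaryid, seq, role, name, ai, sep = "$")
}

# In-memory bundle from compact per-report specs:
# reports = list(list(primaryid, caseid, caseversion, fda_dt, sex, age_years,
#                     drugs = list(c(role, name)), pts, outcomes), ...)
make_bundle <- function(reports, label = "2022Q1") {
  demo <- drug <- reac <- outc <- indi <- list()
  for (r in reports) {
    pid <- as.character(r$primaryid)
    demo[[pid]] <- tibble::tibble(
      primaryid = pid, caseid = as.character(r$caseid %||% r$primaryid),
      caseversion = as.integer(r$caseversion %||% 1),
      fda_dt = r$fda_dt %||% "20220301", event_dt = "",
      age = "", age_cod = "", sex = r$sex %||% "F", wt = "", wt_cod = "",
      occr_country = r$country %||% "US",
      fda_dt_parsed = as.Date(r$fda_dt %||% "20220301", format = "%Y%m%d"),
      age_years = r$age_years %||% NA_real_,
      weight_kg = r$weight_kg %||% NA_real_,
      report_year = as.integer(substr(r$fda_dt %||% "20220301", 1, 4))
    )
    drugs <- r$drugs %||% list(c("PS", "aspirin"))
    drug[[pid]] <- tibble::tibble(
      primaryid = pid, drug_seq = as.character(seq_along(drugs)),
      role_cod = vapply(drugs, `[[`, "", 1),
      drugname = vapply(drugs, `[[`, "", 2),
      prod_ai = toupper(vapply(drugs, `[[`, "", 2)))
    pts <- r$pts %||% "Nausea"
    reac[[pid]] <- tibble::tibble(primaryid = pid, pt = pts)
    if (length(r$outcomes %||% character(0)) > 0) {
      outc[[pid]] <- tibble::tibble(primaryid = pid, outc_cod = r$outcomes)
    }
    if (length(r$indications %||% character(0)) > 0) {
      indi[[pid]] <- tibble::tibble(primaryid = pid, indi_drug_seq = "1",
                                    indi_pt = r$indications)
    }
  }
  empty_outc <- tibble::tibble(primaryid = character(), outc_cod = character())
  empty_indi <- tibble::tibble(primaryid = character(), indi_drug_seq = character(),
                               indi_pt = character())
  new_faers_bundle(
    dplyr::bind_rows(demo), dplyr::bind_rows(drug), dplyr::bind_rows(reac),
    if (length(outc)) dplyr::bind_rows(outc) else empty_outc,
    if (length(indi)) dplyr::bind_rows(indi) else empty_indi,
    label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A regimen report spec (full pola+BR as suspects)
regimen_report <- function(primaryid, pts = "Nausea", outcomes = character(0),
                           ...) {
  list(primaryid = primaryid,
       drugs = list(c("PS", "polatuzumab vedotin"), c("SS", "bendamustine"),
                    c("SS", "rituximab")),
       pts = pts, outcomes = outcomes, ...)
}

# Cohort of n_cohort regimen reports and n_bg background reports, where
# pt appears on a_with cohort reports and c_with background reports.
make_pt_cohort <- function(a_with, n_cohort, c_with, n_bg, pt = "Sepsis") {
  reports <- c(
    lapply(seq_len(n_cohort), function(i) {
      regimen_report(100 + i, pts = if (i <= a_with) c(pt, "Nausea") else "Nausea")
    }),
    lapply(seq_len(n_bg), function(i) {
      list(primaryid = 500 + i,
           pts = if (i <= c_with) c(pt, "Headache") else "Headache")
    })
  )
  build_cohort(deduplicate(make_bundle(reports)))
}

# Closed-form Pearson chi-squared, the independent oracle
chi2_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exhaustive-enumeration Fisher two-sided p, the independent oracle
fisher_enum <- function(a, b, c, d) {
  m <- a + b          # serious margin
  n2 <- c + d         # non-serious margin
  k <- a + c          # event margin
  x <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(x, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
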