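# Synthetic FAERS-style world with known ground truth: injected drug-event
# associations at target reporting odds ratios, planted duplicate case
# versions, suspect-role structure, seriousness outcomes and demographics.

FILLER_PTS <- c("Nausea", "Headache", "Fatigue", "Rash", "Dizziness",
                "Vomiting", "Pruritus", "Insomnia")

BACKGROUND_DRUGS <- c("metformin", "lisinopril", "atorvastatin", "omeprazole",
                      "amlodipine", "levothyroxine", "sertraline", "ibuprofen",
                      "warfarin", "prednisone", "gabapentin", "furosemide",
                      "insulin glargine", "salbutamol", "apixaban", "cisplatin",
                      "paclitaxel", "methotrexate", "adalimumab", "pembrolizumab")

quarter_labels <- function(from = 2019, to = 2023, last_q = 3) {
  labs <- as.vector(outer(1:4, from:to, function(q, y) sprintf("%dQ%d", y, q)))
  labs <- sort(labs)
  labs[labs <= sprintf("%dQ%d", to, last_q)]
}

quarter_start <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  as.Date(sprintf("%d-%02d-01", y, (q - 1) * 3 + 1))
}

quarter_of_date <- function(dates) {
  ud <- sort(unique(dates))
  uq <- sprintf("%sQ%d", format(ud, "%Y"),
                (as.integer(format(ud, "%m")) - 1) %/% 3 + 1)
  uq[match(dates, ud)]
}

#' Exposure-conditional event probability for a target reporting odds ratio
#'
#' Given a background per-report event probability `p0`, returns the
#' probability `p1` inside the exposed cohort that makes the exposure odds
#' exactly `rho` times the background odds:
#' `p1 = rho * p0 / (1 - p0 + rho * p0)`.
#'
#' @param p0 Background event probability, in (0, 1).
#' @param rho Target true reporting odds ratio, > 0.
#' @return Numeric vector of cohort event probabilities.
#' @examples
#' exposure_event_prob(0.01, 5) # about 0.04808
#' @export
exposure_event_prob <- function(p0, rho) {
  stopifnot(all(rho > 0), all(p0 >= 0), all(p0 < 1))
  rho * p0 / (1 - p0 + rho * p0)
}

#' Default background catalog of null Preferred Terms
#'
#' Fifty event terms with per-report probabilities spread over
#' \[0.002, 0.02\] and true ROR 1 (no association with the cohort), so
#' false-positive-rate checks can run alongside power checks.
#'
#' @return Tibble with columns `pt`, `p0`, `rho`.
#' @export
default_pt_catalog <- function() {
  tibble::tibble(
    pt = sprintf("Null event %02d", 1:50),
    p0 = seq(0.002, 0.02, length.out = 50),
    rho = 1
  )
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' Defines the generated world: total report volume, quarter coverage with
#' report volume growing over calendar time, the fraction of reports
#' carrying the full regimen as suspects (the cohort), a fraction carrying
#' only a strict subset, the adverse-event catalog with injected
#' associations, the outcome-code distribution (about 28% serious under the
#' defaults, near the published cohort), planted duplicate case versions,
#' and demographic distributions with realistic missingness.
#'
#' @param n_reports Number of distinct cases to generate (duplicate
#'   versions come on top of this).
#' @param quarters Quarter labels covered by the generated extracts.
#' @param cohort_fraction Probability a case carries the full regimen with
#'   suspect roles.
#' @param partial_regimen_fraction Probability a case carries a strict
#'   subset of the regimen.
#' @param pt_catalog Tibble `pt`, `p0`, and optionally `rho` (default 1)
#'   of background event terms.
#' @param injected_signals Tibble `pt`, `p0`, `rho` of events associated
#'   with the cohort at true ROR `rho`.
#' @param serious_outcome_probs Named probabilities over the outcome codes
#'   plus `none` (no outcome row); must sum to 1.
#' @param duplicate_case_fraction Fraction of cases that receive extra
#'   versions.
#' @param duplicate_versions_probs Distribution of the number of extra
#'   versions per duplicated case (names "1", "2", ...).
#' @param sex_probs,country_probs Named sampling probabilities.
#' @param age_mean,age_sd,age_missing Age model (years) and missingness.
#' @param weight_mean,weight_sd,weight_missing Weight model (kg).
#' @param seed Integer seed; the generated world is fully reproducible
#'   from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_reports = 20000,
                             quarters = quarter_labels(2019, 2023, 3),
                             cohort_fraction = 0.02,
                             partial_regimen_fraction = 0.01,
                             pt_catalog = default_pt_catalog(),
                             injected_signals = tibble::tibble(
                               pt = "Pancytopenia", p0 = 0.01, rho = 5),
                             serious_outcome_probs = c(
                               DE = 0.05, LT = 0.03, HO = 0.18, DS = 0.02,
                               CA = 0.005, RI = 0.015, OT = 0.30, none = 0.40),
                             duplicate_case_fraction = 0.05,
                             duplicate_versions_probs = c("1" = 0.8, "2" = 0.2),
                             sex_probs = c(F = 0.31, M = 0.44, UNK = 0.25),
                             country_probs = c(US = 0.02, IT = 0.13, CA = 0.004,
                                               GB = 0.20, DE = 0.16, FR = 0.17,
                                               JP = 0.16, ES = 0.156),
                             age_mean = 60, age_sd = 14, age_missing = 0.5,
                             weight_mean = 73, weight_sd = 15,
                             weight_missing = 0.6,
                             seed = 1L) {
  pt_catalog <- tibble::as_tibble(pt_catalog)
  if (!"rho" %in% names(pt_catalog)) pt_catalog$rho <- 1
  injected_signals <- tibble::as_tibble(injected_signals)
  catalog <- dplyr::bind_rows(pt_catalog, injected_signals)
  cfg <- list(
    n_reports = as.integer(n_reports), quarters = quarters,
    cohort_fraction = cohort_fraction,
    partial_regimen_fraction = partial_regimen_fraction,
    catalog = catalog,
    serious_outcome_probs = serious_outcome_probs,
    duplicate_case_fraction = duplicate_case_fraction,
    duplicate_versions_probs = duplicate_versions_probs,
    sex_probs = sex_probs, country_probs = country_probs,
    age_mean = age_mean, age_sd = age_sd, age_missing = age_missing,
    weight_mean = weight_mean, weight_sd = weight_sd,
    weight_missing = weight_missing,
    seed = as.integer(seed)
  )
  probs <- c(cohort_fraction, partial_regimen_fraction,
             duplicate_case_fraction, age_missing, weight_missing,
             catalog$p0, serious_outcome_probs, sex_probs, country_probs,
             duplicate_versions_probs)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cohort_fraction + partial_regimen_fraction > 1) {
    stop("cohort_fraction + partial_regimen_fraction must not exceed 1", call. = FALSE)
  }
  if (any(catalog$rho <= 0)) stop("injected true RORs must be positive", call. = FALSE)
  if (abs(sum(serious_outcome_probs) - 1) > 1e-8) {
    stop("serious_outcome_probs must sum to 1", call. = FALSE)
  }
  if (anyDuplicated(tolower(catalog$pt))) {
    stop("duplicate PT in catalog / injected signals", call. = FALSE)
  }
  if (n_reports < 1) stop("n_reports must be positive", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Analytic expected contingency tables for a generator configuration
#'
#' For each catalog PT, the expected deduplicated 2x2 cell counts: with
#' `n` cases, cohort fraction `f`, and cohort event probability `p1` from
#' [exposure_event_prob()], `E[a] = n f p1`, `E[b] = n f (1 - p1)`,
#' `E[c] = n (1 - f) p0`, `E[d] = n (1 - f)(1 - p0)`.
#'
#' @param config A `generator_config`.
#' @return Tibble `pt`, `p0`, `p1`, `rho`, `Ea`, `Eb`, `Ec`, `Ed`.
#' @export
expected_tables <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_reports
  f <- config$cohort_fraction
  cat <- config$catalog
  p1 <- exposure_event_prob(cat$p0, cat$rho)
  tibble::tibble(
    pt = cat$pt, p0 = cat$p0, p1 = p1, rho = cat$rho,
    Ea = n * f * p1, Eb = n * f * (1 - p1),
    Ec = n * (1 - f) * cat$p0, Ed = n * (1 - f) * (1 - cat$p0)
  )
}

# sample() without the length-1 surprise
sample_vec <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

#' Generate a synthetic FAERS-style world
#'
#' Draws `n_reports` base cases (quarter, demographics, regimen membership,
#' reactions, outcomes, indications), plants duplicate case versions that
#' differ only in `primaryid`, `caseversion` and a later `fda_dt`, and
#' packages everything as quarterly `faers_bundle`s plus a ground-truth
#' record. Injected events occur with probability `p1` (the exposure odds
#' transform of `p0` at the target ROR) inside the cohort and `p0` outside.
#'
#' @param config A `generator_config`.
#' @param seed Optional override of `config$seed`.
#' @return List with `bundles` (list of `faers_bundle`, one per non-empty
#'   quarter) and `truth`: the catalog with `p0`/`p1`/`rho`, realized
#'   per-PT base counts (`a`, `c`), cohort `caseid`s, duplicated
#'   `caseid`s, the number of planted extra versions, and the expected
#'   tables.
#' @export
generate_faers <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_reports
  qs <- config$quarters

  caseid <- 1000000L + seq_len(n)
  primaryid <- caseid * 100 + 1

  # report volume grows linearly across quarters
  q_idx <- sample.int(length(qs), n, replace = TRUE, prob = seq_along(qs))
  qstart <- quarter_start(qs)
  fda_dt <- qstart[q_idx] + floor(stats::runif(n, 0, 90))

  member <- sample_vec(c("full", "partial", "background"), n,
                       prob = c(config$cohort_fraction,
                                config$partial_regimen_fraction,
                                1 - config$cohort_fraction -
                                  config$partial_regimen_fraction))
  cohort <- member == "full"

  # formatting dates once per unique day keeps large n fast
  fmt_dates <- function(d) {
    ud <- sort(unique(d))
    format(ud, "%Y%m%d")[match(d, ud)]
  }

  sex <- sample_vec(names(config$sex_probs), n, prob = config$sex_probs)
  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18), 95))
  age[stats::runif(n) < config$age_missing] <- NA
  wt <- round(pmin(pmax(stats::rnorm(n, config$weight_mean, config$weight_sd), 35), 150), 1)
  wt[stats::runif(n) < config$weight_missing] <- NA
  country <- sample_vec(names(config$country_probs), n, prob = config$country_probs)

  demo <- tibble::tibble(
    primaryid = as.character(primaryid), caseid = as.character(caseid),
    caseversion = 1L, fda_dt = fmt_dates(fda_dt), event_dt = "",
    age = ifelse(is.na(age), "", as.character(age)),
    age_cod = ifelse(is.na(age), "", "YR"),
    sex = sex,
    wt = ifelse(is.na(wt), "", as.character(wt)),
    wt_cod = ifelse(is.na(wt), "", "KG"),
    occr_country = country
  )

  # drugs
  regimen <- pola_br_regimen()
  reg_names <- vapply(regimen, `[[`, "", 1)
  pid_chr <- demo$primaryid
  full_ids <- pid_chr[member == "full"]
  drug_full <- tibble::tibble(
    primaryid = rep(full_ids, each = 3),
    drug_seq = as.character(rep(1:3, length(full_ids))),
    role_cod = rep(c("PS", "SS", "SS"), length(full_ids)),
    drugname = rep(unname(reg_names), length(full_ids))
  )
  part_ids <- pid_chr[member == "partial"]
  drug_part <- if (length(part_ids) > 0) {
    k <- sample_vec(1:2, length(part_ids))
    comp <- lapply(k, function(ki) sample.int(3, ki))
    tibble::tibble(
      primaryid = rep(part_ids, k),
      drug_seq = as.character(unlist(lapply(k, seq_len))),
      role_cod = sample_vec(c("PS", "SS"), sum(k)),
      drugname = reg_names[unlist(comp)]
    )
  } else NULL
  bg_ids <- pid_chr[member == "background"]
  n_bg_drugs <- sample_vec(1:2, length(bg_ids))
  drug_bg <- tibble::tibble(
    primaryid = rep(bg_ids, n_bg_drugs),
    drug_seq = as.character(unlist(lapply(n_bg_drugs, seq_len))),
    role_cod = "PS",
    drugname = sample_vec(BACKGROUND_DRUGS, sum(n_bg_drugs))
  )
  # first drug of every background report is PS, extras get a sampled role
  extra_row <- duplicated(drug_bg$primaryid)
  drug_bg$role_cod[extra_row] <- sample_vec(c("SS", "C", "I"), sum(extra_row))
  drug <- dplyr::bind_rows(drug_full, drug_part, drug_bg)
  drug$prod_ai <- toupper(drug$drugname)

  # reactions: one filler PT per report, plus catalog events
  cat <- config$catalog
  p1 <- exposure_event_prob(cat$p0, cat$rho)
  reac_ids <- vector("list", nrow(cat) + 1)
  reac_ids[[1]] <- pid_chr
  realized_a <- integer(nrow(cat)); realized_c <- integer(nrow(cat))
  for (j in seq_len(nrow(cat))) {
    p <- cat$p0[j] + (p1[j] - cat$p0[j]) * cohort
    hit <- stats::runif(n) < p
    realized_a[j] <- sum(hit & cohort)
    realized_c[j] <- sum(hit & !cohort)
    reac_ids[[j + 1]] <- pid_chr[hit]
  }
  reac <- tibble::tibble(
    primaryid = unlist(reac_ids, use.names = FALSE),
    pt = rep(c(NA_character_, cat$pt), lengths(reac_ids)))
  reac$pt[seq_len(n)] <- sample_vec(FILLER_PTS, n)

  # outcomes
  outc_code <- sample_vec(names(config$serious_outcome_probs), n,
                          prob = config$serious_outcome_probs)
  has_outc <- outc_code != "none"
  outc <- tibble::tibble(primaryid = pid_chr[has_outc],
                         outc_cod = outc_code[has_outc])

  # indications
  dlbcl <- c("Diffuse large B-cell lymphoma",
             "Diffuse large B-cell lymphoma refractory",
             "Diffuse large B-cell lymphoma recurrent")
  indi_cohort <- tibble::tibble(
    primaryid = full_ids, indi_drug_seq = "1",
    indi_pt = sample_vec(dlbcl, length(full_ids), prob = c(0.83, 0.11, 0.06)))
  bg_with_indi <- bg_ids[stats::runif(length(bg_ids)) < 0.8]
  indi_bg <- tibble::tibble(
    primaryid = bg_with_indi, indi_drug_seq = "1",
    indi_pt = sample_vec(c("Hypertension", "Diabetes mellitus", "Depression",
                           "Rheumatoid arthritis", "Asthma"),
                         length(bg_with_indi)))
  indi <- dplyr::bind_rows(indi_cohort, indi_bg)

  # planted duplicate versions: same clinical content, new primaryid,
  # incremented caseversion, later fda_dt
  n_dup <- round(config$duplicate_case_fraction * n)
  dup_rows <- if (n_dup > 0) sample.int(n, n_dup) else integer(0)
  extra <- list(demo = NULL, drug = NULL, reac = NULL, outc = NULL, indi = NULL)
  n_versions <- 0L
  if (n_dup > 0) {
    kver <- as.integer(sample_vec(names(config$duplicate_versions_probs), n_dup,
                                  prob = config$duplicate_versions_probs))
    rep_rows <- rep(dup_rows, kver)
    version <- unlist(lapply(kver, function(k) 1 + seq_len(k)))
    n_versions <- length(rep_rows)
    lag <- unlist(lapply(kver, function(k) cumsum(30 + floor(stats::runif(k, 0, 150)))))
    new_dt <- pmin(fda_dt[rep_rows] + lag, max(qstart) + 89)
    d_demo <- demo[rep_rows, , drop = FALSE]
    old_pid <- d_demo$primaryid
    d_demo$primaryid <- as.character(as.numeric(d_demo$caseid) * 100 + version)
    d_demo$caseversion <- as.integer(version)
    d_demo$fda_dt <- fmt_dates(new_dt)
    # replicate child rows once per extra version of their case
    uniq_old <- unique(old_pid)
    ver_by_old <- split(seq_along(old_pid), factor(old_pid, levels = uniq_old))
    remap <- function(tab) {
      m <- match(tab$primaryid, uniq_old)
      hit <- which(!is.na(m))
      if (length(hit) == 0) return(tab[0, , drop = FALSE])
      vers <- ver_by_old[m[hit]]
      out <- tab[rep(hit, lengths(vers)), , drop = FALSE]
      out$primaryid <- d_demo$primaryid[unlist(vers, use.names = FALSE)]
      out
    }
    extra <- list(demo = d_demo, drug = remap(drug), reac = remap(reac),
                  outc = remap(outc), indi = remap(indi))
  }

  demo_all <- dplyr::bind_rows(demo, extra$demo)
  drug_all <- dplyr::bind_rows(drug, extra$drug)
  reac_all <- dplyr::bind_rows(reac, extra$reac)
  outc_all <- dplyr::bind_rows(outc, extra$outc)
  indi_all <- dplyr::bind_rows(indi, extra$indi)

  # attach the typed columns read_quarter would derive
  dt_all <- c(fda_dt, if (n_dup > 0) new_dt else as.Date(character(0)))
  demo_all$fda_dt_parsed <- dt_all
  demo_all$age_years <- suppressWarnings(as.numeric(demo_all$age))
  demo_all$weight_kg <- suppressWarnings(as.numeric(demo_all$wt))

  # split into quarterly bundles by FDA acceptance date, one pass per table
  q_of <- factor(quarter_of_date(dt_all))
  demo_all$report_year <- as.integer(substr(as.character(q_of), 1, 4))
  child_split <- function(tab) {
    q <- q_of[match(tab$primaryid, demo_all$primaryid)]
    split(seq_len(nrow(tab)), q)
  }
  demo_idx <- split(seq_len(nrow(demo_all)), q_of)
  drug_idx <- child_split(drug_all); reac_idx <- child_split(reac_all)
  outc_idx <- child_split(outc_all); indi_idx <- child_split(indi_all)
  bundles <- lapply(levels(q_of), function(q) {
    new_faers_bundle(
      demo_all[demo_idx[[q]], , drop = FALSE],
      drug_all[drug_idx[[q]], , drop = FALSE],
      reac_all[reac_idx[[q]], , drop = FALSE],
      outc_all[outc_idx[[q]], , drop = FALSE],
      indi_all[indi_idx[[q]], , drop = FALSE],
      label = q)
  })

  truth <- list(
    catalog = tibble::tibble(pt = cat$pt, p0 = cat$p0, p1 = p1, rho = cat$rho,
                             a = realized_a, c = realized_c),
    cohort_caseids = demo$caseid[cohort],
    n_cohort_true = sum(cohort),
    n_reports = n,
    duplicate_caseids = demo$caseid[dup_rows],
    n_duplicate_versions = n_versions,
    expected = expected_tables(config)
  )
  list(bundles = bundles, truth = truth)
}
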