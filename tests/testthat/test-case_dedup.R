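# Deduplication, seriousness classification, cohort construction and
# descriptive characteristics.

test_that("the version with the most recent FDA acceptance date is retained", {
  b <- make_bundle(list(
    list(primaryid = 10001, caseid = 100, caseversion = 1, fda_dt = "20210101",
         pts = "Pyrexia"),
    list(primaryid = 10002, caseid = 100, caseversion = 2, fda_dt = "20220301",
         pts = "Sepsis"),
    list(primaryid = 20001, caseid = 200, fda_dt = "20211111")))
  cases <- deduplicate(b)
  expect_equal(nrow(cases$demo), 2)
  expect_equal(cases$n_removed, 1)
  kept <- cases$demo[cases$demo$caseid == "100", ]
  expect_equal(kept$primaryid, "10002")
  # child rows follow the retained version
  expect_equal(cases$reac$pt[cases$reac$primaryid == "10002"], "Sepsis")
  expect_false("10001" %in% cases$reac$primaryid)
})

test_that("equal acceptance dates break ties toward the larger primaryid,
           independent of input order", {
  r1 <- list(primaryid = 30001, caseid = 300, fda_dt = "20220501", pts = "A1")
  r2 <- list(primaryid = 30009, caseid = 300, fda_dt = "20220501", pts = "A2")
  for (reports in list(list(r1, r2), list(r2, r1))) {
    cases <- deduplicate(make_bundle(reports))
    expect_equal(cases$demo$primaryid, "30009")
  }
})

test_that("deduplication is idempotent and order-independent", {
  cfg <- generator_config(n_reports = 400, duplicate_case_fraction = 0.2,
                          seed = 9)
  g <- generate_faers(cfg)
  cases1 <- deduplicate(g$bundles)
  cases2 <- deduplicate(rev(g$bundles))
  expect_equal(cases1$demo$primaryid, cases2$demo$primaryid)
  # planted duplicate versions are exactly what dedup removes
  expect_equal(cases1$n_removed, g$truth$n_duplicate_versions)
  # idempotence: re-wrapping the retained set changes nothing
  again <- deduplicate(new_faers_bundle(cases1$demo, cases1$drug, cases1$reac,
                                        cases1$outc, cases1$indi))
  expect_equal(again$demo$primaryid, cases1$demo$primaryid)
  expect_equal(again$n_removed, 0)
})

test_that("retained duplicates carry the original clinical content", {
  cfg <- generator_config(n_reports = 300, duplicate_case_fraction = 0.3,
                          seed = 21)
  g <- generate_faers(cfg)
  cases <- deduplicate(g$bundles)
  base <- g$bundles
  all_reac <- dplyr::bind_rows(lapply(base, `[[`, "reac"))
  for (cid in utils::head(g$truth$duplicate_caseids, 5)) {
    kept_pid <- cases$demo$primaryid[cases$demo$caseid == cid]
    orig_pid <- as.character(as.numeric(cid) * 100 + 1)
    expect_false(kept_pid == orig_pid)  # a later version won
    kept_pts <- sort(unique(cases$reac$pt[cases$reac$primaryid == kept_pid]))
    orig_pts <- sort(unique(all_reac$pt[all_reac$primaryid == orig_pid]))
    expect_equal(kept_pts, orig_pts)
  }
})

test_that("seriousness follows the four qualifying outcome codes", {
  expect_true(classify_serious("HO"))
  expect_true(classify_serious(c("OT", "DE")))
  expect_false(classify_serious(c("OT", "CA")))
  expect_false(classify_serious(character(0)))
  expect_equal(classify_serious(list("HO", c("CA", "RI"), "LT")),
               c(TRUE, FALSE, TRUE))
})

test_that("cohort membership requires every component as a suspect", {
  b <- make_bundle(list(
    regimen_report(1),
    list(primaryid = 2,  # bendamustine only concomitant
         drugs = list(c("PS", "polatuzumab vedotin"), c("C", "bendamustine"),
                      c("PS", "rituximab"))),
    list(primaryid = 3, drugs = list(c("PS", "polatuzumab vedotin"))),
    list(primaryid = 4,  # trade names count via the synonym sets
         drugs = list(c("PS", "Polivy"), c("SS", "Treanda"), c("SS", "Rituxan"))),
    list(primaryid = 5, drugs = list(c("PS", "aspirin")))))
  coh <- build_cohort(deduplicate(b))
  got <- coh$demo$in_cohort[order(coh$demo$primaryid)]
  expect_equal(got, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(coh$n_cohort, 2)
  expect_equal(coh$n_total_db, 5)
})

test_that("any-k-of-n membership and synonym monotonicity behave as documented", {
  b <- make_bundle(list(
    list(primaryid = 2,
         drugs = list(c("PS", "polatuzumab vedotin"), c("C", "bendamustine"),
                      c("PS", "rituximab"))),
    list(primaryid = 5, drugs = list(c("PS", "asprin-misspelt")))))
  cases <- deduplicate(b)
  # with k = 2 the polatuzumab+rituximab report joins the cohort
  coh2 <- build_cohort(cases, require_k = 2)
  expect_equal(coh2$n_cohort, 1)
  # enlarging a synonym set never shrinks the cohort
  reg <- pola_br_regimen()
  base_n <- build_cohort(cases, regimen = reg, require_k = 1)$n_cohort
  reg$polatuzumab <- c(reg$polatuzumab, "asprin-misspelt")
  expect_gte(build_cohort(cases, regimen = reg, require_k = 1)$n_cohort, base_n)
  expect_error(build_cohort(cases, regimen = list()), "at least one")
})

test_that("age bins follow the <18 / 18-65 / >65 convention, 65 inclusive", {
  reports <- lapply(1:4, function(i) {
    r <- regimen_report(i)
    r$age_years <- c(17, 30, 65, NA)[i]
    r
  })
  coh <- build_cohort(deduplicate(make_bundle(reports)))
  tab <- demographics_summary(coh)
  age <- tab[tab$block == "Age (years)", ]
  expect_equal(age$n[match(c("<18", "18-65", ">65", "Unknown"), age$category)],
               c(1L, 2L, 0L, 1L))
})

test_that("characteristics blocks are internally consistent on synthetic data", {
  cfg <- generator_config(n_reports = 3000, seed = 14)
  g <- generate_faers(cfg)
  coh <- build_cohort(deduplicate(g$bundles))
  tab <- demographics_summary(coh)
  for (blk in unique(tab$block)) {
    expect_equal(sum(tab$n[tab$block == blk]), coh$n_cohort, info = blk)
    expect_equal(sum(tab$pct[tab$block == blk]), 100, tolerance = 0.1, info = blk)
  }
  # seriousness strata sum to the cohort size
  outc <- tab[tab$block == "Outcome", ]
  expect_equal(sum(outc$n), coh$n_cohort)
})

test_that("an empty cohort yields an empty characteristics table", {
  b <- make_bundle(list(list(primaryid = 1, drugs = list(c("PS", "aspirin")))))
  coh <- build_cohort(deduplicate(b))
  expect_equal(nrow(demographics_summary(coh)), 0)
})
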