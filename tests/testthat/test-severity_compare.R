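# Severe vs non-severe testing machinery: chi-squared, Fisher, test choice,
# t-tests, and the assembled comparison table.

test_that("pearson_chi2 equals the closed-form statistic, uncorrected", {
  set.seed(11)
  for (i in 1:25) {
    a <- sample(1:60, 1); b <- sample(50:500, 1)
    c <- sample(1:120, 1); d <- sample(100:1200, 1)
    got <- pearson_chi2(a, b, c, d)
    expect_equal(got$statistic, chi2_closed_form(a, b, c, d), tolerance = 1e-10)
    expect_equal(got$p_value,
                 stats::pchisq(got$statistic, df = 1, lower.tail = FALSE))
    # invariance under transposition and row/column exchange
    expect_equal(pearson_chi2(a, c, b, d)$statistic, got$statistic)
    expect_equal(pearson_chi2(b, a, d, c)$statistic, got$statistic)
    expect_equal(pearson_chi2(c, d, a, b)$statistic, got$statistic)
  }
  # proportional rows mean independence: statistic 0, p 1
  ind <- pearson_chi2(10, 90, 20, 180)
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  expect_error(pearson_chi2(0, 0, 5, 10), "zero margin")
})

test_that("fisher_exact matches exhaustive hypergeometric enumeration", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(8:60, 1)
    a <- sample(0:min(n, 15), 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- max(n - a - b - c, 0)
    p <- fisher_exact(a, b, c, d)$p_value
    expect_equal(p, min(fisher_enum(a, b, c, d), 1), tolerance = 1e-10)
  }
  # all 16 events in one stratum is strong evidence of association
  expect_lt(fisher_exact(0, 474, 16, 1107)$p_value, 0.01)
  # empty event row carries no information
  expect_equal(fisher_exact(0, 40, 0, 70)$p_value, 1)
})

test_that("the expected-count rule picks Fisher below 5 and Pearson at 5", {
  # PT total 10 on strata 474/1123: expected serious cell 2.97
  expect_equal(choose_test(3, 471, 7, 1116), "fisher")
  # PT total 52 on the same strata: all expected counts above 5
  expect_equal(choose_test(26, 448, 26, 1097), "pearson")
  # expected count of exactly 5.0 stays with Pearson
  expect_equal(choose_test(5, 45, 5, 45), "pearson")
})

test_that("pearson and fisher broadly agree on large balanced tables", {
  tables <- list(c(300, 1700, 280, 1720), c(500, 1500, 520, 1480),
                 c(400, 1600, 430, 1570), c(250, 750, 270, 730),
                 c(600, 2400, 630, 2370))
  for (tb in tables) {
    pp <- pearson_chi2(tb[1], tb[2], tb[3], tb[4])$p_value
    pf <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$p_value
    expect_lt(abs(pp - pf) / pf, 0.10)
  }
})

test_that("welch_t matches the textbook formula and handles missing values", {
  x <- c(61, 58, 70, 55, 64); y <- c(57, 60, 52, 66)
  got <- welch_t(x, y)
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  t_hand <- (mean(x) - mean(y)) / se
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  df_hand <- se^4 / ((stats::var(x) / 5)^2 / 4 + (stats::var(y) / 4)^2 / 3)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # missing values dropped per sample
  expect_equal(welch_t(c(x, NA), c(NA, y))$statistic, got$statistic)
  expect_error(welch_t(c(1, NA), y), "two non-missing")
})

test_that("compare_all assembles counts, test choice and demographics rows", {
  reports <- c(
    lapply(1:30, function(i) {
      r <- regimen_report(i, pts = if (i <= 12) "Sepsis" else "Pyrexia",
                          outcomes = if (i <= 15) "HO" else character(0))
      r$age_years <- 50 + i %% 20
      r$sex <- if (i %% 2 == 0) "M" else "F"
      r
    }),
    lapply(31:60, function(i) list(primaryid = i))
  )
  coh <- build_cohort(deduplicate(make_bundle(reports)))
  res <- compare_all(coh, min_count = 3)
  sepsis <- res[res$variable == "Sepsis", ]
  expect_equal(sepsis$serious + sepsis$non_serious, 12L)
  expect_true(all(res$test_used[res$variable %in% c("Sepsis", "Pyrexia")] %in%
                    c("pearson", "fisher")))
  expect_true("sex (male)" %in% res$variable)
  expect_equal(res$test_used[res$variable == "age_years"], "t")
  # the reported test matches the expected-count rule applied to the counts
  n_serious <- sum(coh$demo$serious[coh$demo$in_cohort])
  n_non <- coh$n_cohort - n_serious
  for (v in c("Sepsis", "Pyrexia")) {
    row <- res[res$variable == v, ]
    expect_equal(row$test_used,
                 choose_test(row$serious, n_serious - row$serious,
                             row$non_serious, n_non - row$non_serious))
  }
})

test_that("with seriousness independent of events, small p-values stay rare", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- generator_config(n_reports = 8000, cohort_fraction = 0.3,
                            duplicate_case_fraction = 0, seed = 400 + s)
    g <- generate_faers(cfg)
    coh <- build_cohort(deduplicate(g$bundles))
    res <- compare_all(coh, min_count = 10)
    pts <- res[grepl("^Null event|^Pancytopenia", res$variable) &
                 !res$degenerate, ]
    hits <- hits + sum(pts$p_value < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(pts$p_value))
  }
  expect_lte(hits / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("a cohort with no serious cases yields degenerate flagged rows", {
  reports <- lapply(1:12, function(i) regimen_report(i, pts = "Sepsis"))
  coh <- build_cohort(deduplicate(make_bundle(reports)))
  res <- compare_all(coh, min_count = 3)
  expect_true(all(res$degenerate[res$variable == "Sepsis"]))
})
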