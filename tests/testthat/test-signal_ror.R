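# ROR point estimate, Woolf interval, contingency construction and the
# signal criterion.

test_that("ror_ci matches the hand-evaluated Woolf computation", {
  # independent evaluation: log(11) = 2.397895, se = sqrt(0.1 + 1/90 +
  # 0.01 + 1/9900) = 0.3481553, bounds exp(2.397895 -/+ 1.96*0.3481553)
  ci <- ror_ci(10, 90, 100, 9900)
  expect_equal(ci$ror, 11.0, tolerance = 1e-12)
  expect_equal(ci$ror_lo, 5.5595846, tolerance = 1e-7)
  expect_equal(ci$ror_hi, 21.7642158, tolerance = 1e-7)
})

test_that("ror_ci agrees with an unconditional logistic-regression oracle", {
  set.seed(42)
  for (i in 1:10) {
    a <- sample(5:40, 1); b <- sample(50:400, 1)
    c <- sample(20:200, 1); d <- sample(1000:8000, 1)
    ci <- ror_ci(a, b, c, d)
    # glm on the grouped 2x2 recovers log OR and its Wald interval
    fit <- stats::glm(cbind(c(a, c), c(b, d)) ~ c(1, 0), family = stats::binomial())
    est <- unname(stats::coef(fit)[2])
    se <- sqrt(stats::vcov(fit)[2, 2])
    expect_equal(log(ci$ror), est, tolerance = 1e-5)
    # the Woolf standard error is the glm Wald standard error
    woolf_se <- (log(ci$ror) - log(ci$ror_lo)) / stats::qnorm(0.975)
    expect_equal(woolf_se, se, tolerance = 1e-4)
  }
})

test_that("identical exposure odds give ROR 1 with a CI straddling 1", {
  ci <- ror_ci(5, 5, 50, 50)
  expect_equal(ci$ror, 1)
  expect_lt(ci$ror_lo, 1)
  expect_gt(ci$ror_hi, 1)
})

test_that("exchanging cohort and comparator inverts the ROR and its interval", {
  ci <- ror_ci(12, 88, 40, 960)
  inv <- ror_ci(40, 960, 12, 88)
  expect_equal(inv$ror, 1 / ci$ror)
  expect_equal(inv$ror_lo, 1 / ci$ror_hi)
  expect_equal(inv$ror_hi, 1 / ci$ror_lo)
})

test_that("ror is strictly increasing in a with the other cells fixed", {
  a <- 5:30
  r <- ror_ci(a, 100, 50, 5000)$ror
  expect_true(all(diff(r) > 0))
})

test_that("zero cells error under the strict policy and shift under Haldane", {
  expect_error(ror_ci(0, 10, 5, 100), "zero cell")
  expect_error(ror_ci(3, 10, -1, 100), "non-negative")
  h <- ror_ci(0, 10, 5, 100, zero_cell = "haldane")
  expect_equal(h$ror, (0.5 * 100.5) / (10.5 * 5.5))
  # rows without zeros are left untouched by the correction
  both <- ror_ci(c(0, 10), c(10, 90), c(5, 100), c(100, 9900),
                 zero_cell = "haldane")
  expect_equal(both$ror[2], 11.0)
})

test_that("pt_contingency counts reports with set semantics", {
  coh <- make_pt_cohort(a_with = 2, n_cohort = 3, c_with = 1, n_bg = 7)
  ct <- pt_contingency(coh, "Sepsis")
  expect_equal(ct, list(a = 2L, b = 1L, c = 1L, d = 6L))
  # a report listing the PT twice still counts once
  b <- make_bundle(list(regimen_report(1, pts = c("Sepsis", "sepsis", "Sepsis")),
                        list(primaryid = 2)))
  coh2 <- build_cohort(deduplicate(b))
  expect_equal(pt_contingency(coh2, "Sepsis")$a, 1L)
  # absent PT gives a = c = 0
  ct0 <- pt_contingency(coh, "Vertigo")
  expect_equal(ct0$a + ct0$c, 0L)
})

test_that("contingency tables conserve the database margin and match the
           generator's bookkeeping", {
  cfg <- generator_config(n_reports = 4000, seed = 33)
  g <- generate_faers(cfg)
  coh <- build_cohort(deduplicate(g$bundles))
  for (pt in c("Pancytopenia", "Null event 01", "Null event 50")) {
    ct <- pt_contingency(coh, pt)
    expect_equal(ct$a + ct$b + ct$c + ct$d, coh$n_total_db)
    tr <- g$truth$catalog[g$truth$catalog$pt == pt, ]
    expect_equal(ct$a, tr$a)
    expect_equal(ct$c, tr$c)
  }
})

test_that("detect_signals applies the report-count and CI-lower-bound criteria", {
  # 9 cohort reports with the PT stay below the default threshold
  coh <- make_pt_cohort(a_with = 9, n_cohort = 40, c_with = 4, n_bg = 400)
  sig <- detect_signals(coh)
  expect_false("Sepsis" %in% sig$pt)
  expect_true("Sepsis" %in% detect_signals(coh, min_count = 9)$pt)
  # included but non-significant when the lower bound stays at/below 1
  coh2 <- make_pt_cohort(a_with = 12, n_cohort = 120, c_with = 40, n_bg = 400)
  sig2 <- detect_signals(coh2)
  row <- sig2[sig2$pt == "Sepsis", ]
  expect_equal(row$n, 12L)
  expect_lte(row$ror_lo, 1)
  expect_false(row$significant)
  # results ordered by SOC then n descending
  cfg <- generator_config(n_reports = 3000, seed = 2)
  g <- generate_faers(cfg)
  coh3 <- build_cohort(deduplicate(g$bundles))
  sig3 <- detect_signals(coh3, min_count = 3)
  split_n <- split(sig3$n, sig3$soc)
  expect_true(all(vapply(split_n, function(x) all(diff(x) <= 0), TRUE)))
})

test_that("null PTs are rarely flagged and an injected ROR-5 signal is found", {
  fp <- integer(0); n_eval <- integer(0); found <- logical(0)
  for (s in 1:15) {
    cfg <- generator_config(n_reports = 30000, cohort_fraction = 0.05,
                            duplicate_case_fraction = 0, seed = 100 + s)
    g <- generate_faers(cfg)
    coh <- build_cohort(deduplicate(g$bundles))
    sig <- detect_signals(coh)
    null_rows <- sig[grepl("^Null event", sig$pt), ]
    fp <- c(fp, sum(null_rows$significant))
    n_eval <- c(n_eval, nrow(null_rows))
    found <- c(found, isTRUE(sig$significant[sig$pt == "Pancytopenia"]))
  }
  fpr <- sum(fp) / sum(n_eval)
  # one-sided 2.5% criterion; allow Monte-Carlo error on top of 5%
  expect_lte(fpr, 0.05 + 3 * sqrt(0.05 * 0.95 / sum(n_eval)))
  expect_gte(mean(found), 0.9)
})
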