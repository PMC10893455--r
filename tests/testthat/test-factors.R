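# factor (risk-cofactor) contingency analysis

test_that("a toy death factor table is built correctly", {
  # 10 reports of one drug: 2 SMQ cases (1 death) + 8 non-cases (0 deaths)
  reports <- data.frame(
    report_id = sprintf("r%02d", 1:10), sex = "male", age_group = "a18_44",
    region = "europe", reporter = "physician", year = 2019L,
    serious = c("true", rep("false", 9)),
    death = c(TRUE, rep(FALSE, 9)), stringsAsFactors = FALSE)
  drugs <- data.frame(report_id = reports$report_id, drug_name = "tramadol",
                      atc_code = "N02AX02", role = "suspected")
  events <- data.frame(report_id = reports$report_id,
                       pt = c("apnoea", "bradypnoea", rep("nausea", 8)))
  db <- icsr_db(reports, drugs, events)
  ft <- build_factor_table(db, "tramadol", builtin_acrd_smq(), "death")
  expect_equal(unname(ft$counts),
               matrix(c(1, 0, 1, 8), 2, 2), ignore_attr = TRUE)
  expect_equal(ft$df, 1L)
})

test_that("unknown demographic categories are excluded and counted", {
  db <- generate_reports(test_config(1500, 41))$db
  smq <- smq_definition("mini", "narrow", c("event2", "event3"))
  ft <- build_factor_table(db, "drug1", smq, "sex")
  sub <- filter_reports(db, "drug1")
  case <- is_case(sub, smq)
  # brute-force recount
  expect_equal(ft$excluded_unknown, sum(sub$reports$sex == "unknown"))
  for (s in c("male", "female")) {
    expect_equal(ft$counts["case", s],
                 sum(sub$reports$sex == s & case), ignore_attr = TRUE)
    expect_equal(ft$counts["noncase", s],
                 sum(sub$reports$sex == s & !case), ignore_attr = TRUE)
  }
  expect_equal(sum(ft$counts), sub$n_total - ft$excluded_unknown)
})

test_that("the published age bands collapse to the three analysis strata", {
  ref <- reference_demographics()
  acrd_le17 <- sum(ref$tramadol_acrd[ref$section == "age" &
                                       ref$stratum %in% c("le11", "a12_17")])
  expect_equal(acrd_le17, 111)
  fac <- reference_factors()
  expect_equal(fac$acrd[fac$factor == "age" & fac$category == "le17"], 111)
})

test_that("chi-square matches hand computation and brute force", {
  expect_equal(unname(chi_square(matrix(c(10, 10, 10, 10), 2))["chi2"]), 0)
  expect_equal(unname(chi_square(matrix(c(10, 10, 10, 10), 2))["p_value"]),
               1)
  expect_equal(unname(chi_square(matrix(c(20, 0, 0, 20), 2))["chi2"]), 40)
  expect_equal(unname(chi_square(matrix(c(20, 0, 0, 20), 2))["df"]), 1)
  # published lethality table
  death <- matrix(c(233, 3377, 893, 136218), 2,
                  dimnames = list(c("case", "noncase"),
                                  c("death", "survival")))
  ct <- chi_square(death)
  expect_lt(ct["p_value"], 1e-4)
  expect_equal(unname(ct["chi2"]), brute_chi2(death), tolerance = 1e-12)
  # random tables against the brute-force statistic
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(8, 30) + 1, 2, 4)
    expect_equal(unname(chi_square(m)["chi2"]), brute_chi2(m),
                 tolerance = 1e-9)
  }
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("post hoc residuals match the adjusted standardized residuals", {
  m <- matrix(c(567, 24494, 437, 25557, 86, 86116, 31, 2332, 5, 1096), 2,
              dimnames = list(c("case", "noncase"),
                              c("americas", "europe", "asia", "oceania",
                                "africa")))
  ph <- posthoc(pvsignal:::factor_table_from_counts(
    m, factor_name = "region"))
  # independent computation from the standard chi-square machinery
  std <- suppressWarnings(chisq.test(m, correct = FALSE))$stdres
  expect_equal(ph$residual, unname(std[1, ]), tolerance = 1e-9)
  # the published geography effect: Americas over-reported among cases,
  # Asia under-reported
  expect_true(ph$significant[ph$category == "americas"])
  expect_equal(ph$direction[ph$category == "americas"], "over")
  expect_true(ph$significant[ph$category == "asia"])
  expect_equal(ph$direction[ph$category == "asia"], "under")
})

test_that("post hoc flags nothing on proportional tables, is NULL for k<3", {
  prop <- matrix(c(30, 300, 20, 200, 50, 500), 2)
  expect_false(any(posthoc(pvsignal:::factor_table_from_counts(
    prop))$significant))
  expect_null(posthoc(pvsignal:::factor_table_from_counts(
    matrix(c(10, 5, 20, 40), 2))))
})

test_that("an inflated category is the one flagged (simulation)", {
  set.seed(12)
  hits <- 0L
  for (s in 1:20) {
    case <- as.vector(rmultinom(1, 800, c(0.4, 0.2, 0.2, 0.2)))
    noncase <- as.vector(rmultinom(1, 4000, c(0.25, 0.25, 0.25, 0.25)))
    ph <- posthoc(pvsignal:::factor_table_from_counts(
      rbind(case, noncase)))
    if (ph$significant[1] && ph$direction[1] == "over" &&
        !any(ph$significant[-1] & ph$residual[-1] > ph$residual[1]))
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("factor summaries reproduce the published ratios", {
  fac <- reference_factors()
  get <- function(f) {
    rows <- fac[fac$factor == f, ]
    pvsignal:::factor_table_from_counts(
      rbind(rows$acrd, rows$non_acrd), factor_name = f)
  }
  s_death <- summarize_factor(get("lethality"))
  expect_equal(round_half_up(s_death$proportion_ratio[1], 1), 8.6)
  s_op <- summarize_factor(get("opioids"))
  expect_equal(round_half_up(100 * s_op$prop_case[1], 1), 31.1)
  # equal proportions give ratio 1
  s_eq <- summarize_factor(pvsignal:::factor_table_from_counts(
    matrix(c(10, 100, 30, 300), 2)))
  expect_equal(s_eq$proportion_ratio, c(1, 1))
  # ratios invariant to scaling each row
  m <- matrix(c(20, 400, 80, 1600), 2)
  s1 <- summarize_factor(pvsignal:::factor_table_from_counts(m))
  s2 <- summarize_factor(pvsignal:::factor_table_from_counts(m * c(3, 7)))
  expect_equal(s1$proportion_ratio, s2$proportion_ratio)
})

test_that("published percentages recompute from counts within 0.1 points", {
  fac <- reference_factors()
  for (f in unique(fac$factor)) {
    rows <- fac[fac$factor == f, ]
    pc <- round_half_up(100 * rows$acrd / sum(rows$acrd), 1)
    expect_true(all(abs(pc - rows$pct_acrd) <= 0.105),
                info = paste("case side:", f))
    if (f == "reporter") {
      # the source's non-case reporter column uses the unexcluded total
      pn <- round_half_up(100 * rows$non_acrd / 139595, 1)
    } else {
      pn <- round_half_up(100 * rows$non_acrd / sum(rows$non_acrd), 1)
    }
    expect_true(all(abs(pn - rows$pct_non_acrd) <= 0.105),
                info = paste("non-case side:", f))
  }
})

test_that("derived factors use the terminology predicates", {
  db <- generate_reports(test_config(2500, 47, co_medication = data.frame(
    index_drug = "drug1", co_drug = "drug3", prob = 0.3)))$db
  smq <- smq_definition("mini", "narrow", c("event2", "event3"))
  benzo <- drug_class("benzodiazepines", "drug3")
  ft <- build_factor_table(db, "drug1", smq, benzo)
  sub <- filter_reports(db, "drug1")
  users <- is_class_user(sub, benzo, "drug1")
  expect_equal(sum(ft$counts[, "user"]), sum(users), ignore_attr = TRUE)
  # abuse-style event factor
  flag_smq <- smq_definition("flags", "narrow", "event4")
  ft2 <- build_factor_table(db, "drug1", smq, flag_smq)
  expect_equal(sum(ft2$counts[, "flagged"]),
               sum(is_case(sub, flag_smq)), ignore_attr = TRUE)
  # degenerate factor: every report in one category
  none <- drug_class("opioids", "absentdrug")
  expect_error(build_factor_table(db, "drug1", smq, none), "degenerate")
})
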