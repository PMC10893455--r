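# contingency construction and the disproportionality statistics

make_table <- function(a, b, c, d) pvsignal:::new_contingency(a, b, c, d)

test_that("the four-report toy database fills one report per cell", {
  reports <- data.frame(
    report_id = c("r1", "r2", "r3", "r4"), sex = "male",
    age_group = "a18_44", region = "europe", reporter = "physician",
    year = 2019L, serious = "false", death = FALSE)
  drugs <- data.frame(
    report_id = c("r1", "r2", "r3", "r4"),
    drug_name = c("tramadol", "tramadol", "other", "other"),
    atc_code = "", role = "suspected")
  events <- data.frame(
    report_id = c("r1", "r2", "r3", "r4"),
    pt = c("apnoea", "nausea", "apnoea", "nausea"))
  db <- icsr_db(reports, drugs, events)
  t <- contingency_table(db, "tramadol", "apnoea")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
})

test_that("a report with two SMQ terms counts once in the pooled cell", {
  db <- toy_db()  # t01 carries respiratory arrest AND bradypnoea
  t <- contingency_table(db, "tramadol", builtin_acrd_smq())
  expect_equal(t$a, 2)  # t01 (once) and t02
  expect_equal(t$a + t$b,
               filter_reports(db, "tramadol")$n_total)
})

test_that("cells match the brute-force counter in both scopes", {
  db <- generate_reports(test_config(1200, 19))$db
  set.seed(1)
  pairs <- expand.grid(drug = paste0("drug", 1:4),
                       pt = paste0("event", 2:5),
                       stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), 6), ]
  for (i in seq_len(nrow(pairs))) {
    t <- contingency_table(db, pairs$drug[i], pairs$pt[i])
    bf <- brute_cells(db, pairs$drug[i], pairs$pt[i])
    expect_equal(c(t$a, t$b, t$c, t$d), unname(bf))
    to <- contingency_table(db, pairs$drug[i], pairs$pt[i],
                            scope = "opioids")
    bfo <- brute_cells(db, pairs$drug[i], pairs$pt[i], scope = "opioids")
    expect_equal(c(to$a, to$b, to$c, to$d), unname(bfo))
  }
})

test_that("PRR follows its defining ratio with a log-Wald interval", {
  t <- make_table(10, 90, 10, 890)
  p <- prr(t)
  expect_equal(unname(p["estimate"]), 9)
  se <- sqrt(1 / 10 - 1 / 100 + 1 / 10 - 1 / 900)
  expect_equal(unname(p["ci_low"]), 9 * exp(-qnorm(0.975) * se))
  expect_equal(unname(p["ci_high"]), 9 * exp(qnorm(0.975) * se))
  # equal reporting proportions give PRR 1
  expect_equal(unname(prr(make_table(5, 45, 20, 180))["estimate"]), 1)
  # no comparator events: estimate reported missing
  expect_true(is.na(prr(make_table(3, 7, 0, 100))["estimate"]))
  expect_error(prr(make_table(0, 0, 5, 5)), "undefined")
})

test_that("ROR follows its defining odds ratio and zero-cell handling", {
  t <- make_table(10, 90, 10, 890)
  r <- ror(t)
  expect_equal(unname(r["estimate"]), (10 / 90) / (10 / 890))
  expect_equal(unname(ror(make_table(20, 20, 50, 50))["estimate"]), 1)
  # zero cell: point missing, interval from +0.5 on all cells
  r0 <- ror(make_table(3, 7, 0, 100))
  expect_true(is.na(r0["estimate"]))
  expect_true(is.finite(r0["ci_low"]) && is.finite(r0["ci_high"]))
})

test_that("IC uses the 0.5-offset log2 observed-to-expected ratio", {
  # no observations and no expectation: log2(0.5/0.5) = 0
  expect_equal(unname(ic(make_table(0, 0, 0, 0))["ic"]), 0)
  # worked example at published scale
  t <- pvsignal:::new_contingency(358, 140721 - 358, 20694,
                                  23811236 - 140721 - 20694)
  v <- ic(t)
  expect_equal(unname(v["n_expected"]), 140721 * (358 + 20694) / 23811236)
  expect_equal(unname(v["ic"]),
               log2(358.5 / (unname(v["n_expected"]) + 0.5)))
  expect_lt(abs(v["ic"] - 1.52), 0.005)
  expect_lt(abs(v["ic025"] - 1.37), 0.06)
  # gamma-quantile alternative stays close to the closed form here
  vg <- ic(t, method = "gamma")
  expect_lt(abs(vg["ic025"] - v["ic025"]), 0.05)
  # IC strictly increases in the observed count at near-fixed expectation
  ics <- vapply(c(5, 10, 20, 40), function(a) {
    unname(ic(make_table(a, 10000 - a, 1000, 989000))["ic"])
  }, numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("PRR and ROR are scale-invariant but IC is not", {
  t1 <- make_table(8, 92, 40, 860)
  t5 <- make_table(40, 460, 200, 4300)
  expect_equal(prr(t1)["estimate"], prr(t5)["estimate"])
  expect_equal(ror(t1)["estimate"], ror(t5)["estimate"])
  expect_false(isTRUE(all.equal(ic(t1)["ic"], ic(t5)["ic"])))
})

test_that("the composite rule is a strict conjunction", {
  crit <- signal_criteria()
  # high PRR but only two reports: never a signal
  scr <- pvsignal:::disprop_row(make_table(2, 8, 4, 986), crit)
  expect_gt(scr$prr, 2)
  expect_false(scr$signal)
  # all ratio criteria met but IC bound below zero
  t <- make_table(4, 96, 20, 980)  # prr 2, ror ~2.04, small a
  r <- pvsignal:::disprop_row(t, crit)
  expect_false(r$signal)
  expect_lt(r$ic025, 0)
  # clear signal
  r2 <- pvsignal:::disprop_row(make_table(60, 40, 100, 900), crit)
  expect_true(r2$signal)
})

test_that("screens report every term and the pooled SMQ row", {
  db <- generate_reports(test_config(1500, 29, signal_injections =
    data.frame(drug_name = "drug1", pt = "event2", rr = 8)))$db
  smq <- smq_definition("mini", "narrow", c("event2", "event3"))
  scr <- detect_signals(db, "drug1", smq)
  expect_s3_class(scr, "disprop_screen")
  expect_equal(nrow(scr), 3L)
  expect_equal(sum(scr$pooled), 1L)
  pooled <- scr[scr$pooled, ]
  per_term <- scr[!scr$pooled, ]
  expect_lte(pooled$a, sum(per_term$a))
  # pooled a equals the SMQ case count among the drug's reports
  sub <- filter_reports(db, "drug1")
  expect_equal(pooled$a, sum(is_case(sub, smq)))
})

test_that("age stratification restricts the database correctly", {
  db <- generate_reports(test_config(2500, 37, signal_injections =
    data.frame(drug_name = "drug1", pt = "event2", rr = 10)))$db
  all_bands <- setdiff(c("le11", "a12_17", "a18_44", "a45_64", "a65_74",
                         "ge75"), NULL)
  s_all <- stratified_signals(db, "drug1", "event2", age_groups = all_bands)
  # all-ages stratum = full database minus unknown-age reports
  known <- db$reports$report_id[db$reports$age_group != "unknown"]
  s_manual <- detect_signals(pvsignal:::subset_db(db, known), "drug1",
                             "event2")
  expect_equal(s_all$a, s_manual$a)
  expect_equal(s_all$prr, s_manual$prr)
  # an empty stratum warns and returns no rows
  db0 <- db
  db0$reports$age_group <- "a18_44"
  db0 <- icsr_db(db0$reports, db0$drugs, db0$events)
  expect_warning(s0 <- stratified_signals(db0, "drug1", "event2",
                                          age_groups = "le11"))
  expect_equal(nrow(s0), 0L)
})

test_that("a drug absent from the database yields a zero table, not an error", {
  db <- toy_db()
  scr <- detect_signals(db, "absentdrug", "nausea")
  expect_equal(scr$a, 0)
  expect_true(is.na(scr$prr))
  expect_false(scr$signal)
})
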