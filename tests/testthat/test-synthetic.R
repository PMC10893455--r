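# synthetic-report generator: determinism, calibration, injections

test_that("generation is a pure function of config and seed", {
  cfg <- test_config(500, 42)
  f1 <- tempfile(); f2 <- tempfile()
  write_line_listing(generate_reports(cfg)$db, f1)
  write_line_listing(generate_reports(cfg)$db, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the output
  f3 <- tempfile()
  write_line_listing(generate_reports(cfg, seed = 43)$db, f3)
  expect_false(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3)))
})

test_that("event counts follow the configured binomial marginal", {
  cfg <- test_config(1000, 7, n_events = 2, p_event = 0.05)
  db <- generate_reports(cfg)$db
  observed <- sum(db$events$pt == "event2")  # event1 is the filler
  expect_lt(abs(observed - 1000 * 0.05), 4 * sqrt(1000 * 0.05 * 0.95))
})

test_that("a relative risk of 1 is indistinguishable from no injection", {
  base <- test_config(400, 5)
  inj <- test_config(400, 5, signal_injections = data.frame(
    drug_name = "drug1", pt = "event2", rr = 1))
  f1 <- tempfile(); f2 <- tempfile()
  write_line_listing(generate_reports(base)$db, f1)
  write_line_listing(generate_reports(inj)$db, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("invalid configurations fail before sampling", {
  expect_error(test_config(0, 1), "n_reports")
  expect_error(test_config(100, 1, p_event = 1.5), "probabilities")
  expect_error(test_config(100, 1, signal_injections = data.frame(
    drug_name = "drug1", pt = "event2", rr = -1)), "relative risks")
  expect_error(test_config(100, 1, signal_injections = data.frame(
    drug_name = "nonexistent", pt = "event2", rr = 2)), "catalog")
  cfg <- test_config(100, 1)
  cfg$demographic_marginals$sex <- c(male = 0.5, female = 0.6)
  expect_error(validate_generator_config(cfg), "sum to 1")
})

test_that("demographic marginals are calibrated (goodness of fit)", {
  # chi-square GOF per directly sampled categorical field, alpha = 0.001;
  # with 5 seeds and 4 fields the expected number of rejections under
  # calibration is 0.02 (seriousness is excluded: it is post-adjusted by
  # the death model, which forces fatal reports to serious)
  rejections <- 0L
  for (seed in 1:5) {
    db <- generate_reports(test_config(50000, seed))$db
    marg <- test_config(1, 1)$demographic_marginals
    r <- db$reports
    obs <- list(
      sex = table(factor(r$sex, names(marg$sex))),
      age_group = table(factor(r$age_group, names(marg$age_group))),
      region = table(factor(r$region, names(marg$region))),
      reporter = table(factor(r$reporter, names(marg$reporter))))
    for (f in names(obs)) {
      p <- stats::chisq.test(obs[[f]], p = marg[[f]])$p.value
      if (p < 0.001) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, 1L)
})

test_that("seriousness is coherent with the death model", {
  db <- generate_reports(test_config(2000, 3))$db
  expect_false(any(db$reports$death & db$reports$serious == "false"))
})

test_that("injected relative risks are recovered empirically", {
  inj <- data.frame(drug_name = c("drug1", "drug2", "drug3"),
                    pt = c("event2", "event3", "event4"),
                    rr = c(3, 3, 5))
  cfg <- test_config(150000, 17, p_drug = 0.1, p_event = 0.02,
                     signal_injections = inj)
  gen <- generate_reports(cfg)
  db <- gen$db
  # ledger covers every injected pair with its model expectation
  expect_equal(nrow(gen$ledger$pairs), 3L)
  expect_true(all(gen$ledger$pairs$expected_reports >=
                    150000 * 0.1 * 0.02 * 3 * 0.99))
  ids_by_drug <- split(db$drugs$report_id, db$drugs$drug_name)
  ids_by_pt <- split(db$events$report_id, db$events$pt)
  for (i in 1:3) {
    did <- unique(ids_by_drug[[inj$drug_name[i]]])
    eid <- unique(ids_by_pt[[inj$pt[i]]])
    p_with <- length(intersect(did, eid)) / length(did)
    p_without <- length(setdiff(eid, did)) / (db$n_total - length(did))
    expect_lt(abs(p_with / p_without - inj$rr[i]) / inj$rr[i], 0.10)
  }
})

test_that("co-medication raises the joint exposure probability", {
  cfg <- test_config(20000, 23, co_medication = data.frame(
    index_drug = "drug1", co_drug = "drug2", prob = 0.4))
  db <- generate_reports(cfg)$db
  ids1 <- unique(db$drugs$report_id[db$drugs$drug_name == "drug1"])
  ids2 <- unique(db$drugs$report_id[db$drugs$drug_name == "drug2"])
  p_cond <- length(intersect(ids1, ids2)) / length(ids1)
  # union of the 0.08 marginal and the extra 0.4 conditional draw
  expect_gt(p_cond, 0.3)
  p_marg <- length(setdiff(ids2, ids1)) / (db$n_total - length(ids1))
  expect_lt(p_marg, 0.12)
})

test_that("the study preset validates and matches the published strata", {
  cfg <- tramadol_study_preset(n_reports = 100000, seed = 31)
  expect_true(validate_generator_config(cfg))
  db <- generate_reports(cfg)$db
  tram <- filter_reports(db, "tramadol")
  n <- tram$n_total
  expect_gt(n, 400)
  # Monte-Carlo bands: 4 standard errors around the published shares
  p_f <- mean(tram$reports$sex == "female")
  expect_lt(abs(p_f - 0.609), 4 * sqrt(0.609 * 0.391 / n))
  p_asia <- mean(tram$reports$region == "asia")
  expect_lt(abs(p_asia - 0.613), 4 * sqrt(0.613 * 0.387 / n))
})

test_that("configs round-trip through YAML and JSON", {
  cfg <- test_config(200, 9, signal_injections = data.frame(
    drug_name = "drug1", pt = "event2", rr = 2.5))
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    lst <- unclass(cfg)
    lst$demographic_marginals <- lapply(lst$demographic_marginals, as.list)
    lst$role_probabilities <- lapply(lst$role_probabilities, as.list)
    if (ext == ".json") jsonlite::write_json(lst, f, auto_unbox = TRUE)
    else yaml::write_yaml(lst, f)
    cfg2 <- read_generator_config(f)
    f1 <- tempfile(); f2 <- tempfile()
    write_line_listing(generate_reports(cfg)$db, f1)
    write_line_listing(generate_reports(cfg2)$db, f2)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  }
})
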