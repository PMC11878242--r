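test_that("per-drug shares reproduce the published cohort percentages", {
  glp1 <- cohort_from_counts(c(
    exenatide = 142, liraglutide = 384, dulaglutide = 290,
    lixisenatide = 12, semaglutide = 655, tirzepatide = 226))
  sh <- drug_share(glp1, class = "GLP-1 RA")
  expect_equal(sum(sh$n), 1709)
  expect_equal(sh$percent[sh$drug == "semaglutide"], 38.33)
  expect_equal(sh$percent[sh$drug == "exenatide"], 8.31)
  expect_equal(sh$percent[sh$drug == "lixisenatide"], 0.70)

  dpp4 <- cohort_from_counts(c(
    alogliptin = 13, linagliptin = 79, sitagliptin = 382, saxagliptin = 32))
  sh2 <- drug_share(dpp4, class = "DPP-4 inhibitor")
  expect_equal(sh2$percent[sh2$drug == "sitagliptin"], 75.49)

  single <- cohort_from_counts(c(semaglutide = 7))
  expect_equal(drug_share(single)$percent, 100)
  expect_error(drug_share(glp1[0, ]), "empty")
})

test_that("age bands split at the documented boundaries", {
  expect_equal(as.character(assign_age_bin(c(18.9, 19, 45, 46, 65, 66, NA))),
               c("<19", "19-45", "19-45", "46-65", "46-65", ">65", "unknown"))
  expect_error(assign_age_bin(-1), "negative")
})

test_that("demographic tables count every category and rank countries", {
  n <- 1709
  sex <- rep(c("male", "female", "not_specified", "unknown"),
             c(647, 944, 4, 114))
  country <- rep(c("US", "JP", "GB", "FR", NA), c(1104, 88, 66, 300, 151))
  r <- cohort_from_counts(c(semaglutide = n), sex = sex, country = country)
  dem <- demographic_table(r)
  expect_equal(dem$percent[dem$variable == "sex" & dem$category == "female"],
               55.24)
  expect_equal(dem$percent[dem$variable == "sex" & dem$category == "male"],
               37.86)
  expect_equal(dem$n[dem$variable == "country"][1], 1104)
  expect_equal(dem$percent[dem$variable == "country"][1], 64.60)
  expect_equal(dem$category[dem$variable == "country"], c("US", "FR", "JP"))
  # sex percentages cover the cohort
  expect_equal(sum(dem$n[dem$variable == "sex"]), n)
  expect_lt(abs(sum(dem$percent[dem$variable == "sex"]) - 100), 0.05)
  # all ages unknown: summary flags the absence rather than inventing one
  expect_true(is.na(age_summary(r)$median))
  known <- dplyr::mutate(r, age_years = 60)
  expect_equal(age_summary(known)$median, 60)
})

test_that("serious-outcome rates count a report once and match the anchors", {
  ex <- cohort_from_counts(c(exenatide = 142), serious = list(exenatide = 86))
  sr <- serious_rate(ex)
  expect_equal(sr$n_serious, 86)
  expect_equal(sr$n_total, 142)
  expect_equal(sr$percent, 60.56)
  sita <- cohort_from_counts(c(sitagliptin = 382),
                             serious = list(sitagliptin = 308))
  expect_equal(serious_rate(sita)$percent, 80.63)

  # a report with several serious codes still counts once
  multi <- ae_reports(
    primary_id = "1", case_id = "C1", fda_date = "2020-01-01",
    drugs = list(c(PS = "sitagliptin")), reactions = list("nausea"),
    outcomes = list(c("DE", "HO", "LT")))
  expect_equal(serious_rate(multi)$n_serious, 1)

  # no serious codes at all
  none <- cohort_from_counts(c(sitagliptin = 5))
  expect_equal(serious_rate(none)$percent, 0)

  # monotone in the rule
  r <- random_reports(150, seed = 12)
  base <- serious_rate(r, rule = serious_codes(include_ri = FALSE))
  wider <- serious_rate(r, rule = c(serious_codes(include_ri = FALSE), "OT"))
  expect_gte(wider$n_serious, base$n_serious)

  by_drug <- serious_rate(r, by = "drug")
  expect_equal(sum(by_drug$n_total), nrow(r))
})

test_that("rate comparison is the r-by-2 Pearson test", {
  same <- compare_rates(tibble::tibble(n_serious = c(50, 50),
                                       n_total = c(100, 100)))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  res <- compare_rates(tibble::tibble(n_serious = c(90, 10),
                                      n_total = c(100, 100)))
  expect_equal(res$chi2, 128)
  expect_equal(res$df, 1)
  three <- compare_rates(tibble::tibble(n_serious = c(20, 20, 20),
                                        n_total = c(80, 80, 80)))
  expect_equal(three$chi2, 0)

  # brute-force expected-count oracle on random configurations
  set.seed(13)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    tot <- sample(20:300, k, replace = TRUE)
    ser <- vapply(tot, function(t) sample(seq_len(t - 1), 1), integer(1))
    got <- compare_rates(tibble::tibble(n_serious = ser, n_total = tot))
    obs <- rbind(ser, tot - ser)
    expe <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    chi <- sum((obs - expe)^2 / expe)
    expect_equal(got$chi2, chi, tolerance = 1e-9)
    expect_equal(got$df, k - 1)
    expect_equal(got$p, stats::pchisq(chi, k - 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  expect_error(compare_rates(tibble::tibble(n_serious = 1, n_total = 2)),
               "two groups")
  expect_error(compare_rates(tibble::tibble(n_serious = c(0, 0),
                                            n_total = c(5, 5))),
               "expected")
})

test_that("yearly trends tally totals and SMQ matches with zero-filled years", {
  cat <- tiny_catalog()
  r <- bind_reports(
    mk_report("1", fda_date = "2013-02-01", reactions = "pt a1"),
    mk_report("2", fda_date = "2013-08-01", reactions = "nausea"),
    mk_report("3", fda_date = "2015-03-01", reactions = "shared pt"),
    mk_report("4", fda_date = "2015-06-01", reactions = "root only pt"),
    mk_report("5", fda_date = "2015-07-01", reactions = "nausea")
  )
  tr <- yearly_trend(r, cat)
  expect_equal(tr$year, 2013:2015)
  expect_equal(tr$n_total, c(2, 0, 3))
  expect_equal(tr$n_smq, c(1, 0, 2))
  expect_true(all(tr$n_smq <= tr$n_total))
  one <- yearly_trend(r[1, ], cat)
  expect_equal(nrow(one), 1)
})

test_that("subgroup analysis localises a stratum-specific excess", {
  # build a cohort where only (female, 19-45) carries an excess of the event
  set.seed(99)
  n <- 6000
  sex <- sample(c("male", "female"), n, TRUE)
  age <- runif(n, 20, 80)
  drug <- sample(c("sitagliptin", "metformin"), n, TRUE, prob = c(0.3, 0.7))
  stratum <- sex == "female" & age <= 45
  p_event <- ifelse(drug == "sitagliptin" & stratum, 0.40, 0.05)
  event <- runif(n) < p_event
  r <- ae_reports(
    primary_id = as.character(seq_len(n)), case_id = paste0("C", seq_len(n)),
    fda_date = "2020-01-01",
    drugs = lapply(drug, function(d) c(PS = d)),
    reactions = lapply(event, function(e) if (e) "cholelithiasis" else "nausea"),
    sex = sex, age_years = age
  )
  strata <- tidyr::expand_grid(sex = c("male", "female"),
                               age_bin = c("19-45", "46-65"))
  out <- subgroup_signals(r, "sitagliptin", "cholelithiasis", strata = strata)
  expect_equal(nrow(out), 4)
  hot <- out$sex == "female" & out$age_bin == "19-45"
  expect_true(out$positive[hot])
  expect_false(any(out$positive[!hot], na.rm = TRUE))

  # additivity: stratum a-cells sum to the unstratified a over the partition
  full_strata <- tidyr::expand_grid(sex = c("male", "female"),
                                    age_bin = c("<19", "19-45", "46-65", ">65"))
  parts <- subgroup_signals(r, "sitagliptin", "cholelithiasis",
                            strata = full_strata)
  whole <- contingency_table(r, "sitagliptin", "cholelithiasis")
  expect_equal(sum(parts$a, na.rm = TRUE), whole$a)

  # a stratum with no exposed-and-event reports is a no-data marker
  vac <- subgroup_signals(r, "sitagliptin", "cholelithiasis",
                          strata = tibble::tibble(sex = "male",
                                                  age_bin = "<19"))
  expect_true(vac$no_data)
})
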