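test_that("reading a well-formed extract normalises drugs and keeps all rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "primary_id,case_id,fda_date,drugs,reactions,sex,age_years,country,outcomes",
    "1,C1,2020-01-02,Januvia:PS,Cholelithiasis,F,61,us,HO;OT",
    "2,C2,2021-03-04,OZEMPIC:PS;metformin:C,nausea;cholecystitis,M,47,JP,",
    "3,C3,2019-11-30,liraglutide:PS,headache,NS,,,DE"
  ), f)
  r <- read_ae_reports(f)
  expect_equal(nrow(r), 3)
  expect_equal(nrow(quarantined(r)), 0)
  expect_equal(r$drugs[[1]], c(PS = "sitagliptin"))
  expect_equal(r$drugs[[2]], c(PS = "semaglutide", C = "other"))
  expect_equal(r$reactions[[1]], "cholelithiasis")
  expect_equal(r$sex, c("female", "male", "not_specified"))
  expect_equal(r$country[1:2], c("US", "JP"))
  expect_true(is.na(r$age_years[3]))
  expect_equal(r$outcomes[[2]], character(0))
})

test_that("malformed rows are quarantined with a reason, not dropped silently", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "primary_id,case_id,fda_date,drugs,reactions,sex,age_years,country,outcomes",
    "1,C1,2020-01-02,sitagliptin:PS,cholelithiasis,F,61,US,HO",
    "2,C2,2024-13-40,sitagliptin:PS,cholelithiasis,F,61,US,HO",
    "3,C3,2020-01-02,sitagliptin:PS,cholelithiasis,F,200,US,HO",
    "4,C4,2020-01-02,sitagliptin:PS,,F,61,US,HO"
  ), f)
  expect_message(r <- read_ae_reports(f), "quarantined")
  expect_equal(nrow(r), 1)
  q <- quarantined(r)
  expect_setequal(q$reason, c("unparseable fda_date", "age outside [0, 130]",
                              "no reaction terms"))
})

test_that("a missing mandatory column is a hard error naming the column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "primary_id,case_id,fda_date,drugs,sex,age_years,country,outcomes",
    "1,C1,2020-01-02,sitagliptin:PS,F,61,US,HO"
  ), f)
  expect_error(read_ae_reports(f), "reactions")
})

test_that("the dialect round-trips field for field", {
  r <- random_reports(40, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ae_reports(r, f)
  back <- read_ae_reports(f)
  attr(back, "quarantine") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(r))
})

test_that("deduplication keeps the latest acceptance date, then the higher id", {
  two <- bind_reports(
    mk_report("100", case_id = "C1", fda_date = "2020-01-01"),
    mk_report("101", case_id = "C1", fda_date = "2021-06-01")
  )
  expect_equal(deduplicate_reports(two)$primary_id, "101")

  tie <- bind_reports(
    mk_report("100", case_id = "C1", fda_date = "2020-01-01"),
    mk_report("200", case_id = "C1", fda_date = "2020-01-01")
  )
  expect_equal(deduplicate_reports(tie)$primary_id, "200")

  # numeric, not lexicographic, when ids are all digits
  tie2 <- bind_reports(
    mk_report("9", case_id = "C1", fda_date = "2020-01-01"),
    mk_report("10", case_id = "C1", fda_date = "2020-01-01")
  )
  expect_equal(deduplicate_reports(tie2)$primary_id, "10")

  # lexicographic fallback with non-numeric ids
  tie3 <- bind_reports(
    mk_report("A9", case_id = "C1", fda_date = "2020-01-01"),
    mk_report("A10", case_id = "C1", fda_date = "2020-01-01")
  )
  expect_equal(deduplicate_reports(tie3)$primary_id, "A9")
})

test_that("deduplication is idempotent and keeps one row per case", {
  for (seed in 1:3) {
    r <- random_reports(200, seed = seed, n_cases = 120)
    d1 <- deduplicate_reports(r)
    expect_equal(nrow(d1), dplyr::n_distinct(r$case_id))
    expect_equal(deduplicate_reports(d1), d1)
  }
  empty <- random_reports(5, 1)[0, ]
  expect_equal(nrow(deduplicate_reports(empty)), 0)
  distinct <- random_reports(30, seed = 9, n_cases = 1e6)
  expect_equal(nrow(deduplicate_reports(distinct)), 30)
})

test_that("window filtering is a closed quarter range on the acceptance date", {
  r <- bind_reports(
    mk_report("1", fda_date = "2013-01-01"),
    mk_report("2", fda_date = "2012-12-31"),
    mk_report("3", fda_date = "2024-03-31"),
    mk_report("4", fda_date = "2024-04-01")
  )
  kept <- filter_window(r, "2013Q1", "2024Q1")
  expect_setequal(kept$primary_id, c("1", "3"))
  expect_error(filter_window(r, "2024Q1", "2013Q1"), "window")
  expect_error(filter_window(r, "13Q1", "2024Q1"), "quarter")

  # brute-force comparison on a mixed fixture
  dates <- c("2012-06-01", "2012-12-31", "2013-01-01", "2015-07-15",
             "2020-02-29", "2024-03-31", "2024-04-01", "2025-01-01",
             "2018-10-10", "2013-04-01")
  mixed <- purrr::map(seq_along(dates),
                      ~ mk_report(as.character(.x), fda_date = dates[.x]))
  mixed <- dplyr::bind_rows(mixed)
  lo <- as.Date("2013-01-01"); hi <- as.Date("2024-03-31")
  expect_equal(nrow(filter_window(mixed)), sum(dates >= lo & dates <= hi))
  expect_equal(nrow(filter_window(mixed)), 6)
})

test_that("dedup and window filter commute when case versions stay together", {
  for (seed in 4:6) {
    r <- random_reports(150, seed = seed, n_cases = 100)
    # collapse each case's versions onto one date so both versions fall on the
    # same side of any boundary
    r$fda_date <- r$fda_date[match(r$case_id, r$case_id)]
    a <- filter_window(deduplicate_reports(r), "2015Q1", "2020Q4")
    b <- deduplicate_reports(filter_window(r, "2015Q1", "2020Q4"))
    expect_equal(a, b)
  }
})

test_that("drug selection respects the role code", {
  r <- bind_reports(
    mk_report("1", drug = "semaglutide", role = "PS"),
    mk_report("2", drug = "semaglutide", role = "C"),
    ae_reports(primary_id = "3", case_id = "C3", fda_date = "2020-01-01",
               drugs = list(c(PS = "sitagliptin", SS = "other")),
               reactions = list("nausea"))
  )
  glp1 <- class_drugs(class = "GLP-1 RA")
  expect_equal(select_by_drug(r, glp1)$primary_id, "1")
  expect_equal(select_by_drug(r, "sitagliptin")$primary_id, "3")
  expect_equal(nrow(select_by_drug(r, "semaglutide", role = "C")), 1)
  expect_error(select_by_drug(r, character()), "non-empty")
})

test_that("the report constructor rejects invariant violations", {
  expect_error(mk_report("1", age_years = 150), "130")
  expect_error(mk_report("1", role = "XX"), "role")
  expect_error(mk_report("1", outcomes = "ZZ"), "outcome")
  expect_error(mk_report("1", sex = "other"), "sex")
  expect_error(
    ae_reports(primary_id = "1", case_id = "C", fda_date = "2020-01-01",
               drugs = list(c(PS = "x")), reactions = list(character())),
    "reaction")
})
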