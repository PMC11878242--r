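test_that("contingency tables classify each report into exactly one cell", {
  r <- dplyr::bind_rows(
    purrr::map(1:2, ~ mk_report(paste0("e", .x), drug = "sitagliptin",
                                reactions = "cholelithiasis")),
    purrr::map(1:3, ~ mk_report(paste0("x", .x), drug = "sitagliptin",
                                reactions = "nausea")),
    mk_report("c1", drug = "metformin", reactions = "cholelithiasis"),
    purrr::map(1:4, ~ mk_report(paste0("d", .x), drug = "metformin",
                                reactions = "headache"))
  )
  ct <- contingency_table(r, "sitagliptin", "cholelithiasis")
  expect_equal(unlist(ct), c(a = 2, b = 3, c = 1, d = 4))
  expect_equal(sum(unlist(ct)), nrow(r))

  # no reaction matches: empty event column
  ct0 <- contingency_table(r, "sitagliptin", "vertigo")
  expect_equal(ct0$a + ct0$c, 0)
  # all reports exposed: degenerate margin
  ct1 <- contingency_table(r, c("sitagliptin", "metformin"), "cholelithiasis")
  expect_equal(ct1$c + ct1$d, 0)
  expect_error(contingency_table(r[0, ], "sitagliptin", "x"), "positive")
  # exposure requires the PS role
  rc <- mk_report("z", drug = "sitagliptin", role = "C")
  ctc <- contingency_table(dplyr::bind_rows(r, rc), "sitagliptin",
                           "cholelithiasis")
  expect_equal(ctc$c + ctc$d, 6)
})

test_that("ROR and its Woolf interval match the worked example", {
  res <- ror_stats(tibble::tibble(a = 25, b = 75, c = 100, d = 900))
  expect_equal(res$ror, 3)
  expect_equal(res$ror_lo, 1.824030, tolerance = 1e-5)
  expect_equal(res$ror_hi, 4.934129, tolerance = 1e-5)
  # proportional rows give exactly 1
  expect_equal(ror_stats(tibble::tibble(a = 10, b = 90, c = 90, d = 810))$ror, 1)
  # symmetry under exchanging (a, d) with themselves / transposition
  t1 <- ror_stats(tibble::tibble(a = 2, b = 8, c = 8, d = 2))
  t2 <- ror_stats(tibble::tibble(a = 2, b = 8, c = 8, d = 2)[, c(1, 3, 2, 4)])
  expect_equal(t1$ror, t2$ror)
})

test_that("PRR, its interval and the chi-square match the worked example", {
  res <- prr_stats(tibble::tibble(a = 25, b = 75, c = 100, d = 900))
  expect_equal(res$prr, 2.5)
  expect_equal(res$prr_lo, 1.697611, tolerance = 1e-5)
  expect_equal(res$prr_hi, 3.681645, tolerance = 1e-5)
  expect_equal(res$chi2, 20.307692, tolerance = 1e-6)
  null <- prr_stats(tibble::tibble(a = 10, b = 90, c = 90, d = 810))
  expect_equal(null$prr, 1)
  expect_equal(null$chi2, 0)
  # chi-square is invariant under transposing the table
  x <- tibble::tibble(a = 7, b = 21, c = 13, d = 59)
  xt <- tibble::tibble(a = 7, b = 13, c = 21, d = 59)
  expect_equal(prr_stats(x)$chi2, prr_stats(xt)$chi2)
  expect_error(prr_stats(tibble::tibble(a = 0, b = 0, c = 3, d = 7)),
               "margin")
})

test_that("2x2 statistics agree with an independent oracle on random tables", {
  set.seed(7)
  for (i in 1:200) {
    cells <- as.list(setNames(sample(1:400, 4, replace = TRUE),
                              c("a", "b", "c", "d")))
    got <- prr_stats(ror_stats(tibble::as_tibble(cells)))
    want <- oracle_2x2(cells$a, cells$b, cells$c, cells$d)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10,
                   label = paste(f, "at", paste(unlist(cells), collapse = ",")))
    }
  }
})

test_that("zero cells follow the configured policy", {
  z <- tibble::tibble(a = 0, b = 10, c = 5, d = 85)
  flagged <- ror_stats(z)
  expect_false(flagged$ror_defined)
  expect_true(is.na(flagged$ror))
  hald <- ror_stats(z, zero_cell = "haldane")
  expect_true(hald$ror_defined)
  expect_equal(hald$ror, (0.5 / 10.5) / (5.5 / 85.5))
  p <- prr_stats(z)
  expect_equal(p$prr, 0)
  expect_true(is.na(p$prr_lo))
  expect_false(p$prr_defined)
})

test_that("the closed-form information component behaves at its anchors", {
  # independence: prior-dominated shift only
  ind <- bcpnn_ic(tibble::tibble(a = 10, b = 90, c = 90, d = 810))
  expect_lt(abs(ind$ic), 0.05)
  expect_lt(ind$ic025, ind$ic)

  # moderate signal: within 0.1 of the crude log2(a N / (n1 n.1))
  sig <- bcpnn_ic(tibble::tibble(a = 25, b = 75, c = 100, d = 900))
  crude <- log2(25 * 1100 / (100 * 125))
  expect_lt(abs(sig$ic - crude), 0.1)

  # large-count limit: E(IC) -> crude IC and V(IC) -> 0
  big <- bcpnn_ic(tibble::tibble(a = 2500, b = 7500, c = 10000, d = 90000))
  crude_big <- log2(2500 * 110000 / (10000 * 12500))
  expect_equal(big$ic, crude_big, tolerance = 1e-3)
  small <- bcpnn_ic(tibble::tibble(a = 25, b = 75, c = 100, d = 900))
  expect_lt(big$ic_var, small$ic_var / 50)
  expect_lt(big$ic_var, 0.002)
})

test_that("the Monte-Carlo IC mode agrees with the closed form at scale", {
  tbl <- tibble::tibble(a = 5000, b = 45000, c = 20000, d = 430000)
  closed <- bcpnn_ic(tbl)
  set.seed(1)
  mc <- bcpnn_ic(tbl, method = "mc", mc_draws = 5e4)
  expect_equal(mc$ic, closed$ic, tolerance = 0.01)
  expect_equal(mc$ic025, closed$ic025, tolerance = 0.02)
})

test_that("disproportionality grows with the joint cell", {
  base <- tibble::tibble(a = c(5, 10, 20, 40), b = 100, c = 50, d = 1000)
  r <- ror_stats(base)$ror
  p <- prr_stats(base)$prr
  ic <- bcpnn_ic(base)$ic
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(ic) > 0))
})

test_that("the joint rule is a pure conjunction of the four thresholds", {
  ok <- tibble::tibble(n = 382, ror_lo = 3.13, chi2 = 648.23, prr_lo = 3.0,
                       ic025 = 1.60, ebgm05 = 3.11)
  expect_true(evaluate_signals(ok)$positive)

  # class-level pattern: strong ROR/PRR but shrunken EBGM05 below 2
  glp1 <- tibble::tibble(n = 1709, ror_lo = 1.52, chi2 = 367.69,
                         prr_lo = 1.51, ic025 = 0.58, ebgm05 = 1.51)
  g <- evaluate_signals(glp1)
  expect_true(g$ror_pass && g$prr_pass && g$ic_pass)
  expect_false(g$ebgm_pass)
  expect_false(g$positive)

  # n >= 3 gate alone blocks a signal
  tiny <- dplyr::mutate(ok, n = 2)
  expect_false(evaluate_signals(tiny)$positive)

  # flipping any single criterion flips the decision
  flips <- list(
    dplyr::mutate(ok, ror_lo = 0.9),
    dplyr::mutate(ok, chi2 = 3.9),
    dplyr::mutate(ok, prr_lo = 1.0),
    dplyr::mutate(ok, ic025 = 0),
    dplyr::mutate(ok, ebgm05 = 2)
  )
  for (m in flips) expect_false(evaluate_signals(m)$positive)

  # an undefined bound fails its criterion
  na_m <- dplyr::mutate(ok, ror_lo = NA_real_)
  expect_false(evaluate_signals(na_m)$ror_pass)
  expect_false(evaluate_signals(na_m)$positive)
})
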