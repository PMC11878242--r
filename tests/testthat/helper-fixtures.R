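# in-code fixtures shared across test files

# quick single-report builder with sensible defaults
mk_report <- function(primary_id, case_id = paste0("C", primary_id),
                      fda_date = "2020-06-01", drug = "sitagliptin",
                      role = "PS", reactions = "cholelithiasis",
                      sex = "female", age_years = 60, country = "US",
                      outcomes = "HO") {
  ae_reports(
    primary_id = primary_id, case_id = case_id, fda_date = fda_date,
    drugs = list(setNames(drug, role)), reactions = list(reactions),
    sex = sex, age_years = age_years, country = country,
    outcomes = list(outcomes)
  )
}

bind_reports <- function(...) dplyr::bind_rows(...)

# a tiny two-level SMQ catalog built in code
tiny_catalog <- function() {
  smq_catalog(
    nodes = tibble::tibble(
      name = c("root smq", "child a", "child b"),
      parent = c(NA, "root smq", "root smq")
    ),
    terms = tibble::tibble(
      smq = c("root smq", "child a", "child a", "child b"),
      term = c("root only pt", "pt a1", "shared pt", "shared pt")
    )
  )
}

# random cohort of simple single-drug reports for property-style tests
random_reports <- function(n, seed, n_cases = n) {
  set.seed(seed)
  drugs <- c("sitagliptin", "semaglutide", "liraglutide", "other")
  pts <- c("cholelithiasis", "cholecystitis", "nausea", "headache")
  ae_reports(
    primary_id = as.character(seq_len(n) + 1000),
    case_id = paste0("C", sample.int(n_cases, n, replace = TRUE)),
    fda_date = as.Date("2013-01-01") + sample.int(4000, n, replace = TRUE),
    drugs = lapply(sample(drugs, n, TRUE), function(d) c(PS = d)),
    reactions = lapply(seq_len(n), function(i) {
      sample(pts, sample(1:2, 1))
    }),
    sex = sample(c("male", "female", "unknown"), n, TRUE),
    age_years = ifelse(runif(n) < 0.3, NA, runif(n, 10, 90)),
    country = sample(c("US", "JP", NA), n, TRUE),
    outcomes = lapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) sample(c("DE", "HO", "OT"), 1) else character()
    })
  )
}

# quadrature oracle for the posterior gamma mixture: geometric mean and
# lower quantile by numerical integration, independent of the package's
# digamma/bisection path
quad_ebgm <- function(n, E, fit, p = 0.05) {
  l1 <- dnbinom(n, size = fit$shape1, prob = fit$rate1 / (fit$rate1 + E)) *
    fit$w
  l2 <- dnbinom(n, size = fit$shape2, prob = fit$rate2 / (fit$rate2 + E)) *
    (1 - fit$w)
  q1 <- l1 / (l1 + l2)
  dens <- function(x) {
    q1 * stats::dgamma(x, fit$shape1 + n, rate = fit$rate1 + E) +
      (1 - q1) * stats::dgamma(x, fit$shape2 + n, rate = fit$rate2 + E)
  }
  upper <- stats::qgamma(1 - 1e-12, fit$shape1 + n, rate = fit$rate1 + E) +
    stats::qgamma(1 - 1e-12, fit$shape2 + n, rate = fit$rate2 + E)
  elog <- stats::integrate(function(x) log(x) * dens(x), 0, upper,
                           rel.tol = 1e-10)$value
  cdf <- function(q) stats::integrate(dens, 0, q, rel.tol = 1e-10)$value
  q05 <- stats::uniroot(function(q) cdf(q) - p, c(1e-12, upper),
                        tol = 1e-12)$root
  list(ebgm = exp(elog), ebgm05 = q05)
}

# expand per-drug counts into a minimal report collection; attributes beyond
# the ones under test take defaults
cohort_from_counts <- function(counts, serious = NULL, sex = NULL,
                               country = NULL) {
  n <- sum(counts)
  drug <- rep(names(counts), counts)
  is_serious <- rep(FALSE, n)
  if (!is.null(serious)) {
    for (d in names(serious)) {
      idx <- which(drug == d)
      is_serious[idx[seq_len(serious[[d]])]] <- TRUE
    }
  }
  ae_reports(
    primary_id = as.character(seq_len(n)),
    case_id = paste0("C", seq_len(n)),
    fda_date = "2020-01-01",
    drugs = lapply(drug, function(d) c(PS = d)),
    reactions = rep(list("cholelithiasis"), n),
    sex = if (is.null(sex)) "unknown" else sex,
    age_years = NA_real_,
    country = if (is.null(country)) NA_character_ else country,
    outcomes = lapply(is_serious, function(s) if (s) "HO" else character())
  )
}

# null-heavy cells (mildly overdispersed around ratio 1, as real extracts
# are) with a minority of genuinely elevated reporting ratios — the regime
# the shrinker is meant for; exactly-Poisson nulls would drive the mixture
# towards a point mass
null_fit <- function(seed = 5, n_cells = 400, frac_signal = 0.1) {
  set.seed(seed)
  E <- exp(runif(n_cells, log(1), log(150)))
  lam <- rgamma(n_cells, 100, 100)
  hot <- seq_len(ceiling(frac_signal * n_cells))
  lam[hot] <- rgamma(length(hot), 2, 1)
  n <- rpois(n_cells, lam * E)
  mgps_fit(tibble::tibble(n = n, expected = E))
}

# independently written 2x2 statistics used as oracles (textbook formulas,
# scalar arithmetic, no shared code with the package internals)
oracle_2x2 <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  lse <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  pse <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  chi <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(
    ror = or, ror_lo = exp(log(or) - 1.96 * lse),
    ror_hi = exp(log(or) + 1.96 * lse),
    prr = prr, prr_lo = exp(log(prr) - 1.96 * pse),
    prr_hi = exp(log(prr) + 1.96 * pse),
    chi2 = unname(chi$statistic)
  )
}
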