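#' Default drug menu for the synthetic generator
#'
#' Ten incretin-based study drugs plus four high-volume background drugs.
#' Study-drug weights follow the relative report volumes of the two classes
#' (GLP-1 RA roughly 87% of the incretin reports) and the within-class
#' report shares of the biliary cohorts; background drugs supply the
#' comparator mass that a database-wide extract would contribute.
#'
#' @return Tibble `drug`, `class`, `weight` (weights are sampling
#'   probabilities up to normalisation).
#' @export
default_drug_menu <- function() {
  glp1 <- tibble::tibble(
    drug = c("exenatide", "liraglutide", "dulaglutide", "lixisenatide",
             "semaglutide", "tirzepatide"),
    class = "GLP-1 RA",
    weight = 0.26 * c(0.083, 0.225, 0.170, 0.007, 0.383, 0.132)
  )
  dpp4 <- tibble::tibble(
    drug = c("linagliptin", "alogliptin", "saxagliptin", "sitagliptin"),
    class = "DPP-4 inhibitor",
    weight = 0.04 * c(0.156, 0.026, 0.063, 0.755)
  )
  bg <- tibble::tibble(
    drug = c("metformin", "atorvastatin", "lisinopril", "adalimumab"),
    class = "other",
    weight = c(0.20, 0.18, 0.15, 0.17)
  )
  dplyr::bind_rows(glp1, dpp4, bg)
}

#' Default event menu for the synthetic generator
#'
#' The biliary preferred terms of the bundled synthetic SMQ catalog at low
#' baseline reporting probabilities, plus ten common background terms at
#' higher baselines. Baselines are per-report Bernoulli probabilities for a
#' drug with rate ratio 1.
#'
#' @param catalog An `smq_catalog`; defaults to the bundled fixture.
#' @return Tibble `term`, `smq` (`NA` for background terms), `baseline`.
#' @export
default_event_menu <- function(catalog = read_smq_catalog(example_smq_path())) {
  bil <- catalog$terms
  n_b <- nrow(bil)
  biliary <- tibble::tibble(
    term = bil$term,
    smq = bil$smq,
    baseline = rep(c(0.001, 0.002, 0.004), length.out = n_b)
  )
  background <- tibble::tibble(
    term = c("nausea", "vomiting", "diarrhoea", "headache", "dizziness",
             "fatigue", "rash", "pruritus", "arthralgia", "dyspnoea"),
    smq = NA_character_,
    baseline = c(0.10, 0.07, 0.06, 0.05, 0.04, 0.04, 0.03, 0.02, 0.02, 0.02)
  )
  dplyr::bind_rows(biliary, background)
}

#' Default demographic model
#'
#' Sex probabilities, an age model (two-component normal mixture, clamped to
#' \[0, 120\], with a missing fraction) and country weights chosen to echo
#' the published biliary-cohort distributions: a small female excess, a
#' middle-aged/elderly age skew, roughly 40% missing ages, and a US-heavy
#' country mix.
#'
#' @return A list with elements `sex_probs`, `age` (means, sds, weights,
#'   missing fraction) and `country` (named weights; `NA` weight is the
#'   unknown share).
#' @export
default_demographics <- function() {
  list(
    sex_probs = c(male = 0.40, female = 0.525, not_specified = 0.005,
                  unknown = 0.07),
    age = list(means = c(55, 72), sds = c(11, 8), weights = c(0.65, 0.35),
               missing = 0.40),
    country = c(US = 0.62, JP = 0.07, GB = 0.04, FR = 0.04, CA = 0.03,
                DE = 0.03, other = 0.12, unknown = 0.05)
  )
}

#' Default outcome model
#'
#' Each report draws a latent severity class (serious with probability
#' `p_serious`); serious reports draw one code from the serious-code
#' distribution and may add the other-serious code, non-serious reports
#' carry `OT` or nothing.
#'
#' @param p_serious Probability of the serious latent class, default 0.55.
#' @return A list `p_serious`, `serious_code_probs`, `p_ot_extra`,
#'   `p_ot_nonserious`.
#' @export
default_outcome_model <- function(p_serious = 0.55) {
  list(
    p_serious = p_serious,
    serious_code_probs = c(DE = 0.12, LT = 0.05, HO = 0.62, DS = 0.01,
                           CA = 0.001, RI = 0.009, OT = 0.19),
    p_ot_extra = 0.25,
    p_ot_nonserious = 0.55
  )
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' Defines a generative model for OpenVigil/FAERS-style report collections
#' with known ground truth: each report draws one primary-suspect drug from
#' the menu, each preferred term independently via a Bernoulli draw with
#' probability `baseline * rho(drug, term)` (capped at 1, `rho = 1` unless
#' spiked), demographics and outcomes from their models, and a fraction of
#' reports is cloned as duplicate case versions (same case identifier,
#' fresh entry identifier, later acceptance date).
#'
#' @param n_reports Number of distinct cases to generate.
#' @param drug_menu Tibble `drug`, `class`, `weight` ([default_drug_menu()]).
#' @param event_menu Tibble `term`, `smq`, `baseline`
#'   ([default_event_menu()]).
#' @param spikes Optional tibble `drug`, `term`, `rho` of spiked
#'   reporting-rate ratios (`rho > 0`; 1 is null).
#' @param duplicate_rate Fraction of cases that receive one duplicate entry,
#'   in \[0, 1).
#' @param demographics See [default_demographics()].
#' @param outcome_model See [default_outcome_model()].
#' @param window Character vector of two quarter specs bounding the FDA
#'   acceptance dates.
#' @param seed Integer seed; generation is reproducible given the config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 2000,
                             drug_menu = default_drug_menu(),
                             event_menu = default_event_menu(),
                             spikes = NULL,
                             duplicate_rate = 0.1,
                             demographics = default_demographics(),
                             outcome_model = default_outcome_model(),
                             window = c("2013Q1", "2024Q1"),
                             seed = 1L) {
  if (n_reports < 1) abort("n_reports must be a positive integer")
  stopifnot(all(c("drug", "weight") %in% names(drug_menu)),
            all(c("term", "baseline") %in% names(event_menu)))
  if (any(drug_menu$weight <= 0)) abort("drug weights must be positive")
  if (any(event_menu$baseline < 0 | event_menu$baseline > 1)) {
    abort("event baselines must be probabilities in [0, 1]")
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    abort("duplicate_rate must lie in [0, 1)")
  }
  if (!is.null(spikes)) {
    stopifnot(all(c("drug", "term", "rho") %in% names(spikes)))
    if (any(spikes$rho <= 0)) abort("spike rate ratios must be positive")
    if (!all(spikes$drug %in% drug_menu$drug)) {
      abort("spiked drug not in drug_menu")
    }
    if (!all(spikes$term %in% event_menu$term)) {
      abort("spiked term not in event_menu")
    }
  }
  sp <- demographics$sex_probs
  if (is.null(names(sp)) || !all(names(sp) %in% .SEX_LEVELS) || any(sp < 0)) {
    abort("sex_probs must be non-negative and named by sex level")
  }
  structure(list(
    n_reports = as.integer(n_reports), drug_menu = drug_menu,
    event_menu = event_menu, spikes = spikes,
    duplicate_rate = duplicate_rate, demographics = demographics,
    outcome_model = outcome_model, window = window, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# rate-ratio lookup matrix (drugs x terms), 1 unless spiked
rho_matrix <- function(config) {
  drugs <- config$drug_menu$drug
  terms <- config$event_menu$term
  m <- matrix(1, length(drugs), length(terms), dimnames = list(drugs, terms))
  if (!is.null(config$spikes)) {
    for (i in seq_len(nrow(config$spikes))) {
      m[config$spikes$drug[i], config$spikes$term[i]] <- config$spikes$rho[i]
    }
  }
  m
}

#' Generate a synthetic report collection with ground truth
#'
#' Runs the generative model of a [synthetic_config()]. Reports whose
#' Bernoulli draws produce no reaction receive the filler term
#' `"drug ineffective"` (outside the event menu, so menu probabilities stay
#' exact); duplicate entries are appended after the base entries.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements
#'   * `reports`: a report-collection tibble (base entries plus duplicates);
#'   * `truth`: list with `pairs` (tibble `drug`, `term`, `rho`),
#'     `duplicates` (tibble `primary_id`, `duplicate_of`) and `n_cases`.
#' @examples
#' sim <- simulate_reports(synthetic_config(n_reports = 200, seed = 7))
#' nrow(sim$reports) >= sim$truth$n_cases
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  menu <- config$drug_menu
  events <- config$event_menu
  P <- nrow(events)

  drug <- sample(menu$drug, n, replace = TRUE,
                 prob = menu$weight / sum(menu$weight))

  thr <- matrix(rep(events$baseline, each = n), n, P)
  if (!is.null(config$spikes)) {
    for (i in seq_len(nrow(config$spikes))) {
      rows <- drug == config$spikes$drug[i]
      col <- match(config$spikes$term[i], events$term)
      thr[rows, col] <- pmin(1, events$baseline[col] * config$spikes$rho[i])
    }
  }
  hit <- matrix(runif(n * P), n, P) < thr

  ri <- rep(seq_len(n), P)[hit]
  tm <- rep(events$term, each = n)[hit]
  reactions <- split(tm, factor(ri, levels = seq_len(n)))
  empty <- lengths(reactions) == 0
  reactions[empty] <- list("drug ineffective")
  reactions <- unname(reactions)

  dem <- config$demographics
  sex <- sample(names(dem$sex_probs), n, replace = TRUE,
                prob = dem$sex_probs)
  comp <- sample(seq_along(dem$age$weights), n, replace = TRUE,
                 prob = dem$age$weights)
  age <- pmin(120, pmax(0, rnorm(n, dem$age$means[comp], dem$age$sds[comp])))
  age[runif(n) < dem$age$missing] <- NA_real_
  country <- sample(names(dem$country), n, replace = TRUE,
                    prob = dem$country)
  country[country == "unknown"] <- NA_character_

  om <- config$outcome_model
  serious <- runif(n) < om$p_serious
  code <- sample(names(om$serious_code_probs), n, replace = TRUE,
                 prob = om$serious_code_probs)
  ot_extra <- runif(n) < om$p_ot_extra
  ot_ns <- runif(n) < om$p_ot_nonserious
  outcomes <- lapply(seq_len(n), function(i) {
    if (serious[i]) {
      unique(c(code[i], if (ot_extra[i]) "OT"))
    } else if (ot_ns[i]) "OT" else character()
  })

  lo <- quarter_bounds(config$window[1])$start
  hi <- quarter_bounds(config$window[2])$end
  fda_date <- lo + sample.int(as.integer(hi - lo) + 1L, n, replace = TRUE) - 1L

  primary_id <- as.character(10000000L + seq_len(n))
  case_id <- paste0("C", primary_id)

  reports <- tibble::tibble(
    primary_id = primary_id, case_id = case_id, fda_date = fda_date,
    drugs = lapply(drug, function(d) c(PS = d)),
    reactions = reactions, sex = sex, age_years = age, country = country,
    outcomes = outcomes
  )

  n_dup <- rbinom(1, n, config$duplicate_rate)
  dup_tbl <- tibble::tibble(primary_id = character(),
                            duplicate_of = character())
  if (n_dup > 0) {
    idx <- sort(sample.int(n, n_dup))
    clones <- reports[idx, , drop = FALSE]
    clones$primary_id <- as.character(10000000L + n + seq_len(n_dup))
    # follow-up versions arrive later but stay inside the study window; on a
    # date tie the higher entry identifier still selects the clone
    clones$fda_date <- pmin(hi, clones$fda_date +
                              sample(30:365, n_dup, replace = TRUE))
    reports <- dplyr::bind_rows(reports, clones)
    dup_tbl <- tibble::tibble(primary_id = clones$primary_id,
                              duplicate_of = reports$primary_id[idx])
  }

  rho <- rho_matrix(config)
  pairs <- tidyr::expand_grid(drug = menu$drug, term = events$term)
  pairs$rho <- rho[cbind(pairs$drug, pairs$term)]

  list(reports = validate_ae_reports(reports),
       truth = list(pairs = pairs, duplicates = dup_tbl, n_cases = n))
}

#' Odds ratio implied by the generative model
#'
#' Closed form from the configuration: with normalised drug weights `w` and
#' per-drug event probability `q_d = min(1, baseline * rho(d, term))`, the
#' reporting odds ratio of a (drug, term) pair is the exposed odds
#' `q_d / (1 - q_d)` over the comparator odds
#' `sum(w' q') / sum(w' (1 - q'))` across the other drugs. For rare events
#' this approaches the spiked rate ratio.
#'
#' @param config A [synthetic_config()].
#' @param drug,term A pair present in the menus.
#' @return The theoretical odds ratio (a single number).
#' @export
expected_ror <- function(config, drug, term) {
  stopifnot(inherits(config, "synthetic_config"))
  menu <- config$drug_menu
  events <- config$event_menu
  if (!drug %in% menu$drug) abort(paste0("unknown drug: ", drug))
  if (!term %in% events$term) abort(paste0("unknown term: ", term))
  w <- menu$weight / sum(menu$weight)
  base <- events$baseline[events$term == term]
  rho <- rho_matrix(config)[, term]
  q <- pmin(1, base * rho)
  i <- match(drug, menu$drug)
  odds_exposed <- q[i] / (1 - q[i])
  comp_q <- sum(w[-i] * q[-i]) / sum(w[-i])
  odds_comp <- comp_q / (1 - comp_q)
  odds_exposed / odds_comp
}

#' Write a simulated dataset to disk
#'
#' Emits the report collection in the package CSV dialect plus ground-truth
#' sidecar files (`truth_pairs.csv` with the true rate ratios,
#' `truth_duplicates.csv` with the duplicate links) and a `config.json`
#' run record.
#'
#' @param sim Result of [simulate_reports()].
#' @param dir Output directory (created if needed).
#' @param config The [synthetic_config()] used (recorded as JSON metadata).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ae_reports(sim$reports, file.path(dir, "reports.csv"))
  readr::write_csv(sim$truth$pairs, file.path(dir, "truth_pairs.csv"),
                   progress = FALSE)
  readr::write_csv(sim$truth$duplicates,
                   file.path(dir, "truth_duplicates.csv"), progress = FALSE)
  if (!is.null(config)) {
    meta <- config
    class(meta) <- NULL
    jsonlite::write_json(meta, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(dir)
}
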