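#' Age-band labels used in the descriptive and subgroup analyses
#'
#' Bands are `<19` (age < 19), `19-45` (19 <= age <= 45), `46-65`
#' (46 <= age <= 65), `>65` (age > 65) and `unknown` for missing ages;
#' boundaries are inclusive on the side written.
#'
#' @param age_years Numeric vector of ages (`NA` for unknown).
#' @return Factor with levels `<19`, `19-45`, `46-65`, `>65`, `unknown`.
#' @examples
#' assign_age_bin(c(18.9, 45, 46, 80, NA))
#' @export
assign_age_bin <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) abort("age cannot be negative")
  lv <- c("<19", "19-45", "46-65", ">65", "unknown")
  out <- dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 19 ~ "<19",
    age_years <= 45 ~ "19-45",
    age_years <= 65 ~ "46-65",
    TRUE ~ ">65"
  )
  factor(out, levels = lv)
}

#' Per-drug report counts and shares within a class cohort
#'
#' @param reports Reports restricted to one class cohort (deduplicated).
#' @param catalog A [drug_catalog()].
#' @param class Optional class label; when given, only primary-suspect drugs
#'   of that class are tabulated (other reports are dropped with a warning).
#' @return Tibble `drug`, `n`, `percent` (percent of the cohort total,
#'   rounded half-up to 2 decimals), sorted by the catalog's drug order.
#' @export
drug_share <- function(reports, catalog = drug_catalog(), class = NULL) {
  if (nrow(reports) == 0) abort("empty cohort")
  drug <- ps_drug(reports)
  if (!is.null(class)) {
    keep <- drug %in% class_drugs(catalog, class)
    if (!all(keep)) {
      warn(paste0(sum(!keep), " report(s) without a primary-suspect ", class,
                  " drug dropped from the share table"))
    }
    drug <- drug[keep]
    if (length(drug) == 0) abort("empty cohort")
  }
  out <- dplyr::count(tibble::tibble(drug = drug), .data$drug, name = "n")
  ord <- match(out$drug, catalog$classes$drug)
  out <- out[order(ifelse(is.na(ord), Inf, ord), out$drug), ]
  dplyr::mutate(out, percent = round_half_up(100 * .data$n / sum(.data$n), 2))
}

#' Sex, age-band and country distribution of a report cohort
#'
#' Counts and percentages per category, including the `not_specified` and
#' `unknown` rows kept separate; countries are ranked by descending count.
#' Percentages are rounded half-up to 2 decimals and are relative to the
#' full cohort size.
#'
#' @param reports A report-collection tibble.
#' @param top_countries How many countries to keep (default 3, the
#'   conventional presentation); `Inf` keeps all.
#' @return Tibble with columns `variable` (`sex`/`age`/`country`),
#'   `category`, `n`, `percent`.
#' @export
demographic_table <- function(reports, top_countries = 3) {
  N <- nrow(reports)
  pct <- function(n) round_half_up(100 * n / N, 2)

  sex <- dplyr::count(reports, category = factor(.data$sex, .SEX_LEVELS),
                      name = "n", .drop = FALSE)
  sex <- dplyr::mutate(sex, variable = "sex", category = as.character(.data$category))

  age <- dplyr::count(reports, category = assign_age_bin(.data$age_years),
                      name = "n", .drop = FALSE)
  age <- dplyr::mutate(age, variable = "age", category = as.character(.data$category))

  country <- dplyr::count(
    tibble::tibble(category = ifelse(is.na(reports$country), "unknown",
                                     reports$country)),
    .data$category, name = "n")
  country <- dplyr::arrange(country,
                            dplyr::desc(.data$n), .data$category)
  country <- dplyr::mutate(country, variable = "country")
  known <- country[country$category != "unknown", , drop = FALSE]
  country <- utils::head(known, n = top_countries)

  out <- dplyr::bind_rows(sex, age, country)
  dplyr::transmute(out, .data$variable, .data$category, .data$n,
                   percent = pct(.data$n))
}

#' Median and quartiles of the known ages
#'
#' @param reports A report-collection tibble.
#' @return One-row tibble `n_known`, `median`, `q1`, `q3`; the quantiles are
#'   `NA` when no age is known.
#' @export
age_summary <- function(reports) {
  known <- reports$age_years[!is.na(reports$age_years)]
  if (length(known) == 0) {
    return(tibble::tibble(n_known = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_))
  }
  q <- stats::quantile(known, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(n_known = length(known), median = q[2], q1 = q[1], q3 = q[3])
}

#' Outcome codes counted as serious
#'
#' The core serious outcomes are death (`DE`), life-threatening event
#' (`LT`), hospitalization (`HO`), disability (`DS`) and congenital anomaly
#' (`CA`). Required intervention (`RI`) is included by default: the reported
#' class-level serious totals equal the five-code sums plus the RI row, so
#' the default reproduces the published rates; set `include_ri = FALSE` for
#' the strict five-code rule.
#'
#' @param include_ri Include `RI` (default `TRUE`).
#' @return Character vector of outcome codes.
#' @export
serious_codes <- function(include_ri = TRUE) {
  codes <- c("DE", "LT", "HO", "DS", "CA")
  if (include_ri) codes <- c(codes, "RI")
  codes
}

#' Serious-outcome counts and rate
#'
#' A report is serious when its outcome set intersects the rule's codes
#' (counted once however many codes it carries).
#'
#' @param reports A report-collection tibble.
#' @param rule Character vector of serious outcome codes, see
#'   [serious_codes()].
#' @param by Optional grouping: `"drug"` groups by primary-suspect drug.
#' @return Tibble with `n_serious`, `n_total`, `percent` (rounded half-up to
#'   2 decimals), one row per group (or a single row).
#' @export
serious_rate <- function(reports, rule = serious_codes(), by = NULL) {
  if (length(rule) == 0) abort("serious-outcome rule must be non-empty")
  serious <- vapply(reports$outcomes, function(o) any(o %in% rule), logical(1))
  tab <- tibble::tibble(serious = serious)
  if (!is.null(by)) {
    stopifnot(identical(by, "drug"))
    tab$drug <- ps_drug(reports)
    out <- dplyr::summarise(dplyr::group_by(tab, .data$drug),
                            n_serious = sum(.data$serious),
                            n_total = dplyr::n(), .groups = "drop")
  } else {
    out <- dplyr::summarise(tab, n_serious = sum(.data$serious),
                            n_total = dplyr::n())
  }
  dplyr::mutate(out,
                percent = round_half_up(100 * .data$n_serious / .data$n_total, 2))
}

#' Compare serious-outcome rates across groups
#'
#' Standard r-by-2 Pearson chi-square test of homogeneity of the serious
#' proportion across groups (no continuity correction), df = r - 1.
#'
#' @param groups Data frame with columns `n_serious` and `n_total`
#'   (one row per group, at least two rows).
#' @return One-row tibble `chi2`, `df`, `p`.
#' @examples
#' compare_rates(tibble::tibble(n_serious = c(90, 10), n_total = c(100, 100)))
#' @export
compare_rates <- function(groups) {
  stopifnot(all(c("n_serious", "n_total") %in% names(groups)))
  if (nrow(groups) < 2) abort("need at least two groups")
  if (any(groups$n_total <= 0)) abort("group totals must be positive")
  if (any(groups$n_serious > groups$n_total)) {
    abort("n_serious cannot exceed n_total")
  }
  m <- cbind(groups$n_serious, groups$n_total - groups$n_serious)
  exp_cells <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_cells == 0)) abort("a zero expected cell: rates not comparable")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(chi2 = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = unname(ht$p.value))
}

#' Yearly report counts, overall and for an SMQ
#'
#' Tallies reports per calendar year of the FDA acceptance date, both all
#' reports and the subset matching the SMQ; years with no reports inside the
#' observed range appear with zero counts.
#'
#' @param reports A report-collection tibble.
#' @param catalog An `smq_catalog`.
#' @param smq SMQ title, default the catalog root.
#' @return Tibble `year`, `n_total`, `n_smq`. Class `yearly_trend` (plot via
#'   [plot_yearly_trend()]).
#' @export
yearly_trend <- function(reports, catalog, smq = smq_root(catalog)) {
  if (nrow(reports) == 0) {
    return(tibble::tibble(year = integer(), n_total = integer(),
                          n_smq = integer()))
  }
  year <- as.integer(format(reports$fda_date, "%Y"))
  hit <- report_matches_smq(reports, catalog, smq)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(year = year, hit = hit), .data$year),
    n_total = dplyr::n(), n_smq = sum(.data$hit), .groups = "drop")
  all_years <- tibble::tibble(year = seq(min(year), max(year)))
  out <- dplyr::left_join(all_years, out, by = "year")
  out <- dplyr::mutate(out,
                       n_total = tidyr::replace_na(.data$n_total, 0L),
                       n_smq = tidyr::replace_na(.data$n_smq, 0L))
  class(out) <- c("yearly_trend", class(out))
  out
}

#' Default sex-by-age subgroup grid
#'
#' Male/female crossed with the four known age bands; unknown sex or age is
#' excluded from subgroup estimates (but stays in cohort totals).
#'
#' @return Tibble `sex`, `age_bin` (8 rows).
#' @export
default_strata <- function() {
  tidyr::expand_grid(sex = c("male", "female"),
                     age_bin = c("<19", "19-45", "46-65", ">65"))
}

#' Sex-by-age subgroup disproportionality
#'
#' For each stratum, both the exposed and the comparator reports are
#' restricted to the stratum, the fourfold table is rebuilt and all four
#' statistics plus the joint decision are recomputed. Strata without any
#' exposed-and-event report (`a = 0`) are returned with `no_data = TRUE`
#' and `NA` metrics.
#'
#' @param reports A deduplicated report-collection tibble.
#' @param target_drugs Character vector of canonical drug names.
#' @param event_terms Character vector of preferred terms.
#' @param strata Data frame with columns `sex` and/or `age_bin`; rows must
#'   be disjoint subgroups (default [default_strata()]).
#' @param fit Optional [mgps_fit()] reused across strata; fitted on the full
#'   dataset's drug-term cells when `NULL`.
#' @inheritParams signal_table
#' @return Tibble with one row per stratum: stratum labels, `no_data`, and
#'   the [signal_table()] metric/decision columns where computable.
#' @export
subgroup_signals <- function(reports, target_drugs, event_terms,
                             strata = default_strata(), fit = NULL,
                             priors = bcpnn_priors(),
                             thresholds = signal_thresholds(),
                             zero_cell = c("flag", "haldane"),
                             ebgm_quantile = 0.05, role = "PS") {
  zero_cell <- match.arg(zero_cell)
  if (is.null(fit)) fit <- mgps_fit(mgps_cells(reports, role = role))
  age_bin <- as.character(assign_age_bin(reports$age_years))

  purrr::pmap_dfr(strata, function(...) {
    s <- list(...)
    keep <- rep(TRUE, nrow(reports))
    if (!is.null(s$sex)) keep <- keep & reports$sex == s$sex
    if (!is.null(s$age_bin)) keep <- keep & age_bin == s$age_bin
    sub <- reports[keep, , drop = FALSE]
    lab <- tibble::as_tibble(s)
    if (nrow(sub) == 0) {
      return(dplyr::mutate(lab, no_data = TRUE))
    }
    ct <- contingency_table(sub, target_drugs, event_terms, role = role)
    if (ct$a == 0) {
      return(dplyr::bind_cols(lab, ct, tibble::tibble(no_data = TRUE)))
    }
    res <- finish_signal_table(ct, fit, priors, thresholds, zero_cell,
                               ebgm_quantile)
    dplyr::bind_cols(lab, tibble::tibble(no_data = FALSE),
                     tibble::as_tibble(res))
  })
}
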