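#' Disproportionality metrics for named drug-set / event-set pairs
#'
#' The workhorse of an analysis run: for every combination of an exposure
#' (a named set of canonical drug names) and an event definition (a named
#' set of preferred terms, typically an SMQ's effective terms), builds the
#' fourfold table against the rest of the loaded reports, computes all four
#' disproportionality statistics with their bounds and applies the joint
#' positive-signal rule.
#'
#' The EBGM step needs the dataset-wide gamma-mixture prior; when `fit` is
#' `NULL` it is fitted once on all (primary-suspect drug, preferred term)
#' cells of `reports` via [mgps_cells()] + [mgps_fit()]. The expected count
#' of each analysed pair uses the table's own margins, `E = (a+b)(a+c)/N`.
#'
#' @param reports A deduplicated report-collection tibble.
#' @param exposures Named list of character vectors of canonical drug names
#'   (a bare character vector is treated as a single exposure set).
#' @param events Named list of character vectors of preferred terms (a bare
#'   character vector is one event set).
#' @param fit Optional [mgps_fit()] object; fitted from the data when `NULL`.
#' @param priors [bcpnn_priors()] for the information component.
#' @param thresholds [signal_thresholds()] for the decision.
#' @param zero_cell Zero-cell policy for ROR/PRR, see [ror_stats()].
#' @param ebgm_quantile Lower posterior quantile for EBGM05, default 0.05.
#' @param role Drug role defining exposure.
#' @return Tibble with one row per exposure-event combination: identifiers,
#'   cells `a`-`d`, `n`, `expected`, all metrics, pass flags and `positive`.
#'   Class `signal_table` (plots via [plot_signal_intervals()]).
#' @examples
#' \dontrun{
#' catalog <- read_smq_catalog(example_smq_path())
#' signal_table(
#'   reports,
#'   exposures = list(sitagliptin = "sitagliptin"),
#'   events = list(biliary = effective_terms(catalog, "biliary disorders"))
#' )
#' }
#' @export
signal_table <- function(reports, exposures, events, fit = NULL,
                         priors = bcpnn_priors(),
                         thresholds = signal_thresholds(),
                         zero_cell = c("flag", "haldane"),
                         ebgm_quantile = 0.05, role = "PS") {
  zero_cell <- match.arg(zero_cell)
  if (is.character(exposures)) exposures <- list(exposure = exposures)
  if (is.character(events)) events <- list(event = events)
  stopifnot(length(exposures) > 0, length(events) > 0,
            !is.null(names(exposures)), !is.null(names(events)))
  if (is.null(fit)) fit <- mgps_fit(mgps_cells(reports, role = role))

  combos <- tidyr::expand_grid(exposure = names(exposures),
                               event = names(events))
  tabs <- purrr::pmap_dfr(combos, function(exposure, event) {
    ct <- contingency_table(reports, exposures[[exposure]], events[[event]],
                            role = role)
    dplyr::mutate(ct, exposure = exposure, event = event, .before = 1)
  })
  finish_signal_table(tabs, fit, priors, thresholds, zero_cell, ebgm_quantile)
}

# shared tail of signal_table()/drug_event_signals(): metrics + decision.
# Rows with a zero margin (an event matching no report, or an exposure
# covering everything) cannot carry PRR/EBGM; they are kept with NA metrics
# so a sweep over many event sets never aborts.
finish_signal_table <- function(tabs, fit, priors, thresholds, zero_cell,
                                ebgm_quantile) {
  out <- dplyr::mutate(tabs,
                       n = .data$a,
                       expected = as.numeric(.data$a + .data$b) *
                         (.data$a + .data$c) /
                         (as.numeric(.data$a) + .data$b + .data$c + .data$d))
  ok <- with(out, a + b > 0 & c + d > 0 & a + c > 0 & b + d > 0)
  res <- out[ok, , drop = FALSE]
  res <- ror_stats(res, zero_cell = zero_cell)
  res <- prr_stats(res, zero_cell = zero_cell)
  res <- bcpnn_ic(res, priors = priors)
  res <- ebgm_scores(res, fit, quantile = ebgm_quantile)
  if (!all(ok)) {
    res <- dplyr::bind_rows(res, dplyr::mutate(out[!ok, , drop = FALSE],
                                               ror_defined = FALSE,
                                               prr_defined = FALSE))
    res <- res[order(c(which(ok), which(!ok))), , drop = FALSE]
  }
  res <- evaluate_signals(res, thresholds)
  class(res) <- c("signal_table", class(res))
  res
}

#' Disproportionality metrics for every drug-event pair in a dataset
#'
#' Screens all (primary-suspect drug, preferred term) pairs at once, the way
#' a signal-detection sweep is run on a whole extract: per-pair fourfold
#' cells are derived from the report-level margins, and the same metric and
#' decision columns as [signal_table()] are attached.
#'
#' @inheritParams signal_table
#' @param min_n Drop pairs with fewer observed reports than this (default 0,
#'   keep all).
#' @return A `signal_table` tibble with one row per (drug, term) pair,
#'   identified by columns `exposure` and `event`.
#' @export
drug_event_signals <- function(reports, fit = NULL, priors = bcpnn_priors(),
                               thresholds = signal_thresholds(),
                               zero_cell = c("flag", "haldane"),
                               ebgm_quantile = 0.05, role = "PS",
                               min_n = 0) {
  zero_cell <- match.arg(zero_cell)
  cells <- mgps_cells(reports, role = role)
  if (is.null(fit)) fit <- mgps_fit(cells)
  N <- nrow(reports)
  tabs <- dplyr::mutate(cells,
                        a = .data$n,
                        b = .data$n_drug - .data$n,
                        c = .data$n_term - .data$n,
                        d = N - .data$n_drug - .data$n_term + .data$n)
  tabs <- dplyr::filter(tabs, .data$n >= min_n)
  tabs <- dplyr::transmute(tabs, exposure = .data$drug, event = .data$term,
                           a = .data$a, b = .data$b, c = .data$c, d = .data$d)
  finish_signal_table(tabs, fit, priors, thresholds, zero_cell, ebgm_quantile)
}
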