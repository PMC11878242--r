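#' Build the fourfold (2x2) table for a drug-set / event-set pair
#'
#' Classifies every report into exactly one cell of the disproportionality
#' fourfold table: exposure means the report names a drug from `target_drugs`
#' in the given role (default primary suspect), the event means the report's
#' reaction set intersects `event_terms`. The counting unit is the report: a
#' report with several matching reaction terms still counts once.
#'
#' @param reports A deduplicated report-collection tibble.
#' @param target_drugs Character vector of canonical drug names.
#' @param event_terms Non-empty character vector of preferred terms (use
#'   [effective_terms()] for an SMQ).
#' @param role Drug role code defining exposure, default `"PS"`.
#' @return One-row tibble with columns `a`, `b`, `c`, `d`
#'   (target drug & target event, target drug & other events, other drugs &
#'   target event, other drugs & other events).
#' @examples
#' \dontrun{
#' contingency_table(reports, c("sitagliptin"), effective_terms(cat, "gallstone related disorders"))
#' }
#' @export
contingency_table <- function(reports, target_drugs, event_terms,
                              role = "PS") {
  if (nrow(reports) == 0) abort("report set is empty: N must be positive")
  if (length(event_terms) == 0) abort("event term set must be non-empty")
  event_terms <- tolower(trimws(event_terms))
  exposed <- vapply(reports$drugs, function(d) {
    any(unname(d) %in% target_drugs & names(d) == role)
  }, logical(1))
  event <- vapply(reports$reactions, function(r) any(r %in% event_terms),
                  logical(1))
  tibble::tibble(
    a = sum(exposed & event),
    b = sum(exposed & !event),
    c = sum(!exposed & event),
    d = sum(!exposed & !event)
  )
}

# the conventional 1.96 at the default level, exact quantile otherwise
ci_z <- function(conf_level) {
  if (identical(conf_level, 0.95)) 1.96
  else stats::qnorm(1 - (1 - conf_level) / 2)
}

check_cells <- function(tbl) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  with(tbl, {
    if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
    if (any(a + b + c + d == 0)) abort("N = a+b+c+d must be positive")
  })
  invisible(tbl)
}

#' Reporting odds ratio with Woolf confidence bounds
#'
#' ROR = (a/b) / (c/d); the two-sided Woolf interval is
#' exp(ln ROR +- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' With a zero cell the estimate or its interval is undefined; the default
#' policy returns `NA` for the affected quantities and sets `ror_defined`
#' to `FALSE` (so the signal rule fails the criterion rather than guessing),
#' the alternative `"haldane"` policy adds 0.5 to every cell first.
#'
#' @param tbl Data frame with integer columns `a`, `b`, `c`, `d`
#'   (one row per table; vectorised).
#' @param conf_level Confidence level of the interval, default 0.95.
#' @param zero_cell `"flag"` (default) or `"haldane"`.
#' @return `tbl` with columns `ror`, `ror_lo`, `ror_hi`, `ror_defined` added.
#' @examples
#' ror_stats(tibble::tibble(a = 25, b = 75, c = 100, d = 900))
#' @export
ror_stats <- function(tbl, conf_level = 0.95, zero_cell = c("flag", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  check_cells(tbl)
  z <- ci_z(conf_level)
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  c <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  defined <- a > 0 & b > 0 & c > 0 & d > 0
  if (zero_cell == "haldane") {
    adj <- !defined
    a <- a + 0.5 * adj; b <- b + 0.5 * adj
    c <- c + 0.5 * adj; d <- d + 0.5 * adj
    defined <- rep(TRUE, length(a))
  }
  est <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- dplyr::mutate(
    tbl,
    ror = ifelse(defined, est, NA_real_),
    ror_lo = ifelse(defined, est * exp(-z * se), NA_real_),
    ror_hi = ifelse(defined, est * exp(z * se), NA_real_),
    ror_defined = defined
  )
  out
}

#' Proportional reporting ratio, its confidence bounds, and Pearson's chi-square
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\] with log-scale interval
#' exp(ln PRR +- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))); the chi-square is
#' the Pearson statistic N(ad - bc)^2 / \[(a+b)(c+d)(a+c)(b+d)\], computed
#' without continuity correction by default.
#'
#' @inheritParams ror_stats
#' @param yates Apply Yates' continuity correction to the chi-square
#'   statistic (default `FALSE`).
#' @return `tbl` with columns `prr`, `prr_lo`, `prr_hi`, `prr_defined`,
#'   `chi2` added. A table with `a = 0` but positive margins yields
#'   `prr = 0` with undefined interval; a zero margin is an error.
#' @examples
#' prr_stats(tibble::tibble(a = 25, b = 75, c = 100, d = 900))
#' @export
prr_stats <- function(tbl, conf_level = 0.95, yates = FALSE,
                      zero_cell = c("flag", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  check_cells(tbl)
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  c <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  n1 <- a + b; n0 <- c + d; e1 <- a + c; e0 <- b + d
  if (any(n1 == 0 | n0 == 0 | e1 == 0 | e0 == 0)) {
    abort("zero margin: PRR and chi-square are undefined")
  }
  z <- ci_z(conf_level)
  n <- n1 + n0
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  chi2 <- n * dev^2 / (n1 * n0 * e1 * e0)

  defined <- a > 0 & c > 0
  aa <- a; cc <- c
  if (zero_cell == "haldane") {
    adj <- !defined
    aa <- a + 0.5 * adj; cc <- c + 0.5 * adj
    n1 <- n1 + 1 * adj; n0 <- n0 + 1 * adj
    defined <- rep(TRUE, length(a))
  }
  est <- (aa / n1) / (cc / n0)
  se <- sqrt(1 / aa - 1 / n1 + 1 / cc - 1 / n0)
  dplyr::mutate(
    tbl,
    prr = ifelse(a == 0 & zero_cell == "flag", 0, ifelse(defined, est, NA_real_)),
    prr_lo = ifelse(defined, est * exp(-z * se), NA_real_),
    prr_hi = ifelse(defined, est * exp(z * se), NA_real_),
    prr_defined = defined,
    chi2 = chi2
  )
}

#' Prior pseudo-counts for the BCPNN information component
#'
#' The defaults (`alpha1 = beta1 = gamma11 = 1`, `alpha = beta = 2`) are the
#' standard uninformative choice for the two marginal Beta priors and the
#' joint cell; the joint prior count `gamma` is tied to the marginals so that
#' the prior expectation of the information component is zero.
#'
#' @param alpha1,beta1 Pseudo-counts of the two marginal "success" cells.
#' @param alpha,beta Marginal totals' pseudo-counts.
#' @param gamma11 Joint-cell pseudo-count.
#' @return A list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11)
  if (any(vals <= 0)) abort("all BCPNN prior pseudo-counts must be positive")
  structure(as.list(vals), class = "bcpnn_priors")
}

#' Information component of the Bayesian confidence propagation neural network
#'
#' The information component IC = log2 of the ratio of the joint reporting
#' probability to the product of its margins. With the independent-Beta
#' posterior of Bate et al. the closed forms are
#' \deqn{E(IC) = \log_2 \frac{(n+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(n_{1.}+\alpha_1)(n_{.1}+\beta_1)}}
#' with \eqn{\gamma = \gamma_{11}(N+\alpha)(N+\beta) /
#' ((n_{1.}+\alpha_1)(n_{.1}+\beta_1))}, and the delta-method variance
#' \deqn{V(IC) = (\ln 2)^{-2} \left[
#'   \frac{N-n+\gamma-\gamma_{11}}{(n+\gamma_{11})(1+N+\gamma)} +
#'   \frac{N-n_{1.}+\alpha-\alpha_1}{(n_{1.}+\alpha_1)(1+N+\alpha)} +
#'   \frac{N-n_{.1}+\beta-\beta_1}{(n_{.1}+\beta_1)(1+N+\beta)} \right].}
#' IC025 = E(IC) - 1.96 sqrt(V(IC)). A Monte-Carlo posterior-quantile mode
#' (`method = "mc"`) draws the three Beta posteriors directly and reports the
#' sample mean and 2.5% quantile of the IC draws; it exists for validation of
#' the closed form.
#'
#' @inheritParams ror_stats
#' @param priors A [bcpnn_priors()] object.
#' @param method `"closed"` (default) or `"mc"`.
#' @param mc_draws Number of Monte-Carlo draws when `method = "mc"`.
#' @return `tbl` with columns `ic` and `ic025` added (and `ic_var` for the
#'   closed form).
#' @examples
#' bcpnn_ic(tibble::tibble(a = 25, b = 75, c = 100, d = 900))
#' @export
bcpnn_ic <- function(tbl, priors = bcpnn_priors(),
                     method = c("closed", "mc"), mc_draws = 1e5) {
  method <- match.arg(method)
  check_cells(tbl)
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  c <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  n <- a; n1 <- a + b; e1 <- a + c; N <- a + b + c + d
  p <- priors
  gamma <- p$gamma11 * (N + p$alpha) * (N + p$beta) /
    ((n1 + p$alpha1) * (e1 + p$beta1))
  if (method == "closed") {
    eic <- log2((n + p$gamma11) * (N + p$alpha) * (N + p$beta) /
                  ((N + gamma) * (n1 + p$alpha1) * (e1 + p$beta1)))
    vic <- ((N - n + gamma - p$gamma11) / ((n + p$gamma11) * (1 + N + gamma)) +
              (N - n1 + p$alpha - p$alpha1) / ((n1 + p$alpha1) * (1 + N + p$alpha)) +
              (N - e1 + p$beta - p$beta1) / ((e1 + p$beta1) * (1 + N + p$beta))) /
      log(2)^2
    dplyr::mutate(tbl, ic = eic, ic_var = vic,
                  ic025 = eic - 1.96 * sqrt(vic))
  } else {
    draws <- function(i) {
      p11 <- stats::rbeta(mc_draws, n[i] + p$gamma11,
                          N[i] - n[i] + gamma[i] - p$gamma11)
      p1 <- stats::rbeta(mc_draws, n1[i] + p$alpha1,
                         N[i] - n1[i] + p$alpha - p$alpha1)
      p2 <- stats::rbeta(mc_draws, e1[i] + p$beta1,
                         N[i] - e1[i] + p$beta - p$beta1)
      log2(p11 / (p1 * p2))
    }
    res <- vapply(seq_along(a), function(i) {
      x <- draws(i)
      c(mean(x), stats::quantile(x, 0.025, names = FALSE))
    }, numeric(2))
    dplyr::mutate(tbl, ic = res[1, ], ic025 = res[2, ])
  }
}

#' Joint positive-signal thresholds
#'
#' The decision rule requires all four methods to clear their threshold:
#' ROR: n >= 3 and lower 95% bound > 1; PRR: chi-square >= 4 and lower 95%
#' bound > 1; BCPNN: IC025 > 0; EBGM: EBGM05 > 2.
#'
#' @param n_min Minimum report count for the ROR criterion.
#' @param ror_lo,prr_lo Lower-bound thresholds (exclusive).
#' @param chi2_min Minimum chi-square for the PRR criterion.
#' @param ic025,ebgm05 Lower-bound thresholds (exclusive).
#' @return A list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(n_min = 3, ror_lo = 1, chi2_min = 4,
                              prr_lo = 1, ic025 = 0, ebgm05 = 2) {
  structure(list(n_min = n_min, ror_lo = ror_lo, chi2_min = chi2_min,
                 prr_lo = prr_lo, ic025 = ic025, ebgm05 = ebgm05),
            class = "signal_thresholds")
}

#' Evaluate the joint positive-signal rule
#'
#' Adds one pass flag per method and their conjunction. An undefined metric
#' (`NA`, e.g. from a zero cell under the flagging policy) fails its
#' criterion.
#'
#' @param metrics Data frame carrying columns `n`, `ror_lo`, `chi2`,
#'   `prr_lo`, `ic025`, `ebgm05` (as produced by [signal_table()] or by
#'   chaining the individual statistics).
#' @param thresholds A [signal_thresholds()] profile.
#' @return `metrics` with logical columns `ror_pass`, `prr_pass`, `ic_pass`,
#'   `ebgm_pass`, `positive` added.
#' @export
evaluate_signals <- function(metrics, thresholds = signal_thresholds()) {
  th <- thresholds
  pass <- function(x) !is.na(x) & x
  dplyr::mutate(
    metrics,
    ror_pass = pass(.data$n >= th$n_min & .data$ror_lo > th$ror_lo),
    prr_pass = pass(.data$chi2 >= th$chi2_min & .data$prr_lo > th$prr_lo),
    ic_pass = pass(.data$ic025 > th$ic025),
    ebgm_pass = pass(.data$ebgm05 > th$ebgm05),
    positive = .data$ror_pass & .data$prr_pass & .data$ic_pass &
      .data$ebgm_pass
  )
}
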