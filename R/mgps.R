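#' Per-cell observed and expected counts for the gamma-Poisson shrinker
#'
#' Tallies, for every (primary-suspect drug, preferred term) pair present in
#' the data, the number of reports naming both (`n`) and the expected count
#' under row/column independence of the report-level margins,
#' `E = n_drug * n_term / N`. These cells are the input to [mgps_fit()].
#'
#' @param reports A deduplicated report-collection tibble.
#' @param role Drug role defining exposure, default `"PS"`.
#' @return Tibble with columns `drug`, `term`, `n`, `expected`, plus the
#'   margins `n_drug`, `n_term` and the report total `n_reports`.
#' @export
mgps_cells <- function(reports, role = "PS") {
  drug <- vapply(reports$drugs, function(d) {
    i <- which(names(d) == role)
    if (length(i) == 0) NA_character_ else unname(d[i[1]])
  }, character(1))
  keep <- !is.na(drug)
  reactions <- reports$reactions[keep]
  drug <- drug[keep]
  N <- nrow(reports)
  long <- tibble::tibble(
    report = rep(seq_along(reactions), lengths(reactions)),
    drug = rep(drug, lengths(reactions)),
    term = unlist(reactions)
  )
  long <- dplyr::distinct(long)
  drug_tot <- dplyr::count(tibble::tibble(drug = drug), .data$drug,
                           name = "n_drug")
  term_tot <- dplyr::count(dplyr::distinct(long, .data$report, .data$term),
                           .data$term, name = "n_term")
  cells <- dplyr::count(long, .data$drug, .data$term, name = "n")
  cells <- dplyr::left_join(cells, drug_tot, by = "drug")
  cells <- dplyr::left_join(cells, term_tot, by = "term")
  dplyr::transmute(cells, .data$drug, .data$term, .data$n,
                   expected = as.numeric(.data$n_drug) * .data$n_term / N,
                   n_drug = .data$n_drug, n_term = .data$n_term,
                   n_reports = N)
}

nb_mix_loglik <- function(theta, n, E) {
  # theta on the working scale: log shapes/rates, logit weight
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  l1 <- dnbinom(n, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- dnbinom(n, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1 + log(w), l2 + log1p(-w))
  sum(m + log(exp(l1 + log(w) - m) + exp(l2 + log1p(-w) - m)))
}

#' Fit the gamma-mixture prior of the multi-item gamma-Poisson shrinker
#'
#' The shrinker models each cell's observed count as
#' `n ~ Poisson(lambda * E)` with the reporting-rate ratio `lambda` drawn
#' from a two-component gamma mixture
#' `w * Gamma(shape1, rate1) + (1 - w) * Gamma(shape2, rate2)`.
#' Marginally each count is a mixture of negative binomials; the
#' hyperparameters are chosen by maximising the summed log marginal
#' likelihood over all cells, deterministically from the fixed starting
#' point.
#'
#' @param cells Data frame with columns `n` (observed counts) and `expected`
#'   (expected counts, all positive), e.g. from [mgps_cells()].
#' @param init Starting values `c(shape1, rate1, shape2, rate2, w)`;
#'   default `c(0.2, 0.1, 2, 4, 1/3)`.
#' @return An object of class `mgps`: hyperparameters, log-likelihood at the
#'   optimum and at the start, convergence flag and the optimiser evaluation
#'   trace. Methods: [tidy.mgps()], [glance.mgps()], `print`.
#' @examples
#' \dontrun{
#' fit <- mgps_fit(mgps_cells(reports))
#' tidy(fit)
#' }
#' @export
mgps_fit <- function(cells, init = c(0.2, 0.1, 2, 4, 1 / 3)) {
  stopifnot(all(c("n", "expected") %in% names(cells)))
  n <- cells$n
  E <- cells$expected
  if (length(n) < 2) {
    abort("degenerate input: the mixture prior cannot be fit to fewer than 2 cells")
  }
  if (any(E <= 0)) abort("all expected counts must be positive")
  stopifnot(length(init) == 5, all(init[1:4] > 0), init[5] > 0, init[5] < 1)

  theta0 <- c(log(init[1:4]), stats::qlogis(init[5]))
  trace_env <- new.env(parent = emptyenv())
  trace_env$vals <- numeric()
  obj <- function(theta) {
    ll <- nb_mix_loglik(theta, n, E)
    if (!is.finite(ll)) ll <- -1e10
    trace_env$vals <- c(trace_env$vals, ll)
    -ll
  }
  # box constraints keep the components away from numerically degenerate
  # point masses (shape/rate overflow) on pathologically homogeneous data
  opt <- nlminb(theta0, obj,
                lower = c(rep(log(1e-6), 4), stats::qlogis(1e-6)),
                upper = c(rep(log(1e6), 4), stats::qlogis(1 - 1e-6)),
                control = list(iter.max = 500, eval.max = 1000))
  ll0 <- nb_mix_loglik(theta0, n, E)
  trace <- tibble::tibble(eval = seq_along(trace_env$vals),
                          loglik = trace_env$vals)
  if (opt$convergence != 0 && -opt$objective < ll0) {
    cond <- rlang::error_cnd(
      "aesignal_mgps_nonconvergence",
      message = paste0("MGPS fit did not converge: ", opt$message),
      trace_tbl = trace
    )
    rlang::cnd_signal(cond)
  }
  theta <- opt$par
  structure(list(
    shape1 = exp(theta[1]), rate1 = exp(theta[2]),
    shape2 = exp(theta[3]), rate2 = exp(theta[4]),
    w = stats::plogis(theta[5]),
    loglik = -opt$objective, loglik_init = ll0,
    convergence = opt$convergence, message = opt$message,
    n_cells = length(n), init = init, trace = trace
  ), class = "mgps")
}

#' @export
print.mgps <- function(x, ...) {
  cat("<mgps> gamma-mixture prior fit on", x$n_cells, "cells\n")
  cat(sprintf("  component 1: shape %.4g, rate %.4g (mean %.4g), weight %.3f\n",
              x$shape1, x$rate1, x$shape1 / x$rate1, x$w))
  cat(sprintf("  component 2: shape %.4g, rate %.4g (mean %.4g), weight %.3f\n",
              x$shape2, x$rate2, x$shape2 / x$rate2, 1 - x$w))
  cat(sprintf("  log-likelihood %.2f (start %.2f)\n", x$loglik, x$loglik_init))
  invisible(x)
}

#' Tidy the fitted gamma-mixture prior
#'
#' @param x An `mgps` object.
#' @param ... Unused.
#' @return One row per mixture component: `component`, `shape`, `rate`,
#'   `weight`, `mean`.
#' @method tidy mgps
#' @export
tidy.mgps <- function(x, ...) {
  tibble::tibble(
    component = c(1L, 2L),
    shape = c(x$shape1, x$shape2),
    rate = c(x$rate1, x$rate2),
    weight = c(x$w, 1 - x$w),
    mean = c(x$shape1 / x$rate1, x$shape2 / x$rate2)
  )
}

#' One-row summary of an MGPS fit
#'
#' @param x An `mgps` object.
#' @param ... Unused.
#' @return Tibble with `loglik`, `loglik_init`, `n_cells`, `convergence`,
#'   `n_eval`, `prior_mean`.
#' @method glance mgps
#' @export
glance.mgps <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, loglik_init = x$loglik_init, n_cells = x$n_cells,
    convergence = x$convergence, n_eval = nrow(x$trace),
    prior_mean = x$w * x$shape1 / x$rate1 + (1 - x$w) * x$shape2 / x$rate2
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# posterior mixture for one cell: component weights and gamma parameters
posterior_mix <- function(n, E, fit) {
  l1 <- dnbinom(n, size = fit$shape1, prob = fit$rate1 / (fit$rate1 + E),
                log = TRUE) + log(fit$w)
  l2 <- dnbinom(n, size = fit$shape2, prob = fit$rate2 / (fit$rate2 + E),
                log = TRUE) + log1p(-fit$w)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  list(q1 = q1,
       shape1 = fit$shape1 + n, rate1 = fit$rate1 + E,
       shape2 = fit$shape2 + n, rate2 = fit$rate2 + E)
}

mix_cdf <- function(q, post, i) {
  post$q1[i] * pgamma(q, post$shape1[i], rate = post$rate1[i]) +
    (1 - post$q1[i]) * pgamma(q, post$shape2[i], rate = post$rate2[i])
}

# bisection for the posterior quantile, relative tolerance 1e-8
mix_quantile <- function(post, i, p) {
  lo <- 0.5 * min(stats::qgamma(p, post$shape1[i], rate = post$rate1[i]),
                  stats::qgamma(p, post$shape2[i], rate = post$rate2[i]))
  hi <- 2 * max(stats::qgamma(p, post$shape1[i], rate = post$rate1[i]),
                stats::qgamma(p, post$shape2[i], rate = post$rate2[i]))
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (mix_cdf(mid, post, i) < p) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-8 * hi) break
  }
  (lo + hi) / 2
}

#' Empirical Bayes geometric mean and its lower posterior quantile
#'
#' Given the fitted gamma-mixture prior, the posterior of a cell's
#' reporting-rate ratio is again a two-component gamma mixture with updated
#' parameters `(shape_k + n, rate_k + E)` and posterior component weights
#' proportional to the marginal likelihoods. The EBGM is the posterior
#' geometric mean `exp(E[ln lambda])`, using
#' `E[ln lambda] = sum_k Q_k (psi(shape_k + n) - ln(rate_k + E))`; the lower
#' bound `ebgm05` solves `CDF(q) = quantile` by bisection (relative
#' tolerance 1e-8).
#'
#' @param cells Data frame with columns `n` and `expected` (vectorised).
#' @param fit An [mgps_fit()] object.
#' @param quantile Lower posterior quantile, default 0.05 (the MGPS
#'   convention behind the name EBGM05); set 0.025 for a two-sided-style
#'   bound.
#' @return `cells` with columns `ebgm` and `ebgm05` added.
#' @export
ebgm_scores <- function(cells, fit, quantile = 0.05) {
  stopifnot(inherits(fit, "mgps"),
            all(c("n", "expected") %in% names(cells)))
  n <- cells$n
  E <- cells$expected
  if (any(E <= 0)) abort("all expected counts must be positive")
  post <- posterior_mix(n, E, fit)
  elog <- post$q1 * (digamma(post$shape1) - log(post$rate1)) +
    (1 - post$q1) * (digamma(post$shape2) - log(post$rate2))
  e05 <- vapply(seq_along(n), function(i) mix_quantile(post, i, quantile),
                numeric(1))
  dplyr::mutate(cells, ebgm = exp(elog), ebgm05 = e05)
}
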