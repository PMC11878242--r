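#' Build and validate a pipeline run configuration
#'
#' A single configuration object drives an end-to-end run (clean, map,
#' analyse, report). The same fields can be supplied from a YAML file via
#' [read_run_config()].
#'
#' @param input Path to a report CSV in the package dialect.
#' @param catalog Path to an SMQ catalog CSV (default: the bundled synthetic
#'   biliary catalog).
#' @param drug_sets Named list of canonical drug-name vectors to analyse as
#'   exposures; the default is the two study classes plus each individual
#'   study drug.
#' @param smqs SMQ titles to analyse (default: every node of the catalog).
#' @param window Length-2 character vector of quarter specs.
#' @param strata Data frame of subgroup definitions or `NULL` to skip the
#'   subgroup stage (default [default_strata()]).
#' @param subgroup_exposures Names (from `drug_sets`) analysed in the
#'   subgroup stage; default the class-level sets.
#' @param thresholds A [signal_thresholds()] profile.
#' @param zero_cell Zero-cell policy, `"flag"` or `"haldane"`.
#' @param ebgm_quantile Lower posterior quantile for EBGM05.
#' @param serious_rule Serious outcome codes, see [serious_codes()].
#' @param outdir Output directory for the TSV artifacts and run metadata.
#' @param seed Integer seed recorded in metadata and used by any
#'   Monte-Carlo validation mode.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input,
                       catalog = example_smq_path(),
                       drug_sets = NULL,
                       smqs = NULL,
                       window = c("2013Q1", "2024Q1"),
                       strata = default_strata(),
                       subgroup_exposures = NULL,
                       thresholds = signal_thresholds(),
                       zero_cell = "flag",
                       ebgm_quantile = 0.05,
                       serious_rule = serious_codes(),
                       outdir = "aesignal-run",
                       seed = 1L) {
  if (!file.exists(input)) abort(paste0("input file not found: ", input))
  if (!file.exists(catalog)) abort(paste0("catalog file not found: ", catalog))
  quarter_bounds(window[1]); quarter_bounds(window[2])
  if (quarter_bounds(window[1])$start > quarter_bounds(window[2])$end) {
    abort("window start is after window end")
  }
  dc <- drug_catalog()
  if (is.null(drug_sets)) {
    classes <- unique(dc$classes$class)
    drug_sets <- c(
      setNames(lapply(classes, class_drugs, catalog = dc), classes),
      setNames(as.list(dc$classes$drug), dc$classes$drug)
    )
  }
  if (is.null(names(drug_sets)) || any(!nzchar(names(drug_sets)))) {
    abort("drug_sets must be a named list")
  }
  if (is.null(subgroup_exposures)) {
    subgroup_exposures <- intersect(unique(dc$classes$class),
                                    names(drug_sets))
  }
  if (!all(subgroup_exposures %in% names(drug_sets))) {
    abort("subgroup_exposures must name entries of drug_sets")
  }
  stopifnot(inherits(thresholds, "signal_thresholds"),
            zero_cell %in% c("flag", "haldane"),
            ebgm_quantile > 0, ebgm_quantile < 0.5)
  structure(list(
    input = input, catalog = catalog, drug_sets = drug_sets, smqs = smqs,
    window = window, strata = strata,
    subgroup_exposures = subgroup_exposures, thresholds = thresholds,
    zero_cell = zero_cell, ebgm_quantile = ebgm_quantile,
    serious_rule = serious_rule, outdir = outdir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; `thresholds` may
#' be a mapping of threshold names to values, `strata` the string
#' `"default"` or `"none"`.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("input", "catalog", "outdir", "zero_cell")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$window)) {
    args$window <- c(y$window$start %||% y$window[[1]],
                     y$window$end %||% y$window[[2]])
  }
  if (!is.null(y$drug_sets)) args$drug_sets <- lapply(y$drug_sets, unlist)
  if (!is.null(y$smqs)) args$smqs <- unlist(y$smqs)
  if (!is.null(y$strata)) {
    # args["strata"] <- list(NULL) keeps an explicit NULL element
    if (identical(y$strata, "none")) {
      args["strata"] <- list(NULL)
    } else if (identical(y$strata, "default")) {
      args$strata <- default_strata()
    } else {
      args$strata <- dplyr::bind_rows(lapply(y$strata, tibble::as_tibble))
    }
  }
  if (!is.null(y$thresholds)) {
    args$thresholds <- do.call(signal_thresholds, y$thresholds)
  }
  if (!is.null(y$subgroup_exposures)) {
    args$subgroup_exposures <- unlist(y$subgroup_exposures) %||% character()
  }
  if (!is.null(y$ebgm_quantile)) args$ebgm_quantile <- y$ebgm_quantile
  if (!is.null(y$serious_rule)) args$serious_rule <- unlist(y$serious_rule)
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(run_config, args)
}

write_tsv_rounded <- function(x, path, digits = 6) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, digits = digits)
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Execute an end-to-end analysis run
#'
#' Stages: read and quarantine, deduplicate, window-filter, descriptive
#' tables (drug shares, demographics, serious-outcome rates and their
#' comparison, yearly trend), the SMQ-by-exposure signal table, and the
#' sex-by-age subgroup table. Every stage logs record counts; all outputs
#' are written as TSV under `config$outdir` together with
#' `run_metadata.json`, which records every setting plus package and R
#' versions (sufficient to re-execute the identical run).
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a named list of the output tibbles plus `files`, the
#'   written paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  dc <- drug_catalog()
  smq_cat <- read_smq_catalog(config$catalog)

  raw <- read_ae_reports(config$input, catalog = dc)
  n_read <- nrow(raw)
  n_quarantined <- nrow(quarantined(raw))
  say("read: ", n_read, " report(s), ", n_quarantined, " quarantined")

  deduped <- deduplicate_reports(raw)
  say("deduplicate: ", nrow(raw), " -> ", nrow(deduped))

  reports <- filter_window(deduped, config$window[1], config$window[2])
  say("window ", config$window[1], "..", config$window[2], ": ",
      nrow(deduped), " -> ", nrow(reports))
  if (nrow(reports) == 0) abort("no reports left after cleaning")

  both_classes <- sum(vapply(reports$drugs, function(d) {
    ps <- unname(d[names(d) == "PS"])
    cls <- dc$classes$class[match(ps, dc$classes$drug)]
    all(c("GLP-1 RA", "DPP-4 inhibitor") %in% cls)
  }, logical(1)))
  if (both_classes > 0) {
    say("note: ", both_classes,
        " report(s) name both study classes as primary suspect")
  }

  smqs <- config$smqs %||% smq_cat$nodes$name
  events <- setNames(lapply(smqs, effective_terms, catalog = smq_cat), smqs)

  fit <- mgps_fit(mgps_cells(reports))
  say("mgps: prior fitted on ", fit$n_cells, " drug-term cells")

  signals <- signal_table(
    reports, exposures = config$drug_sets, events = events, fit = fit,
    thresholds = config$thresholds, zero_cell = config$zero_cell,
    ebgm_quantile = config$ebgm_quantile)
  say("signals: ", nrow(signals), " exposure-event rows, ",
      sum(signals$positive), " positive")

  shares <- purrr::imap_dfr(
    split(dc$classes$drug, dc$classes$class),
    function(drugs, cls) {
      cohort <- select_by_drug(reports, drugs)
      if (nrow(cohort) == 0) return(tibble::tibble())
      dplyr::mutate(drug_share(cohort, dc, class = cls), class = cls,
                    .before = 1)
    })

  demographics <- purrr::imap_dfr(
    split(dc$classes$drug, dc$classes$class),
    function(drugs, cls) {
      cohort <- select_by_drug(reports, drugs)
      if (nrow(cohort) == 0) return(tibble::tibble())
      dplyr::mutate(demographic_table(cohort), class = cls, .before = 1)
    })

  serious <- serious_rate(reports, rule = config$serious_rule, by = "drug")

  trend <- yearly_trend(reports, smq_cat)

  subgroups <- tibble::tibble()
  if (!is.null(config$strata)) {
    root_terms <- effective_terms(smq_cat, smq_root(smq_cat))
    subgroups <- purrr::map_dfr(config$subgroup_exposures, function(nm) {
      dplyr::mutate(
        subgroup_signals(reports, config$drug_sets[[nm]], root_terms,
                         strata = config$strata, fit = fit,
                         thresholds = config$thresholds,
                         zero_cell = config$zero_cell,
                         ebgm_quantile = config$ebgm_quantile),
        exposure = nm, .before = 1)
    })
  }

  cleaned_summary <- tibble::tibble(
    stage = c("read", "quarantined", "deduplicated", "in_window"),
    n = c(n_read, n_quarantined, nrow(deduped), nrow(reports))
  )

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    cleaned_summary = cleaned_summary, signal_table = signals,
    subgroup_table = subgroups, drug_share = shares,
    demographics = demographics, serious_rates = serious, trend = trend
  )
  files <- character()
  for (nm in names(out)) {
    if (nrow(out[[nm]]) == 0) next
    files[nm] <- write_tsv_rounded(out[[nm]],
                                   file.path(config$outdir, nm %p% ".tsv"))
  }
  if (n_quarantined > 0) {
    qpath <- file.path(config$outdir, "quarantine.tsv")
    readr::write_tsv(quarantined(raw), qpath, progress = FALSE)
    files["quarantine"] <- qpath
  }
  meta <- list(
    package = "aesignal",
    package_version = as.character(utils::packageVersion("aesignal")),
    r_version = R.version.string,
    settings = list(
      input = config$input, catalog = config$catalog,
      drug_sets = config$drug_sets, smqs = smqs, window = config$window,
      thresholds = unclass(config$thresholds),
      zero_cell = config$zero_cell, ebgm_quantile = config$ebgm_quantile,
      serious_rule = config$serious_rule, seed = config$seed,
      smq_scope = "all"
    ),
    counts = as.list(setNames(cleaned_summary$n, cleaned_summary$stage)),
    mgps = list(shape1 = fit$shape1, rate1 = fit$rate1, shape2 = fit$shape2,
                rate2 = fit$rate2, w = fit$w, loglik = fit$loglik)
  )
  meta_path <- file.path(config$outdir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files["run_metadata"] <- meta_path
  say("run complete in ",
      sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out$files <- files
  invisible(out)
}

#' Simulate a dataset and write it in the pipeline's input format
#'
#' Convenience wrapper: [simulate_reports()] followed by
#' [write_synthetic_dataset()]; the written `reports.csv` is directly
#' consumable by [run_pipeline()].
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(config, dir) {
  sim <- simulate_reports(config)
  write_synthetic_dataset(sim, dir, config = config)
}
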