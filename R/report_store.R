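#' Construct a spontaneous-report collection
#'
#' A report collection is an ordinary tibble with one row per report entry and
#' the columns below; every downstream function in the package consumes and
#' returns this shape, so collections compose with dplyr verbs and the pipe.
#'
#' * `primary_id` (character) — per-entry identifier, unique in a cleaned
#'   collection (the FAERS `primaryid` analogue);
#' * `case_id` (character) — case identifier shared by successive versions of
#'   the same case;
#' * `fda_date` (Date) — date the report was accepted by the FDA (`FDA_DT`);
#' * `drugs` (list of named character) — drug names with the role code
#'   (`PS`, `SS`, `C`, `I`) as the element name;
#' * `reactions` (list of character) — MedDRA preferred terms, non-empty;
#' * `sex` — one of `male`, `female`, `not_specified`, `unknown`;
#' * `age_years` (numeric) — age in years, `NA` when unknown;
#' * `country` (character) — ISO-3166 alpha-2 code, `NA` when unknown;
#' * `outcomes` (list of character) — subset of `DE`, `LT`, `HO`, `DS`,
#'   `CA`, `RI`, `OT` (possibly empty).
#'
#' @param primary_id,case_id Character vectors.
#' @param fda_date Date vector (or strings in `%Y-%m-%d`).
#' @param drugs List of named character vectors (names are role codes).
#' @param reactions List of character vectors of preferred terms.
#' @param sex Character vector.
#' @param age_years Numeric vector, `NA` for unknown.
#' @param country Character vector, `NA` for unknown.
#' @param outcomes List of character vectors of outcome codes.
#' @return A tibble in the report-collection shape, validated.
#' @examples
#' ae_reports(
#'   primary_id = "1001", case_id = "C1", fda_date = "2020-05-01",
#'   drugs = list(c(PS = "semaglutide")), reactions = list("cholelithiasis"),
#'   sex = "female", age_years = 58, country = "US", outcomes = list("HO")
#' )
#' @export
ae_reports <- function(primary_id, case_id, fda_date, drugs, reactions,
                       sex = "unknown", age_years = NA_real_,
                       country = NA_character_, outcomes = list(character())) {
  out <- tibble::tibble(
    primary_id = as.character(primary_id),
    case_id = as.character(case_id),
    fda_date = as.Date(fda_date),
    drugs = drugs,
    reactions = reactions,
    sex = sex,
    age_years = as.numeric(age_years),
    country = as.character(country),
    outcomes = outcomes
  )
  validate_ae_reports(out)
}

#' Validate a report collection
#'
#' Checks the column contract of [ae_reports()]: required columns and types,
#' role and outcome codes, sex levels, age range and non-empty reaction sets.
#'
#' @param reports A report-collection tibble.
#' @return `reports`, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_ae_reports <- function(reports) {
  required <- c("primary_id", "case_id", "fda_date", "drugs", "reactions",
                "sex", "age_years", "country", "outcomes")
  missing <- setdiff(required, names(reports))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(reports) == 0) return(reports)
  if (anyNA(reports$primary_id) || any(!nzchar(reports$primary_id))) {
    abort("primary_id must be non-empty")
  }
  if (!inherits(reports$fda_date, "Date")) {
    abort("fda_date must be a Date column")
  }
  roles <- unique(unlist(lapply(reports$drugs, names)))
  if (length(roles) > 0 && !all(roles %in% .ROLE_CODES)) {
    abort(paste0("invalid drug role code(s): ",
                 paste(setdiff(roles, .ROLE_CODES), collapse = ", ")))
  }
  if (!all(reports$sex %in% .SEX_LEVELS)) {
    abort("sex must be one of male, female, not_specified, unknown")
  }
  known_age <- reports$age_years[!is.na(reports$age_years)]
  if (any(known_age < 0 | known_age > 130)) {
    abort("age_years must lie in [0, 130] when known")
  }
  if (any(lengths(reports$reactions) == 0)) {
    abort("every report must carry at least one reaction term")
  }
  bad_out <- setdiff(unique(unlist(reports$outcomes)), .OUTCOME_CODES)
  if (length(bad_out) > 0) {
    abort(paste0("invalid outcome code(s): ", paste(bad_out, collapse = ", ")))
  }
  reports
}

# ---- CSV dialect ------------------------------------------------------------
# One row per report entry; multi-value fields are semicolon-delimited, drug
# entries are "name:ROLE" pairs. UTF-8, header row mandatory.

.dialect_cols <- c("primary_id", "case_id", "fda_date", "drugs", "reactions",
                   "sex", "age_years", "country", "outcomes")

split_multi <- function(x) {
  x[is.na(x)] <- ""
  out <- strsplit(x, .FIELD_SEP, fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Read a spontaneous-report extract
#'
#' Parses the package's CSV dialect (one row per report entry, header row,
#' semicolon-delimited multi-value fields, drug entries as `name:ROLE` pairs).
#' Drug names are passed through [normalize_drug()] against `catalog`.
#' Malformed rows are quarantined with a reason, never silently dropped: the
#' returned collection carries the quarantined rows as an attribute,
#' retrievable with [quarantined()].
#'
#' @param path Path to a CSV file in the documented dialect.
#' @param catalog A [drug_catalog()] used for synonym normalisation.
#' @return A validated report-collection tibble; attribute `quarantine` holds
#'   a tibble of rejected raw rows with a `reason` column.
#' @export
read_ae_reports <- function(path, catalog = drug_catalog()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(.dialect_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }

  dates <- as.Date(raw$fda_date, format = "%Y-%m-%d", optional = TRUE)
  # reject dates that "parse" by wrapping (e.g. month 13) or fail outright
  ok_date <- !is.na(dates) &
    format(dates, "%Y-%m-%d") == sprintf("%s", raw$fda_date)
  flag(!ok_date, "unparseable fda_date")

  age <- suppressWarnings(as.numeric(raw$age_years))
  bad_age <- !is.na(raw$age_years) & nzchar(raw$age_years) &
    (is.na(age) | age < 0 | age > 130)
  flag(bad_age, "age outside [0, 130]")

  drug_entries <- split_multi(raw$drugs)
  parsed_drugs <- lapply(drug_entries, function(v) {
    parts <- strsplit(v, .ROLE_SEP, fixed = TRUE)
    nm <- vapply(parts, function(p) p[1], character(1))
    role <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                   character(1))
    setNames(nm, role)
  })
  bad_role <- vapply(parsed_drugs, function(d) {
    length(d) > 0 && !all(names(d) %in% .ROLE_CODES)
  }, logical(1))
  flag(bad_role, "invalid drug role code")

  reactions <- split_multi(raw$reactions)
  reactions <- lapply(reactions, function(r) tolower(r))
  flag(lengths(reactions) == 0, "no reaction terms")

  flag(is.na(raw$primary_id) | !nzchar(raw$primary_id), "empty primary_id")
  flag(duplicated(raw$primary_id), "duplicate primary_id")

  outcomes <- split_multi(raw$outcomes)
  bad_outcome <- vapply(outcomes, function(o) !all(o %in% .OUTCOME_CODES),
                        logical(1))
  flag(bad_outcome, "invalid outcome code")

  sex <- tolower(trimws(raw$sex))
  sex[sex %in% c("m")] <- "male"
  sex[sex %in% c("f")] <- "female"
  sex[sex %in% c("ns", "not specified")] <- "not_specified"
  sex[is.na(sex) | !nzchar(sex)] <- "unknown"
  flag(!(sex %in% .SEX_LEVELS), "invalid sex")

  keep <- is.na(reason)
  quarantine <- dplyr::mutate(raw[!keep, , drop = FALSE],
                              reason = reason[!keep])
  if (nrow(quarantine) > 0) {
    message(nrow(quarantine), " row(s) quarantined (",
            paste(unique(quarantine$reason), collapse = "; "), ")")
  }

  country <- toupper(trimws(raw$country))
  country[is.na(country) | !nzchar(country) | country == "UNKNOWN"] <-
    NA_character_

  out <- tibble::tibble(
    primary_id = raw$primary_id[keep],
    case_id = raw$case_id[keep],
    fda_date = dates[keep],
    drugs = lapply(parsed_drugs[keep], function(d) {
      setNames(normalize_drug(unname(d), catalog), names(d))
    }),
    reactions = reactions[keep],
    sex = sex[keep],
    age_years = age[keep],
    country = country[keep],
    outcomes = outcomes[keep]
  )
  out <- validate_ae_reports(out)
  attr(out, "quarantine") <- quarantine
  out
}

#' Quarantined rows from the last read
#'
#' @param reports A collection returned by [read_ae_reports()].
#' @return Tibble of raw rejected rows with a `reason` column (empty tibble
#'   if nothing was quarantined).
#' @export
quarantined <- function(reports) {
  attr(reports, "quarantine") %||%
    tibble::tibble(reason = character())
}

#' Write a report collection in the package dialect
#'
#' Inverse of [read_ae_reports()]: `read_ae_reports(write_ae_reports(x, f))`
#' reproduces `x` field for field.
#'
#' @param reports A report-collection tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ae_reports <- function(reports, path) {
  validate_ae_reports(reports)
  join <- function(x) vapply(x, paste, character(1), collapse = .FIELD_SEP)
  flat <- tibble::tibble(
    primary_id = reports$primary_id,
    case_id = reports$case_id,
    fda_date = format(reports$fda_date, "%Y-%m-%d"),
    drugs = vapply(reports$drugs, function(d) {
      paste(unname(d), names(d), sep = .ROLE_SEP, collapse = .FIELD_SEP)
    }, character(1)),
    reactions = join(reports$reactions),
    sex = reports$sex,
    age_years = reports$age_years,
    country = reports$country,
    outcomes = join(reports$outcomes)
  )
  readr::write_csv(flat, path, na = "", progress = FALSE)
  invisible(path)
}

# ---- cleaning ---------------------------------------------------------------

# Ranking key for the primary-identifier tie-break: numeric when every id is
# an all-digit string, lexicographic otherwise.
pid_rank <- function(ids) {
  if (all(grepl("^[0-9]+$", ids))) as.numeric(ids) else xtfrm(ids)
}

#' Deduplicate report entries that are versions of one case
#'
#' FAERS cases are re-submitted as follow-ups sharing the case identifier.
#' Among entries with the same `case_id` the entry with the most recent FDA
#' acceptance date is kept; ties on the date are broken by the higher
#' per-entry identifier (compared numerically when all identifiers are
#' all-digit strings, lexicographically otherwise). The operation is
#' idempotent and keeps exactly one entry per distinct `case_id`; output rows
#' are ordered by `case_id` for determinism.
#'
#' @param reports A report-collection tibble.
#' @return Deduplicated collection, one row per `case_id`.
#' @examples
#' r <- ae_reports(
#'   primary_id = c("100", "200"), case_id = c("C1", "C1"),
#'   fda_date = c("2020-01-01", "2021-06-01"),
#'   drugs = list(c(PS = "sitagliptin"), c(PS = "sitagliptin")),
#'   reactions = list("cholelithiasis", "cholelithiasis")
#' )
#' deduplicate_reports(r)$primary_id # "200"
#' @export
deduplicate_reports <- function(reports) {
  validate_ae_reports(reports)
  if (nrow(reports) == 0) return(reports)
  ord <- order(reports$case_id, as.numeric(reports$fda_date),
               pid_rank(reports$primary_id), decreasing = FALSE)
  # within each case the last row in `ord` is the keeper; walk from the back
  back <- rev(ord)
  keep <- back[!duplicated(reports$case_id[back])]
  out <- reports[sort(keep), , drop = FALSE]
  out[order(out$case_id), , drop = FALSE]
}

# ---- window filtering -------------------------------------------------------

parse_quarter <- function(q) {
  m <- regmatches(q, regexec("^([0-9]{4})-?Q([1-4])$", toupper(trimws(q))))[[1]]
  if (length(m) != 3) {
    abort(paste0("invalid quarter spec (expected 'YYYYQn'): ", q))
  }
  list(year = as.integer(m[2]), quarter = as.integer(m[3]))
}

quarter_bounds <- function(q) {
  p <- parse_quarter(q)
  first_month <- (p$quarter - 1) * 3 + 1
  start <- as.Date(sprintf("%04d-%02d-01", p$year, first_month))
  nxt <- if (p$quarter == 4) {
    as.Date(sprintf("%04d-01-01", p$year + 1))
  } else {
    as.Date(sprintf("%04d-%02d-01", p$year, first_month + 3))
  }
  list(start = start, end = nxt - 1)
}

#' Restrict reports to a closed range of calendar quarters
#'
#' Keeps reports whose FDA acceptance date falls inside `[start, end]`,
#' boundaries included (the study window is `"2013Q1"` to `"2024Q1"`).
#'
#' @param reports A report-collection tibble.
#' @param start,end Quarter specs, `"YYYYQn"`.
#' @return Filtered collection.
#' @export
filter_window <- function(reports, start = "2013Q1", end = "2024Q1") {
  lo <- quarter_bounds(start)$start
  hi <- quarter_bounds(end)$end
  if (lo > hi) abort("window start must not be after window end")
  dplyr::filter(reports, .data$fda_date >= lo, .data$fda_date <= hi)
}

#' Select reports naming a drug of interest in a given role
#'
#' Keeps reports having at least one drug entry whose canonical name is in
#' `drugs` with the requested role code (default `"PS"`, primary suspect,
#' matching how the exposure cohorts are defined).
#'
#' @param reports A report-collection tibble.
#' @param drugs Non-empty character vector of canonical drug names.
#' @param role Single role code; one of `PS`, `SS`, `C`, `I`.
#' @return Filtered collection.
#' @export
select_by_drug <- function(reports, drugs, role = "PS") {
  if (length(drugs) == 0) abort("drug set must be non-empty")
  stopifnot(role %in% .ROLE_CODES)
  hit <- vapply(reports$drugs, function(d) {
    any(unname(d) %in% drugs & names(d) == role)
  }, logical(1))
  reports[hit, , drop = FALSE]
}

# Internal: one primary-suspect drug per report (first PS entry, NA if none).
# The generator emits exactly one PS drug per report; on real extracts with
# several PS entries the first is used for per-drug tallies.
ps_drug <- function(reports) {
  vapply(reports$drugs, function(d) {
    i <- which(names(d) == "PS")
    if (length(i) == 0) NA_character_ else unname(d[i[1]])
  }, character(1))
}
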