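#' Built-in catalog of incretin-based antidiabetic drugs
#'
#' The study cohorts are the GLP-1 receptor agonists (exenatide, liraglutide,
#' dulaglutide, lixisenatide, semaglutide, tirzepatide) and the DPP-4
#' inhibitors (linagliptin, alogliptin, saxagliptin, sitagliptin). The catalog
#' maps each canonical generic name to its class and carries a brand/raw-name
#' synonym table so that verbatim drug strings in report extracts can be
#' normalised before any counting.
#'
#' @param extra_synonyms Optional tibble with columns `synonym` and `drug`
#'   appended to the built-in synonym table.
#'
#' @return An object of class `drug_catalog`: a list with
#'   * `classes`: tibble with columns `drug`, `class`;
#'   * `synonyms`: tibble with columns `synonym`, `drug` (synonyms stored
#'     lower-case; lookup is case-insensitive).
#' @examples
#' cat <- drug_catalog()
#' normalize_drug(c("Januvia", "OZEMPIC", "metformin"), cat)
#' @export
drug_catalog <- function(extra_synonyms = NULL) {
  classes <- tibble::tibble(
    drug = c(
      "exenatide", "liraglutide", "dulaglutide", "lixisenatide",
      "semaglutide", "tirzepatide",
      "linagliptin", "alogliptin", "saxagliptin", "sitagliptin"
    ),
    class = c(rep("GLP-1 RA", 6), rep("DPP-4 inhibitor", 4))
  )
  synonyms <- tibble::tribble(
    ~synonym,     ~drug,
    "byetta",     "exenatide",
    "bydureon",   "exenatide",
    "victoza",    "liraglutide",
    "saxenda",    "liraglutide",
    "trulicity",  "dulaglutide",
    "adlyxin",    "lixisenatide",
    "lyxumia",    "lixisenatide",
    "ozempic",    "semaglutide",
    "rybelsus",   "semaglutide",
    "wegovy",     "semaglutide",
    "mounjaro",   "tirzepatide",
    "zepbound",   "tirzepatide",
    "tradjenta",  "linagliptin",
    "trajenta",   "linagliptin",
    "nesina",     "alogliptin",
    "vipidia",    "alogliptin",
    "onglyza",    "saxagliptin",
    "januvia",    "sitagliptin"
  )
  # canonical names resolve to themselves
  synonyms <- dplyr::bind_rows(
    synonyms,
    tibble::tibble(synonym = classes$drug, drug = classes$drug)
  )
  if (!is.null(extra_synonyms)) {
    stopifnot(all(c("synonym", "drug") %in% names(extra_synonyms)))
    synonyms <- dplyr::bind_rows(
      synonyms,
      dplyr::mutate(extra_synonyms, synonym = tolower(.data$synonym))
    )
  }
  if (anyDuplicated(classes$drug) > 0) {
    abort("each canonical drug must belong to exactly one class")
  }
  structure(list(classes = classes, synonyms = synonyms),
            class = "drug_catalog")
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("<drug_catalog> ", nrow(x$classes), " drugs in ",
      dplyr::n_distinct(x$classes$class), " classes, ",
      nrow(x$synonyms), " synonyms\n", sep = "")
  invisible(x)
}

#' Normalise verbatim drug names to canonical generic names
#'
#' Lookup is case-insensitive and total: any string not found in the synonym
#' table maps to `"other"`, so background (non-study) drugs never fail a
#' pipeline run.
#'
#' @param x Character vector of verbatim drug names.
#' @param catalog A [drug_catalog()].
#' @return Character vector of canonical names (or `"other"`).
#' @export
normalize_drug <- function(x, catalog = drug_catalog()) {
  idx <- match(tolower(trimws(x)), catalog$synonyms$synonym)
  out <- catalog$synonyms$drug[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Canonical drug names belonging to one class
#'
#' @param catalog A [drug_catalog()].
#' @param class Class label, e.g. `"GLP-1 RA"` or `"DPP-4 inhibitor"`.
#' @return Character vector of canonical names.
#' @export
class_drugs <- function(catalog = drug_catalog(), class) {
  drugs <- catalog$classes$drug[catalog$classes$class == class]
  if (length(drugs) == 0) {
    abort(paste0("unknown drug class: ", class))
  }
  drugs
}
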