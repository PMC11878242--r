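#' Build a hierarchical SMQ catalog
#'
#' A standardized MedDRA query (SMQ) groups preferred terms (PTs) describing
#' one medical condition area; SMQs may nest, and a parent's effective term
#' set is the union of its own terms and all descendants' terms. The catalog
#' used in the biliary-disorder analysis is a depth-2 tree: a root
#' (`"biliary disorders"`) with nine sub-SMQs (malignant tumours, benign
#' neoplasms, investigations/signs/symptoms, tract disorders, tumours of
#' unspecified malignancy, congenital disorders, gallbladder related,
#' gallstone related, infectious).
#'
#' Real MedDRA term lists are licensed and cannot ship with the package; a
#' synthetic fixture with the study topology is bundled (see
#' [example_smq_path()]) and the same file format accepts user-supplied real
#' lists.
#'
#' @param nodes Tibble with columns `name`, `parent` (`NA` for the root).
#' @param terms Tibble with columns `smq`, `term`, and optionally `scope`
#'   (`"narrow"` or `"broad"`; defaults to `"narrow"`). Terms are normalised
#'   by case-folding and trimming; matching is exact string equality.
#' @return An object of class `smq_catalog`.
#' @export
smq_catalog <- function(nodes, terms) {
  stopifnot(all(c("name", "parent") %in% names(nodes)),
            all(c("smq", "term") %in% names(terms)))
  nodes <- tibble::as_tibble(nodes)
  terms <- tibble::as_tibble(terms)
  if (!"scope" %in% names(terms)) terms$scope <- "narrow"
  terms$scope[is.na(terms$scope) | !nzchar(terms$scope)] <- "narrow"
  if (!all(terms$scope %in% c("narrow", "broad"))) {
    abort("term scope must be 'narrow' or 'broad'")
  }
  terms$term <- tolower(trimws(terms$term))
  terms$smq <- trimws(terms$smq)
  nodes$name <- trimws(nodes$name)

  if (anyDuplicated(nodes$name) > 0) abort("duplicate SMQ node names")
  self_parent <- nodes$name[!is.na(nodes$parent) & nodes$parent == nodes$name]
  if (length(self_parent) > 0) {
    abort(paste0("cycle: node is its own parent: ",
                 paste(self_parent, collapse = ", ")))
  }
  roots <- nodes$name[is.na(nodes$parent) | !nzchar(nodes$parent)]
  if (length(roots) != 1) {
    abort("catalog must have exactly one root SMQ")
  }
  unknown_parent <- setdiff(stats::na.omit(nodes$parent), c(nodes$name, ""))
  if (length(unknown_parent) > 0) {
    abort(paste0("unknown parent for node(s): ",
                 paste(nodes$name[nodes$parent %in% unknown_parent],
                       collapse = ", ")))
  }
  orphan_terms <- setdiff(unique(terms$smq), nodes$name)
  if (length(orphan_terms) > 0) {
    abort(paste0("terms reference unknown SMQ(s): ",
                 paste(orphan_terms, collapse = ", ")))
  }
  # cycle detection: walk each node to the root
  parent_of <- setNames(nodes$parent, nodes$name)
  for (nm in nodes$name) {
    seen <- character()
    cur <- nm
    while (!is.na(parent_of[[cur]]) && nzchar(parent_of[[cur]])) {
      if (cur %in% seen) {
        abort(paste0("cycle in SMQ hierarchy involving: ",
                     paste(seen, collapse = " -> ")))
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  structure(list(nodes = nodes, terms = terms), class = "smq_catalog")
}

#' @export
print.smq_catalog <- function(x, ...) {
  cat("<smq_catalog> ", nrow(x$nodes), " SMQs (root: ",
      smq_root(x), "), ", nrow(x$terms), " term entries\n", sep = "")
  invisible(x)
}

#' Read an SMQ catalog file
#'
#' The file is a plain CSV with one row per (SMQ, term) pair: columns `name`,
#' `parent` (empty for the root), `term` (may be empty for internal nodes
#' whose membership comes entirely from descendants) and optional `scope`
#' (`narrow`/`broad`).
#'
#' @param path Catalog CSV path.
#' @return An `smq_catalog` object.
#' @export
read_smq_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("name", "parent", "term")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  nodes <- dplyr::distinct(raw, name = .data$name, parent = .data$parent)
  if (anyDuplicated(nodes$name) > 0) {
    abort("a node is listed with two different parents")
  }
  has_term <- !is.na(raw$term) & nzchar(trimws(raw$term))
  terms <- tibble::tibble(
    smq = raw$name[has_term],
    term = raw$term[has_term],
    scope = if ("scope" %in% names(raw)) raw$scope[has_term] else "narrow"
  )
  smq_catalog(nodes, terms)
}

#' Path to the bundled synthetic biliary SMQ catalog
#'
#' A stand-in catalog with the study's depth-2 biliary topology (one root,
#' nine sub-SMQs) and invented preferred-term lists; it is *not* a MedDRA
#' extract and carries `synthetic` in its filename to say so.
#'
#' @return File path inside the installed package.
#' @export
example_smq_path <- function() {
  system.file("extdata", "smq_biliary_synthetic.csv", package = "aesignal",
              mustWork = TRUE)
}

smq_root <- function(catalog) {
  catalog$nodes$name[is.na(catalog$nodes$parent) |
                       !nzchar(catalog$nodes$parent)]
}

smq_children <- function(catalog, smq_name) {
  catalog$nodes$name[!is.na(catalog$nodes$parent) &
                       catalog$nodes$parent == smq_name]
}

#' Effective preferred-term set of an SMQ node
#'
#' Union of the node's own terms and all descendants' terms; a superset of
#' each child's effective set by construction.
#'
#' @param catalog An `smq_catalog`.
#' @param smq_name SMQ title.
#' @param scope `"all"` (default), `"narrow"` or `"broad"`: which scope tags
#'   to include. The scope the source analysis used is not recorded in its
#'   methods, so the default includes every term.
#' @return Character vector of normalised preferred terms.
#' @export
effective_terms <- function(catalog, smq_name, scope = "all") {
  if (!smq_name %in% catalog$nodes$name) {
    abort(paste0("unknown SMQ: ", smq_name))
  }
  members <- smq_name
  frontier <- smq_name
  while (length(frontier) > 0) {
    kids <- unlist(lapply(frontier, smq_children, catalog = catalog))
    kids <- setdiff(kids, members)
    members <- c(members, kids)
    frontier <- kids
  }
  t <- catalog$terms[catalog$terms$smq %in% members, , drop = FALSE]
  if (scope != "all") t <- t[t$scope == scope, , drop = FALSE]
  sort(unique(t$term))
}

#' Does each report match an SMQ?
#'
#' A report matches when its reaction set intersects the SMQ's effective term
#' set; it matches at most once per SMQ however many of its reactions fall in
#' the set, and a match on a child implies a match on every ancestor.
#'
#' @param reports A report-collection tibble.
#' @param catalog An `smq_catalog`.
#' @param smq_name SMQ title (default: the catalog root).
#' @param scope Passed to [effective_terms()].
#' @return Logical vector, one element per report.
#' @export
report_matches_smq <- function(reports, catalog, smq_name = smq_root(catalog),
                               scope = "all") {
  terms <- effective_terms(catalog, smq_name, scope)
  vapply(reports$reactions, function(r) any(tolower(r) %in% terms), logical(1))
}
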