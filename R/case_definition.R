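#' Define a reaction-term case definition
#'
#' A case definition is a named set of MedDRA-style preferred terms; a report
#' is a case when at least one of its reaction terms matches one of these,
#' case- and whitespace-insensitively. Matching is flat string equality after
#' [normalize_term()]: no term-hierarchy traversal is attempted, since the
#' licensed dictionary is not available and published case definitions name
#' preferred terms directly.
#'
#' @param terms Character vector of preferred terms (nonempty).
#' @param name Label for the definition.
#' @return An object of class `case_definition`.
#' @export
case_definition <- function(terms, name = "custom") {
  terms <- unique(normalize_term(as.character(terms)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) {
    stop("a case definition needs at least one term", call. = FALSE)
  }
  structure(list(name = name, terms = sort(terms)), class = "case_definition")
}

#' @export
print.case_definition <- function(x, ...) {
  cat("<case_definition> ", x$name, ": ", length(x$terms), " term(s)\n", sep = "")
  cat(paste(" -", x$terms, collapse = "\n"), "\n")
  invisible(x)
}

#' The default acute kidney disease case definition
#'
#' Ten preferred terms covering the AKD phenotype as reported to
#' pharmacovigilance systems: acute kidney injury, renal failure, renal
#' impairment, blood creatinine increased, renal injury, blood urea increased,
#' tubulointerstitial nephritis, glomerular filtration rate decreased,
#' oliguria and anuria. Co-reported terms (dehydration, hypotension, ...) are
#' descriptive context, not part of the definition.
#'
#' @return A [case_definition()] named `"AKD"`.
#' @export
akd_case_definition <- function() {
  path <- system.file("extdata", "akd_case_terms.txt", package = "akdsignal",
                      mustWork = TRUE)
  read_case_definition(path, name = "AKD")
}

#' Read a case definition from a plain-text file
#'
#' One preferred term per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @param name Label for the definition (default: file name without extension).
#' @return A [case_definition()].
#' @export
read_case_definition <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  case_definition(lines, name = name)
}

#' Is a report a case under a case definition?
#'
#' @param x A character vector of reaction terms (returns a single logical),
#'   or a [report_set()] (returns one logical per record).
#' @param cd A [case_definition()].
#' @return Logical.
#' @export
is_case <- function(x, cd) {
  stopifnot(inherits(cd, "case_definition"))
  if (inherits(x, "report_set")) {
    vapply(x$records$reactions,
           function(r) any(normalize_term(r) %in% cd$terms), logical(1))
  } else if (is.character(x)) {
    any(normalize_term(x) %in% cd$terms)
  } else {
    stop("`x` must be a report_set or a character vector of reactions",
         call. = FALSE)
  }
}

#' Partition a report set into cases and non-cases
#'
#' @param rs A [report_set()] (deduplicate first for report-level counting).
#' @param cd A [case_definition()].
#' @return A list with `report_set` elements `cases` and `noncases`; the two
#'   are disjoint and their union is `rs`.
#' @export
split_cases <- function(rs, cd) {
  stopifnot(inherits(rs, "report_set"))
  flag <- is_case(rs, cd)
  list(
    cases = report_set(rs$records[flag, ],
                       provenance = paste0(rs$provenance, " [cases:", cd$name, "]"),
                       deduplicated = rs$deduplicated, n_removed = rs$n_removed),
    noncases = report_set(rs$records[!flag, ],
                          provenance = paste0(rs$provenance, " [noncases:", cd$name, "]"),
                          deduplicated = rs$deduplicated, n_removed = rs$n_removed)
  )
}
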