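#' Bibliographic nephrotoxicity score categories
#'
#' The bibliographic score (BS) counts, for one drug, in how many of five
#' predetermined literature sources (two databases, one website, two
#' reference books) nephrotoxicity evidence is found: an integer from 0
#' (no evidence anywhere) to 5 (evidence in every source). Drugs are then
#' classed as `non_nephrotoxic` (BS 0), `potentially_nephrotoxic` (BS 1-2)
#' or `nephrotoxic` (BS >= 3).
#'
#' @param score Integer vector of scores in 0..5.
#' @return Factor with levels `non_nephrotoxic`, `potentially_nephrotoxic`,
#'   `nephrotoxic`.
#' @export
bs_category <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 5) ||
      any(score != round(score))) {
    stop("bibliographic scores must be integers in 0..5", call. = FALSE)
  }
  cut(score, breaks = c(-0.5, 0.5, 2.5, 5.5),
      labels = c("non_nephrotoxic", "potentially_nephrotoxic", "nephrotoxic"))
}

#' Score per-source nephrotoxicity evidence
#'
#' @param ingredient Character vector of drug labels (normalized internally).
#' @param sources A logical matrix or data frame with one row per drug and
#'   exactly five columns: evidence present/absent in each of the five
#'   predetermined bibliographic sources.
#' @return A tibble with columns `ingredient`, `score` (0-5 row sums) and
#'   `category` (see [bs_category()]).
#' @export
score_evidence <- function(ingredient, sources) {
  sources <- as.matrix(as.data.frame(sources))
  if (ncol(sources) != 5L) {
    stop("exactly five evidence indicators are required per drug", call. = FALSE)
  }
  if (!is.logical(sources)) {
    if (!all(sources %in% c(0, 1, NA))) {
      stop("evidence indicators must be logical (or 0/1)", call. = FALSE)
    }
    sources <- sources == 1
  }
  if (any(is.na(sources))) {
    stop("evidence indicators must not be missing", call. = FALSE)
  }
  if (nrow(sources) != length(ingredient)) {
    stop("one row of indicators per ingredient is required", call. = FALSE)
  }
  score <- as.integer(rowSums(sources))
  tibble::tibble(ingredient = normalize_ingredient(ingredient),
                 score = score, category = bs_category(score))
}

#' Nephrotoxicity class proportions
#'
#' Shares of the three bibliographic-score classes over a collection of
#' scored drugs, as one-decimal percentages of the collection size
#' (half-away-from-zero rounding, see [pct()]). All three classes appear in
#' the output even when empty.
#'
#' @param scores An integer vector of scores 0-5, or a data frame with a
#'   `score` or `bs` column (e.g. from [score_evidence()],
#'   [read_biblio_scores()] or [akd_reference_signals()]).
#' @return A tibble with columns `category`, `count`, `pct`.
#' @export
class_proportions <- function(scores) {
  if (is.data.frame(scores)) {
    scores <- if ("score" %in% names(scores)) scores$score else scores$bs
  }
  if (length(scores) == 0L) {
    stop("cannot compute class proportions of an empty collection", call. = FALSE)
  }
  cat <- bs_category(scores)
  counts <- table(cat)
  tibble::tibble(category = names(counts),
                 count = as.integer(counts),
                 pct = pct(as.integer(counts), length(scores)))
}

#' Read bibliographic scores from a delimited file
#'
#' Accepts either an `ingredient` column plus five indicator columns (any
#' names; values logical or 0/1), or an `ingredient` column plus a
#' precomputed integer `score` column.
#'
#' @param path Comma- or tab-delimited file with a header.
#' @param delim Delimiter; `NULL` auto-detects comma vs tab.
#' @return A tibble with `ingredient`, `score`, `category`.
#' @export
read_biblio_scores <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (length(first) > 0L && grepl("\t", first[1])) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"ingredient" %in% names(raw)) {
    stop("schema error: `ingredient` column is required", call. = FALSE)
  }
  if ("score" %in% names(raw)) {
    score <- as.integer(raw$score)
    return(tibble::tibble(ingredient = normalize_ingredient(raw$ingredient),
                          score = score, category = bs_category(score)))
  }
  ind <- raw[, setdiff(names(raw), "ingredient"), drop = FALSE]
  if (ncol(ind) != 5L) {
    stop("schema error: expected a `score` column or exactly five indicator columns",
         call. = FALSE)
  }
  score_evidence(raw$ingredient, ind)
}

#' Published reference signals for drug-associated acute kidney disease
#'
#' The 24 most notable drugs from a published worldwide pharmacovigilance
#' analysis of acute kidney disease, with their first-level ATC class, number
#' of reports, leading reported phenotype, disproportionality statistics
#' (IC025 and ROR against the full background database, which is proprietary
#' and not reproducible here) and bibliographic nephrotoxicity score. Shipped
#' as reference data for score classification and output formatting.
#'
#' @return A tibble with columns `ingredient`, `atc_class`, `n_reports`,
#'   `phenotype`, `ic025`, `ror`, `bs`.
#' @export
akd_reference_signals <- function() {
  path <- system.file("extdata", "akd_reference_signals.tsv",
                      package = "akdsignal", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
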