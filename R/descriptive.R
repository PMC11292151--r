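#' One-decimal percentage with half-away-from-zero rounding
#'
#' Publication-style percentages: `100 * count / denom` rounded half away
#' from zero (so 6.25 prints as 6.3, not base R's round-half-even 6.2).
#'
#' @param count Nonnegative count(s), at most `denom`.
#' @param denom Positive denominator.
#' @param digits Decimal places (default 1; use 0 where a table prints whole
#'   percentages, 3 for database-share figures).
#' @return Numeric vector of percentages.
#' @examples
#' pct(155606, 435677)  # 35.7
#' pct(29919, 435677)   # 6.9
#' @export
pct <- function(count, denom, digits = 1) {
  if (length(denom) != 1L || is.na(denom) || denom <= 0) {
    stop("denominator must be a single positive number", call. = FALSE)
  }
  if (any(is.na(count)) || any(count < 0) || any(count > denom)) {
    stop("counts must lie in [0, denom]", call. = FALSE)
  }
  round_half_away(100 * count / denom, digits)
}

#' Round half away from zero
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny absolute nudge so that values intended to be exact halves, but
  # stored a hair below due to binary floating point, still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

freq_table <- function(label, count, denominator, denominator_kind, digits = 1) {
  out <- tibble::tibble(label = as.character(label),
                        count = as.integer(count),
                        pct = if (length(count) > 0L && denominator > 0L)
                          pct(count, denominator, digits) else numeric(length(count)))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$label)
  attr(out, "denominator") <- as.integer(denominator)
  attr(out, "denominator_kind") <- denominator_kind
  out
}

count_labels <- function(label_sets, universe = NULL) {
  labels <- unlist(label_sets, use.names = FALSE)
  counts <- table(labels)
  if (!is.null(universe)) {
    full <- stats::setNames(integer(length(universe)), universe)
    full[names(counts)[names(counts) %in% universe]] <-
      as.integer(counts[names(counts) %in% universe])
    full
  } else {
    stats::setNames(as.integer(counts), names(counts))
  }
}

#' Frequencies of main and co-reported reaction terms
#'
#' Over a case report set: the main table counts, per case-definition term,
#' the reports whose reactions include it; the concomitant table does the
#' same for every reaction term outside the definition. A report contributes
#' to every term it mentions, so percentages can sum above 100.
#'
#' @param cases A [report_set()] of cases (from [split_cases()]).
#' @param cd The [case_definition()] used to split.
#' @return A list of two frequency tables, `main` and `concomitant`
#'   (tibbles with `label`, `count`, `pct`; denominator = number of cases).
#' @export
term_freq <- function(cases, cd) {
  stopifnot(inherits(cases, "report_set"), inherits(cd, "case_definition"))
  denom <- nrow(cases$records)
  per_report <- lapply(cases$records$reactions,
                       function(r) unique(normalize_term(r)))
  main_counts <- count_labels(lapply(per_report, intersect, y = cd$terms))
  conc_counts <- count_labels(lapply(per_report, setdiff, y = cd$terms))
  list(
    main = freq_table(names(main_counts), main_counts, denom, "all_cases"),
    concomitant = freq_table(names(conc_counts), conc_counts, denom, "all_cases")
  )
}

report_atc_letters <- function(rs, role) {
  lapply(rs$records$drugs, function(d) {
    if (role == "suspected") d <- d[d$role == "suspected", , drop = FALSE]
    unique(unlist(d$atc))
  })
}

report_ingredients <- function(rs, role) {
  lapply(rs$records$drugs, function(d) {
    if (role == "suspected") d <- d[d$role == "suspected", , drop = FALSE]
    unique(d$ingredient)
  })
}

#' Report frequencies by first-level ATC class
#'
#' A report counts once toward every distinct ATC letter among its
#' (role-filtered) drugs; percentages of multi-class reports therefore sum
#' above 100, matching how pharmacovigilance class tables are printed.
#'
#' @param rs A [report_set()].
#' @param role `"suspected"` (default) or `"any"`.
#' @param denominator_kind Label recorded on the table (default `all_cases`).
#' @return A frequency tibble (`label`, `count`, `pct`).
#' @export
atc_freq <- function(rs, role = c("suspected", "any"),
                     denominator_kind = "all_cases") {
  stopifnot(inherits(rs, "report_set"))
  role <- match.arg(role)
  counts <- count_labels(report_atc_letters(rs, role))
  freq_table(names(counts), counts, nrow(rs$records), denominator_kind)
}

#' Report frequencies by active ingredient
#'
#' Report-level counts per (normalized) ingredient, most-reported first,
#' ties broken lexicographically.
#'
#' @inheritParams atc_freq
#' @param top_n Keep the first `top_n` rows (default `Inf`, keep all).
#' @return A frequency tibble (`label`, `count`, `pct`).
#' @export
ingredient_freq <- function(rs, top_n = Inf, role = c("suspected", "any"),
                            denominator_kind = "all_cases") {
  stopifnot(inherits(rs, "report_set"))
  role <- match.arg(role)
  counts <- count_labels(report_ingredients(rs, role))
  out <- freq_table(names(counts), counts, nrow(rs$records), denominator_kind)
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  out
}

#' Demographic breakdowns of a report set
#'
#' @param rs A [report_set()].
#' @return A list of frequency tables `sex` and `age_group`; every level of
#'   the vocabulary appears, including zero rows, and since each report has
#'   exactly one value per field the percentages sum to 100 within rounding.
#' @export
demographics <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  denom <- nrow(rs$records)
  sex_counts <- count_labels(as.list(rs$records$sex), SEX_LEVELS)
  age_counts <- count_labels(as.list(rs$records$age_group), AGE_GROUPS)
  list(
    sex = freq_table(names(sex_counts), sex_counts, denom, "all_cases"),
    age_group = freq_table(names(age_counts), age_counts, denom, "all_cases")
  )
}

#' Seriousness-criteria table and serious share
#'
#' Counts reports per regulatory seriousness criterion (a report with several
#' criteria counts toward each) and the share of reports carrying at least
#' one criterion — the "serious" share.
#'
#' @param rs A [report_set()].
#' @return A list with `criteria` (frequency tibble over
#'   [SERIOUSNESS_CRITERIA]), `n_serious` and `serious_pct`.
#' @export
seriousness_table <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  denom <- nrow(rs$records)
  counts <- count_labels(rs$records$seriousness, SERIOUSNESS_CRITERIA)
  n_serious <- sum(lengths(rs$records$seriousness) > 0L)
  list(
    criteria = freq_table(names(counts), counts, denom, "all_cases"),
    n_serious = n_serious,
    serious_pct = if (denom > 0L) pct(n_serious, denom) else NA_real_
  )
}

#' Fatal-outcome share and breakdowns of fatal reports
#'
#' The fatal share uses the fatal-outcome flag (not the `"death"` seriousness
#' criterion — the two are distinct fields with different counts). ATC and
#' ingredient tables are computed over the fatal subset, with the fatal count
#' as denominator.
#'
#' @inheritParams atc_freq
#' @return A list with `n_fatal`, `fatal_pct` (share of all records), `atc`
#'   and `ingredients` frequency tibbles (denominator = fatal count), and
#'   `demographics` of the fatal subset.
#' @export
fatal_breakdowns <- function(rs, role = c("suspected", "any")) {
  stopifnot(inherits(rs, "report_set"))
  role <- match.arg(role)
  denom <- nrow(rs$records)
  fatal_rs <- report_set(rs$records[rs$records$fatal, ],
                         provenance = paste0(rs$provenance, " [fatal]"),
                         deduplicated = rs$deduplicated, n_removed = rs$n_removed)
  n_fatal <- nrow(fatal_rs$records)
  list(
    n_fatal = n_fatal,
    fatal_pct = if (denom > 0L) pct(n_fatal, denom) else NA_real_,
    atc = atc_freq(fatal_rs, role, denominator_kind = "fatal_cases"),
    ingredients = ingredient_freq(fatal_rs, role = role,
                                  denominator_kind = "fatal_cases"),
    demographics = demographics(fatal_rs)
  )
}
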