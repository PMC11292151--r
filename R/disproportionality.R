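#' Construct a 2x2 report-level contingency table
#'
#' Cells count whole reports, cross-classified by "contains the drug" and
#' "meets the case definition":
#' \describe{
#'   \item{a}{drug present and case event present}
#'   \item{b}{drug present, no case event}
#'   \item{c}{case event present, no drug}
#'   \item{d}{neither}
#' }
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param ingredient Optional drug label attached to the table.
#' @return An object of class `contingency_table` with derived margins `N`,
#'   `n_drug` (= a + b) and `n_event` (= a + c).
#' @export
contingency_table <- function(a, b, c, d, ingredient = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) <= 0) stop("table total N must be positive", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d,
                 n_drug = a + b, n_event = a + c, ingredient = ingredient),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>", if (!is.null(x$ingredient)) x$ingredient, "\n")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  cat("N =", x$N, " n_drug =", x$n_drug, " n_event =", x$n_event, "\n")
  invisible(x)
}

report_has_drug <- function(rs, ingredient, role = c("suspected", "any")) {
  role <- match.arg(role)
  vapply(rs$records$drugs, function(d) {
    if (role == "suspected") d <- d[d$role == "suspected", , drop = FALSE]
    ingredient %in% d$ingredient
  }, logical(1))
}

#' Build the 2x2 table for one drug against a case definition
#'
#' A report "has the drug" when any of its drug entries matches the
#' (normalized) ingredient under the role filter; a report "has the event"
#' when [is_case()] is true. Counting is at whole-report level, so a drug
#' listed twice on one report still counts once.
#'
#' @param rs A deduplicated [report_set()] — the comparator population is all
#'   reports in `rs`.
#' @param ingredient Drug label (normalized internally).
#' @param cd A [case_definition()].
#' @param role `"suspected"` (default) counts only suspected drug entries;
#'   `"any"` also counts concomitant ones.
#' @return A [contingency_table()]. If the ingredient is absent the table has
#'   `a = b = 0` (valid; downstream statistics will refuse the zero margin).
#' @export
build_table <- function(rs, ingredient, cd, role = c("suspected", "any")) {
  stopifnot(inherits(rs, "report_set"), inherits(cd, "case_definition"))
  role <- match.arg(role)
  ingredient <- normalize_ingredient(ingredient)
  has_drug <- report_has_drug(rs, ingredient, role)
  has_event <- is_case(rs, cd)
  contingency_table(
    a = sum(has_drug & has_event),
    b = sum(has_drug & !has_event),
    c = sum(!has_drug & has_event),
    d = sum(!has_drug & !has_event),
    ingredient = ingredient
  )
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a d) / (b c); the two-sided 100(1 - alpha)% interval is
#' exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d)) (Woolf logit method). When
#' any raw cell is zero and `continuity = TRUE`, 0.5 is added to all four
#' cells first (Haldane-Anscombe correction); with continuity disabled a zero
#' cell is an error because the estimate is undefined.
#'
#' @param t A [contingency_table()].
#' @param alpha Two-sided type-I level for the interval (default 0.05).
#' @param continuity Apply the 0.5 correction when a cell is zero?
#' @return A list with `ror`, `ci_low`, `ci_high`.
#' @export
ror <- function(t, alpha = 0.05, continuity = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (!continuity) {
      stop("zero cell: ROR undefined without continuity correction",
           call. = FALSE)
    }
    cells <- cells + 0.5
  }
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  list(ror = est,
       ci_low = exp(log(est) - z * se),
       ci_high = exp(log(est) + z * se))
}

#' Bayesian information component (IC) and its lower credibility bound
#'
#' The IC compares the observed count of reports with both drug and event
#' against the count expected under independence, on a log2 scale with
#' shrinkage: E = n_drug n_event / N and IC = log2((a + 0.5) / (E + 0.5)).
#' The 0.5 shrinkage pulls small-count associations toward zero, damping
#' spurious signals. IC025, the lower end of the 95% credibility interval, is
#' the screening statistic: IC025 > 0 means even the pessimistic end of the
#' interval has observed exceeding expected.
#'
#' Two modes for IC025:
#' \describe{
#'   \item{`"approx"`}{the closed-form approximation
#'     IC - 3.3 (a + 0.5)^(-1/2) - 2 (a + 0.5)^(-3/2), the default;}
#'   \item{`"gamma"`}{the exact 2.5% quantile of the posterior
#'     Gamma(a + 0.5, E + 0.5) on the log2 scale.}
#' }
#' The deviation between the two depends only on the observed count and stays
#' below 0.05 log2 units, peaking near a = 20.
#'
#' @param t A [contingency_table()] with positive N, n_drug and n_event.
#' @param method `"approx"` or `"gamma"`.
#' @return A list with `ic`, `ic025` and `expected` (E).
#' @export
ic <- function(t, method = c("approx", "gamma")) {
  stopifnot(inherits(t, "contingency_table"))
  method <- match.arg(method)
  if (t$N <= 0 || t$n_drug <= 0 || t$n_event <= 0) {
    stop("IC undefined: N, n_drug and n_event must all be positive",
         call. = FALSE)
  }
  e <- t$n_drug * t$n_event / t$N
  o <- t$a + 0.5
  ic_val <- log2(o / (e + 0.5))
  ic025 <- switch(method,
    approx = ic_val - 3.3 * o^(-0.5) - 2 * o^(-1.5),
    gamma = log2(stats::qgamma(0.025, shape = o, rate = e + 0.5))
  )
  list(ic = ic_val, ic025 = ic025, expected = e)
}

#' Two-stage disproportionality screen
#'
#' Flags results where IC025 > 0 (strict) AND ROR > 1: the IC credibility
#' bound is the primary gate and the ROR the confirmation. Results failing
#' the gate are kept with `screened_in = FALSE` — negative and null
#' associations are reported, not hidden.
#'
#' @param results A tibble with columns `ic025` and `ror` (as produced by
#'   [run_disproportionality()]).
#' @return The same tibble with a logical `screened_in` column.
#' @export
screen <- function(results) {
  stopifnot(all(c("ic025", "ror") %in% names(results)))
  dplyr::mutate(results, screened_in = .data$ic025 > 0 & .data$ror > 1)
}

atc_of_ingredient <- function(rs, ingredient, role) {
  letters <- unlist(lapply(rs$records$drugs, function(d) {
    if (role == "suspected") d <- d[d$role == "suspected", , drop = FALSE]
    unlist(d$atc[d$ingredient == ingredient])
  }))
  paste(sort(unique(letters)), collapse = ";")
}

#' Disproportionality analysis of every drug in a report set
#'
#' Builds the report-level 2x2 table for each distinct ingredient (under the
#' role filter), computes ROR with its 95% CI and IC with IC025, applies the
#' two-stage screen, and ranks by IC025 descending (ties: ROR descending,
#' then ingredient name). Drugs with fewer than `min_reports` drug-and-event
#' reports are dropped to avoid vacuous signals.
#'
#' @inheritParams build_table
#' @param min_reports Minimum `a` cell (default 3).
#' @param alpha,continuity Passed to [ror()].
#' @param ic_method Passed to [ic()].
#' @return A tibble with one row per ingredient: `ingredient`, `atc`, `a`,
#'   `b`, `c`, `d`, `n_reports` (= a), `expected`, `ror`, `ror_ci_low`,
#'   `ror_ci_high`, `ic`, `ic025`, `screened_in`.
#' @export
run_disproportionality <- function(rs, cd, min_reports = 3,
                                   role = c("suspected", "any"),
                                   alpha = 0.05, continuity = TRUE,
                                   ic_method = c("approx", "gamma")) {
  stopifnot(inherits(rs, "report_set"), inherits(cd, "case_definition"))
  role <- match.arg(role)
  ic_method <- match.arg(ic_method)
  n <- nrow(rs$records)
  if (n == 0L) return(empty_dispro_tibble())

  has_event <- is_case(rs, cd)
  per_report <- lapply(rs$records$drugs, function(d) {
    if (role == "suspected") d <- d[d$role == "suspected", , drop = FALSE]
    unique(d$ingredient)
  })
  idx <- rep.int(seq_len(n), lengths(per_report))
  ing <- unlist(per_report)
  if (length(ing) == 0L) return(empty_dispro_tibble())

  a_by <- tapply(has_event[idx], ing, sum)
  nd_by <- tapply(idx, ing, length)
  n_event <- sum(has_event)

  rows <- lapply(names(a_by), function(g) {
    a <- as.integer(a_by[[g]]); nd <- as.integer(nd_by[[g]])
    if (a < min_reports) return(NULL)
    t <- contingency_table(a, nd - a, n_event - a, n - nd - (n_event - a),
                           ingredient = g)
    r <- ror(t, alpha = alpha, continuity = continuity)
    i <- ic(t, method = ic_method)
    tibble::tibble(ingredient = g, atc = atc_of_ingredient(rs, g, role),
                   a = t$a, b = t$b, c = t$c, d = t$d, n_reports = t$a,
                   expected = i$expected, ror = r$ror,
                   ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
                   ic = i$ic, ic025 = i$ic025)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty_dispro_tibble())
  out <- screen(out)
  dplyr::arrange(out, dplyr::desc(.data$ic025), dplyr::desc(.data$ror),
                 .data$ingredient)
}

empty_dispro_tibble <- function() {
  tibble::tibble(ingredient = character(0), atc = character(0),
                 a = integer(0), b = integer(0), c = integer(0), d = integer(0),
                 n_reports = integer(0), expected = numeric(0), ror = numeric(0),
                 ror_ci_low = numeric(0), ror_ci_high = numeric(0),
                 ic = numeric(0), ic025 = numeric(0), screened_in = logical(0))
}
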