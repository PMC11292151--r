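#' Declare a planted drug-event association
#'
#' A planted signal multiplies, for every report containing the signal
#' ingredient, the odds of including each of its event terms by `lambda`.
#' Because inclusion is an independent Bernoulli per term, the report-level
#' 2x2 odds ratio implied for a single-term signal equals `lambda` exactly
#' (up to the small conditioning on reports being nonempty), which makes the
#' generator's truth analytically available to tests.
#'
#' @param ingredient Drug label (normalized internally).
#' @param event_terms Character vector of reaction terms receiving the odds
#'   multiplier (nonempty).
#' @param lambda Odds multiplier >= 1; 1 means a null association.
#' @param expect_detect Should the screen find this signal at the configured
#'   sample size? Bookkeeping flag for tests; `NA` if unstated.
#' @return An object of class `planted_signal`.
#' @export
planted_signal <- function(ingredient, event_terms, lambda,
                           expect_detect = NA) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (lambda < 1) stop("lambda must be >= 1", call. = FALSE)
  event_terms <- unique(normalize_term(as.character(event_terms)))
  event_terms <- event_terms[nzchar(event_terms)]
  if (length(event_terms) == 0L) {
    stop("a planted signal needs at least one event term", call. = FALSE)
  }
  structure(list(ingredient = normalize_ingredient(ingredient),
                 event_terms = event_terms, lambda = as.numeric(lambda),
                 expect_detect = expect_detect),
            class = "planted_signal")
}

check_prob <- function(p, what, open = TRUE) {
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop(what, " must be in (0, 1)", call. = FALSE)
  }
  invisible(p)
}

#' Configure the synthetic report generator
#'
#' Describes a spontaneous-reporting background: per-drug and per-term
#' inclusion probabilities, planted drug-event signals, demographic
#' distributions, per-criterion seriousness probabilities, a fatal-outcome
#' probability and a seed. Each report includes every catalog drug and term
#' independently with its marginal probability (signals multiply term odds,
#' see [planted_signal()]); reports are conditioned on containing at least
#' one drug and one reaction by redrawing empty draws.
#'
#' @param n_reports Number of reports to generate (>= 0).
#' @param drug_catalog Data frame with columns `ingredient`, `atc`
#'   (`";"`-separated first-level letters, possibly empty) and `prob`.
#' @param term_catalog Data frame with columns `term` and `prob`.
#' @param signals List of [planted_signal()] objects (signal ingredients must
#'   appear in the drug catalog, event terms in the term catalog).
#' @param demographics List with named probability vectors `sex`, `age_group`
#'   and `year` (names are the category labels; each vector sums to 1).
#' @param seriousness_probs Named vector of per-criterion probabilities over
#'   [SERIOUSNESS_CRITERIA]; criteria are drawn independently.
#' @param fatal_prob Probability of a fatal outcome.
#' @param seed Integer seed; a fixed seed makes [generate_reports()] output
#'   bit-reproducible.
#' @return An object of class `synthetic_config`.
#' @seealso [default_synthetic_config()], [generate_reports()],
#'   [true_tables()]
#' @export
synthetic_config <- function(n_reports, drug_catalog, term_catalog,
                             signals = list(), demographics = NULL,
                             seriousness_probs = NULL, fatal_prob = 0.1,
                             seed = 1L) {
  stopifnot(is.numeric(n_reports), length(n_reports) == 1L, n_reports >= 0)
  drug_catalog <- tibble::as_tibble(drug_catalog)
  term_catalog <- tibble::as_tibble(term_catalog)
  stopifnot(all(c("ingredient", "atc", "prob") %in% names(drug_catalog)),
            all(c("term", "prob") %in% names(term_catalog)),
            nrow(drug_catalog) > 0L, nrow(term_catalog) > 0L)
  drug_catalog$ingredient <- normalize_ingredient(drug_catalog$ingredient)
  term_catalog$term <- normalize_term(term_catalog$term)
  if (anyDuplicated(drug_catalog$ingredient) || anyDuplicated(term_catalog$term)) {
    stop("catalog entries must be unique", call. = FALSE)
  }
  check_prob(drug_catalog$prob, "drug marginal probabilities")
  check_prob(term_catalog$prob, "term marginal probabilities")
  if (inherits(signals, "planted_signal")) signals <- list(signals)
  for (s in signals) {
    stopifnot(inherits(s, "planted_signal"))
    if (!s$ingredient %in% drug_catalog$ingredient) {
      stop("signal ingredient not in drug catalog: ", s$ingredient, call. = FALSE)
    }
    if (!all(s$event_terms %in% term_catalog$term)) {
      stop("signal event terms not all in term catalog: ", s$ingredient,
           call. = FALSE)
    }
  }
  if (is.null(demographics)) {
    demographics <- list(
      sex = c(male = 0.495, female = 0.45, unknown = 0.055),
      age_group = c("0-1" = 0.02, "2-11" = 0.03, "12-17" = 0.03,
                    "18-44" = 0.25, "45-64" = 0.255, "65-74" = 0.15,
                    ">=75" = 0.15, "unknown" = 0.115),
      year = stats::setNames(
        c(0.055, 0.06, 0.065, 0.07, 0.075, 0.08, 0.085, 0.09, 0.095, 0.109,
          0.078, 0.07, 0.068),
        as.character(2010:2022))
    )
  }
  for (nm in c("sex", "age_group", "year")) {
    p <- demographics[[nm]]
    if (is.null(p) || is.null(names(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6) {
      stop("demographics$", nm, " must be a named probability vector summing to 1",
           call. = FALSE)
    }
  }
  if (is.null(seriousness_probs)) {
    seriousness_probs <- c(other_medically_important = 0.441,
                           hospitalization = 0.405, death = 0.115,
                           life_threatening = 0.066, disabling = 0.026,
                           congenital_anomaly = 0.001)
  }
  if (!setequal(names(seriousness_probs), SERIOUSNESS_CRITERIA) ||
      any(seriousness_probs < 0) || any(seriousness_probs >= 1)) {
    stop("seriousness_probs must cover exactly the seriousness criteria with probabilities in [0, 1)",
         call. = FALSE)
  }
  stopifnot(fatal_prob >= 0, fatal_prob < 1)
  structure(list(n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog, term_catalog = term_catalog,
                 signals = signals, demographics = demographics,
                 seriousness_probs = seriousness_probs[SERIOUSNESS_CRITERIA],
                 fatal_prob = fatal_prob, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' A realistic default generator configuration
#'
#' A background of 20 drugs (proton pump inhibitors, antivirals, antibiotics,
#' diuretics, ...) and 18 reaction terms — the ten acute-kidney-disease
#' preferred terms plus common co-reported reactions — with inclusion
#' probabilities chosen so that reports average roughly 1-2 drugs and 1-2
#' reactions, kidney terms are a minority of the background, and demographic,
#' seriousness and fatal-outcome rates resemble published case series.
#'
#' @param n_reports Number of reports.
#' @param signals Optional list of [planted_signal()] objects.
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
default_synthetic_config <- function(n_reports = 20000, signals = list(),
                                     seed = 1L) {
  drug_catalog <- tibble::tribble(
    ~ingredient, ~atc, ~prob,
    "omeprazole", "A", 0.050,
    "esomeprazole", "A", 0.040,
    "lansoprazole", "A", 0.035,
    "pantoprazole", "A", 0.030,
    "metformin", "A", 0.030,
    "emtricitabine + tenofovir disoproxil", "J", 0.010,
    "tenofovir disoproxil", "J", 0.012,
    "vancomycin", "J", 0.020,
    "gentamicin", "J", 0.008,
    "acyclovir", "J", 0.008,
    "covid-19 vaccine", "J", 0.025,
    "furosemide", "C", 0.025,
    "spironolactone", "C", 0.012,
    "lisinopril", "C", 0.015,
    "rivaroxaban", "B", 0.015,
    "ibuprofen", "M", 0.040,
    "paracetamol", "N", 0.045,
    "methotrexate", "L", 0.015,
    "lenalidomide", "L", 0.012,
    "ciclosporin", "L", 0.010
  )
  term_catalog <- tibble::tribble(
    ~term, ~prob,
    "acute kidney injury", 0.020,
    "renal failure", 0.014,
    "renal impairment", 0.010,
    "blood creatinine increased", 0.008,
    "renal injury", 0.003,
    "blood urea increased", 0.003,
    "tubulointerstitial nephritis", 0.002,
    "glomerular filtration rate decreased", 0.001,
    "oliguria", 0.001,
    "anuria", 0.001,
    "nausea", 0.120,
    "diarrhoea", 0.100,
    "vomiting", 0.090,
    "headache", 0.110,
    "dizziness", 0.080,
    "pyrexia", 0.070,
    "fatigue", 0.090,
    "rash", 0.080
  )
  synthetic_config(n_reports = n_reports, drug_catalog = drug_catalog,
                   term_catalog = term_catalog, signals = signals,
                   fatal_prob = 0.137, seed = seed)
}

odds_adjust <- function(p, mult) {
  odds <- p / (1 - p) * mult
  odds / (1 + odds)
}

# Draw the report x drug and report x term inclusion matrices. Assumes the
# RNG state has been set by the caller; draw order (drugs, then terms, then
# redraws) is part of the reproducibility contract.
draw_inclusions <- function(cfg) {
  n <- cfg$n_reports
  q <- cfg$drug_catalog$prob
  p <- cfg$term_catalog$prob
  nd <- length(q); nt <- length(p)

  qmat <- matrix(q, n, nd, byrow = TRUE)
  drug_mat <- matrix(stats::runif(n * nd), n, nd) < qmat
  repeat {
    empty <- which(rowSums(drug_mat) == 0L)
    if (length(empty) == 0L) break
    drug_mat[empty, ] <- matrix(stats::runif(length(empty) * nd),
                                length(empty), nd) < qmat[empty, , drop = FALSE]
  }

  mult <- matrix(1, n, nt)
  for (s in cfg$signals) {
    j <- match(s$ingredient, cfg$drug_catalog$ingredient)
    cols <- match(s$event_terms, cfg$term_catalog$term)
    rows <- which(drug_mat[, j])
    mult[rows, cols] <- mult[rows, cols] * s$lambda
  }
  pmat <- odds_adjust(matrix(p, n, nt, byrow = TRUE), mult)
  term_mat <- matrix(stats::runif(n * nt), n, nt) < pmat
  repeat {
    empty <- which(rowSums(term_mat) == 0L)
    if (length(empty) == 0L) break
    term_mat[empty, ] <- matrix(stats::runif(length(empty) * nt),
                                length(empty), nt) < pmat[empty, , drop = FALSE]
  }
  list(drug_mat = drug_mat, term_mat = term_mat)
}

#' Generate a synthetic report set
#'
#' Draws `cfg$n_reports` notifications from the configured background model:
#' drugs and reaction terms by independent inclusion (conditioned nonempty),
#' planted signals by odds multiplication, demographics, seriousness criteria
#' and fatal outcome independently from their configured distributions. All
#' generated drug entries carry the `"suspected"` role. The same seed yields
#' bit-identical output.
#'
#' @param cfg A [synthetic_config()].
#' @return A [report_set()] with `provenance = "synthetic"`.
#' @export
generate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_reports
  if (n == 0L) {
    return(report_set(provenance = "synthetic", deduplicated = TRUE,
                      n_removed = 0L))
  }
  set.seed(cfg$seed)
  inc <- draw_inclusions(cfg)

  dem <- cfg$demographics
  sex <- sample(names(dem$sex), n, replace = TRUE, prob = dem$sex)
  age <- sample(names(dem$age_group), n, replace = TRUE, prob = dem$age_group)
  year <- as.integer(sample(names(dem$year), n, replace = TRUE, prob = dem$year))
  ser_mat <- matrix(stats::runif(n * length(cfg$seriousness_probs)), n) <
    matrix(cfg$seriousness_probs, n, length(cfg$seriousness_probs), byrow = TRUE)
  fatal <- stats::runif(n) < cfg$fatal_prob

  cat_ing <- cfg$drug_catalog$ingredient
  cat_atc <- lapply(cfg$drug_catalog$atc, parse_atc)
  terms <- cfg$term_catalog$term
  crit <- SERIOUSNESS_CRITERIA

  hits_d <- which(inc$drug_mat, arr.ind = TRUE)
  drugs_by_row <- split(hits_d[, 2], factor(hits_d[, 1], levels = seq_len(n)))
  hits_t <- which(inc$term_mat, arr.ind = TRUE)
  terms_by_row <- split(hits_t[, 2], factor(hits_t[, 1], levels = seq_len(n)))

  drugs <- lapply(drugs_by_row, function(js) {
    js <- sort(js)
    tibble::new_tibble(list(ingredient = cat_ing[js], atc = cat_atc[js],
                            role = rep("suspected", length(js))),
                       nrow = length(js))
  })
  reactions <- lapply(terms_by_row, function(js) sort(terms[js]))
  seriousness <- lapply(seq_len(n), function(i) crit[ser_mat[i, ]])

  records <- tibble::tibble(
    report_id = sprintf("SYN%07d", seq_len(n)),
    year = year, sex = sex, age_group = age,
    drugs = unname(drugs), reactions = unname(reactions),
    seriousness = seriousness, fatal = fatal
  )
  report_set(records, provenance = "synthetic", deduplicated = TRUE,
             n_removed = 0L)
}

#' Simulate per-drug 2x2 tables directly
#'
#' Draws the same drug/term inclusion matrices as [generate_reports()] (same
#' seed, same draws) and tabulates report-level contingency tables for each
#' requested ingredient against an event defined by a set of terms, skipping
#' the per-record assembly. Used for replicate-heavy operating-characteristic
#' studies; on a common seed its cell counts equal [build_table()] applied to
#' [generate_reports()] output.
#'
#' @param cfg A [synthetic_config()].
#' @param cd A [case_definition()] or character vector of event terms.
#' @param ingredients Ingredients to tabulate (default: whole drug catalog).
#' @return A tibble with columns `ingredient`, `a`, `b`, `c`, `d`.
#' @export
simulate_contingency <- function(cfg, cd, ingredients = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  terms <- if (inherits(cd, "case_definition")) cd$terms else normalize_term(cd)
  if (is.null(ingredients)) ingredients <- cfg$drug_catalog$ingredient
  ingredients <- normalize_ingredient(ingredients)
  set.seed(cfg$seed)
  inc <- draw_inclusions(cfg)
  ev_cols <- which(cfg$term_catalog$term %in% terms)
  has_event <- rowSums(inc$term_mat[, ev_cols, drop = FALSE]) > 0L
  n_ev <- sum(has_event)
  n <- cfg$n_reports
  rows <- lapply(ingredients, function(g) {
    j <- match(g, cfg$drug_catalog$ingredient)
    if (is.na(j)) stop("ingredient not in catalog: ", g, call. = FALSE)
    has_drug <- inc$drug_mat[, j]
    a <- sum(has_drug & has_event)
    tibble::tibble(ingredient = g, a = a, b = sum(has_drug) - a,
                   c = n_ev - a, d = n - sum(has_drug) - n_ev + a)
  })
  dplyr::bind_rows(rows)
}

#' Closed-form expected contingency probabilities for planted signals
#'
#' Computes, for each planted signal, the exact cell probabilities
#' (P(a), P(b), P(c), P(d)) of the report-level 2x2 table implied by the
#' generative model — independent inclusion with odds multiplication,
#' conditioned on at least one drug and one term per report — together with
#' the implied odds ratio. Exact enumeration over the joint presence states
#' of all signal drugs; used as a simulation oracle.
#'
#' @param cfg A [synthetic_config()] with at least one signal.
#' @return A tibble with columns `ingredient`, `lambda`, `p_a`, `p_b`, `p_c`,
#'   `p_d` and `odds_ratio`.
#' @export
true_tables <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (length(cfg$signals) == 0L) {
    stop("config has no planted signals", call. = FALSE)
  }
  q <- cfg$drug_catalog$prob
  p <- cfg$term_catalog$prob
  sig_idx <- vapply(cfg$signals, function(s)
    match(s$ingredient, cfg$drug_catalog$ingredient), integer(1))
  k <- length(sig_idx)
  if (k > 12L) stop("closed form supported for at most 12 signal drugs", call. = FALSE)

  # P(exact signal-drug subset S present, >= 1 drug overall) / P(>= 1 drug)
  p_none_all <- prod(1 - q)
  p_none_nonsig <- prod(1 - q[-sig_idx])
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  w <- apply(subsets, 1, function(in_s) {
    base <- prod(ifelse(in_s, q[sig_idx], 1 - q[sig_idx]))
    if (!any(in_s)) base * (1 - p_none_nonsig) else base
  })
  w <- w / (1 - p_none_all)

  # event probability given a signal-drug subset, conditioned >= 1 term
  event_prob <- function(in_s, ev_cols) {
    mult <- rep(1, length(p))
    for (si in which(in_s)) {
      cols <- match(cfg$signals[[si]]$event_terms, cfg$term_catalog$term)
      mult[cols] <- mult[cols] * cfg$signals[[si]]$lambda
    }
    padj <- odds_adjust(p, mult)
    (1 - prod(1 - padj[ev_cols])) / (1 - prod(1 - padj))
  }

  rows <- lapply(seq_along(cfg$signals), function(si) {
    s <- cfg$signals[[si]]
    ev_cols <- match(s$event_terms, cfg$term_catalog$term)
    pe <- apply(subsets, 1, event_prob, ev_cols = ev_cols)
    has_d <- subsets[[si]]
    a <- sum(w[has_d] * pe[has_d]); b <- sum(w[has_d] * (1 - pe[has_d]))
    cc <- sum(w[!has_d] * pe[!has_d]); d <- sum(w[!has_d] * (1 - pe[!has_d]))
    tibble::tibble(ingredient = s$ingredient, lambda = s$lambda,
                   p_a = a, p_b = b, p_c = cc, p_d = d,
                   odds_ratio = (a * d) / (b * cc))
  })
  dplyr::bind_rows(rows)
}
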