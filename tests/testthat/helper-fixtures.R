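# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use plain per-record loops, not the package's
# vectorized counting paths.

make_drugs <- function(...) {
  dplyr::bind_rows(list(...))
}

# quick record builder with defaults
rec <- function(id, drugs, reactions, year = 2020L, sex = "female",
                age_group = "45-64", seriousness = character(0),
                fatal = FALSE) {
  notification(report_id = id, drugs = drugs, reactions = reactions,
               year = year, sex = sex, age_group = age_group,
               seriousness = seriousness, fatal = fatal)
}

# a random report set built record by record, independent of the package's
# synthetic generator
random_report_set <- function(n, seed, n_drugs = 6, n_terms = 8) {
  set.seed(seed)
  drug_names <- paste0("drug", seq_len(n_drugs))
  atc_pool <- c("A", "C", "J", "L", "M", "N")
  term_pool <- c("acute kidney injury", "renal failure", "oliguria",
                 "nausea", "headache", "rash", "pyrexia", "dizziness")[seq_len(n_terms)]
  recs <- lapply(seq_len(n), function(i) {
    k_d <- sample(1:3, 1)
    di <- sample(n_drugs, k_d)
    drugs <- dplyr::bind_rows(lapply(di, function(j) {
      drug_entry(drug_names[j], atc = sample(atc_pool, sample(0:2, 1)),
                 role = sample(c("suspected", "concomitant"), 1, prob = c(0.8, 0.2)))
    }))
    rec(sprintf("R%04d", i), drugs,
        reactions = sample(term_pool, sample(1:3, 1)),
        year = sample(2015:2022, 1),
        sex = sample(c("male", "female", "unknown"), 1),
        age_group = sample(AGE_GROUPS, 1),
        seriousness = sample(SERIOUSNESS_CRITERIA, sample(0:2, 1)),
        fatal = runif(1) < 0.2)
  })
  report_set(recs, provenance = "test")
}

# ---- oracles ------------------------------------------------------------

oracle_has_drug <- function(record_drugs, ingredient, role) {
  hit <- FALSE
  for (i in seq_len(nrow(record_drugs))) {
    if (role == "suspected" && record_drugs$role[i] != "suspected") next
    if (record_drugs$ingredient[i] == ingredient) hit <- TRUE
  }
  hit
}

oracle_table <- function(rs, ingredient, cd, role = "suspected") {
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(rs$records))) {
    hd <- oracle_has_drug(rs$records$drugs[[i]], ingredient, role)
    he <- length(intersect(tolower(trimws(rs$records$reactions[[i]])),
                           cd$terms)) > 0
    if (hd && he) a <- a + 1L
    else if (hd) b <- b + 1L
    else if (he) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

oracle_ror <- function(a, b, c, d, alpha = 0.05) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  est <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  c(ror = est, lo = exp(log(est) - z * se), hi = exp(log(est) + z * se))
}

oracle_ic <- function(a, n_drug, n_event, n) {
  a <- unname(a); n_drug <- unname(n_drug); n_event <- unname(n_event)
  e <- n_drug * n_event / n
  ic <- log2((a + 0.5) / (e + 0.5))
  c(ic = ic, ic025 = ic - 3.3 * (a + 0.5)^-0.5 - 2 * (a + 0.5)^-1.5)
}

# per-label report counts by scanning one record at a time
oracle_label_counts <- function(label_sets) {
  counts <- list()
  for (s in label_sets) {
    for (lab in unique(s)) {
      counts[[lab]] <- (counts[[lab]] %||% 0L) + 1L
    }
  }
  unlist(counts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

expect_same_freq <- function(ft, oracle_counts) {
  got <- setNames(ft$count, ft$label)
  oracle_counts <- oracle_counts[oracle_counts > 0]
  expect_mapequal(as.list(got[got > 0]), as.list(oracle_counts))
}
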