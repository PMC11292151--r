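#' Normalize an active-ingredient label
#'
#' Canonicalizes WHODrug-style ingredient names so that the same substance
#' always compares equal: trims and collapses whitespace, lower-cases, and for
#' combination products splits on `"+"`, normalizes each component, sorts
#' components lexicographically and re-joins them with `" + "`. The function is
#' idempotent and invariant to the order in which combination components are
#' written.
#'
#' @param raw Character vector of ingredient labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_ingredient("  Omeprazole ")
#' normalize_ingredient("tenofovir disoproxil + emtricitabine")
#' @export
normalize_ingredient <- function(raw) {
  if (!is.character(raw)) {
    stop("`raw` must be a character vector", call. = FALSE)
  }
  out <- vapply(raw, function(x) {
    if (is.na(x)) {
      stop("ingredient label must not be NA", call. = FALSE)
    }
    parts <- strsplit(x, "+", fixed = TRUE)[[1]]
    parts <- tolower(trimws(gsub("[[:space:]]+", " ", parts)))
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) {
      stop("ingredient label is empty after normalization: ",
           encodeString(x, quote = "\""), call. = FALSE)
    }
    paste(sort(parts), collapse = " + ")
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Normalize a reaction preferred term for matching
#'
#' Lower-cases, trims and collapses internal whitespace. Used for
#' case-insensitive matching of MedDRA-style preferred terms against a case
#' definition.
#'
#' @param term Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(term) {
  tolower(trimws(gsub("[[:space:]]+", " ", term)))
}

norm_enum <- function(x, levels, unknown = "unknown") {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | !nzchar(x) | !(x %in% levels)] <- unknown
  x
}

parse_atc <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  letters <- toupper(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
  letters <- letters[nzchar(letters)]
  bad <- setdiff(letters, ATC_LETTERS)
  if (length(bad) > 0L) {
    warning("dropping unrecognized ATC letter(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    letters <- intersect(letters, ATC_LETTERS)
  }
  sort(unique(letters))
}

#' Construct one drug entry
#'
#' @param ingredient Ingredient label (normalized internally).
#' @param atc Character vector of first-level ATC letters (possibly empty), or
#'   a single `";"`-separated string.
#' @param role `"suspected"` or `"concomitant"`.
#' @return A one-row tibble with columns `ingredient`, `atc` (list column of
#'   letters) and `role`.
#' @export
drug_entry <- function(ingredient, atc = character(0), role = "suspected") {
  role <- match.arg(role, c("suspected", "concomitant"))
  if (length(atc) == 1L && grepl(";", atc)) atc <- strsplit(atc, ";")[[1]]
  atc <- toupper(trimws(as.character(atc)))
  atc <- atc[nzchar(atc)]
  if (length(atc) > 0L && !all(atc %in% ATC_LETTERS)) {
    stop("ATC letters must be in {", paste(ATC_LETTERS, collapse = ","), "}",
         call. = FALSE)
  }
  tibble::tibble(ingredient = normalize_ingredient(ingredient),
                 atc = list(sort(unique(atc))), role = role)
}

#' Construct one notification record
#'
#' A notification is one deduplicated spontaneous report: at least one drug,
#' at least one reaction term, demographics, regulatory seriousness criteria
#' and the fatal-outcome flag. The fatal flag is a reported outcome and is
#' deliberately independent of whether `"death"` appears among the seriousness
#' criteria: the two fields come from different parts of a report form and
#' their counts differ in real databases.
#'
#' @param report_id Unique identifier string.
#' @param drugs A tibble of drug entries (rows from [drug_entry()]).
#' @param reactions Character vector of reaction preferred terms (>= 1).
#' @param year Integer year of receipt (`NA` allowed).
#' @param sex,age_group Demographic values; unrecognized values map to
#'   `"unknown"` (see [vocabularies]).
#' @param seriousness Character vector of seriousness criteria (possibly
#'   empty), from [SERIOUSNESS_CRITERIA].
#' @param fatal Logical fatal-outcome flag.
#' @return A one-row tibble in the `report_set` record layout.
#' @export
notification <- function(report_id, drugs, reactions, year = NA_integer_,
                         sex = "unknown", age_group = "unknown",
                         seriousness = character(0), fatal = FALSE) {
  stopifnot(is.character(report_id), length(report_id) == 1L, nzchar(report_id))
  if (is.data.frame(drugs)) drugs <- tibble::as_tibble(drugs)
  else stop("`drugs` must be a data frame of drug entries", call. = FALSE)
  if (nrow(drugs) == 0L) stop("a notification needs at least one drug", call. = FALSE)
  reactions <- trimws(gsub("[[:space:]]+", " ", as.character(reactions)))
  reactions <- unique(reactions[nzchar(reactions)])
  if (length(reactions) == 0L) {
    stop("a notification needs at least one reaction term", call. = FALSE)
  }
  seriousness <- unique(as.character(seriousness))
  bad <- setdiff(seriousness, SERIOUSNESS_CRITERIA)
  if (length(bad) > 0L) {
    stop("unknown seriousness criteria: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    report_id = report_id,
    year = as.integer(year),
    sex = norm_enum(sex, SEX_LEVELS),
    age_group = ifelse(trimws(as.character(age_group)) %in% AGE_GROUPS,
                       trimws(as.character(age_group)), "unknown"),
    drugs = list(drugs),
    reactions = list(sort(reactions)),
    seriousness = list(sort(seriousness)),
    fatal = isTRUE(fatal)
  )
}

#' Construct a report set
#'
#' A `report_set` is the package's container for a collection of notification
#' records: a tibble of records plus provenance and deduplication metadata.
#'
#' @param records A tibble of records (rows from [notification()]), or a list
#'   of such one-row tibbles.
#' @param provenance Free-text label describing where the reports came from.
#' @param deduplicated Logical; has [deduplicate()] been applied?
#' @param n_removed Number of duplicates removed (NA if never deduplicated).
#' @return An object of class `report_set`.
#' @export
report_set <- function(records = NULL, provenance = "unspecified",
                       deduplicated = FALSE, n_removed = NA_integer_) {
  if (is.null(records)) {
    records <- tibble::tibble(
      report_id = character(0), year = integer(0), sex = character(0),
      age_group = character(0), drugs = list(), reactions = list(),
      seriousness = list(), fatal = logical(0))
  }
  if (is.list(records) && !is.data.frame(records)) {
    records <- dplyr::bind_rows(records)
  }
  records <- tibble::as_tibble(records)
  if (anyDuplicated(records$report_id) > 0L) {
    stop("duplicate report_id in report set", call. = FALSE)
  }
  structure(list(records = records, provenance = provenance,
                 deduplicated = deduplicated,
                 n_removed = as.integer(n_removed)),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x$records), " notification(s)",
      if (isTRUE(x$deduplicated)) sprintf(" [deduplicated, %d removed]", x$n_removed),
      "\n  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
length.report_set <- function(x) nrow(x$records)

#' Number of records in a report set
#' @param rs A `report_set`.
#' @return Integer count.
#' @export
n_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  nrow(rs$records)
}

# Canonical long-format column names; a schema maps these onto file columns.
CANONICAL_COLUMNS <- c("report_id", "year", "sex", "age_group", "drug", "atc",
                       "role", "reaction", "seriousness", "fatal")
MANDATORY_COLUMNS <- c("report_id", "drug", "reaction")

resolve_schema <- function(schema, file_cols) {
  if (is.null(schema)) {
    schema <- stats::setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
  } else if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- unlist(yaml::read_yaml(schema))
  }
  schema <- schema[names(schema) %in% CANONICAL_COLUMNS]
  schema <- schema[schema %in% file_cols]
  missing <- setdiff(MANDATORY_COLUMNS, names(schema))
  if (length(missing) > 0L) {
    stop("schema error: mandatory column(s) not mapped or absent from file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  schema
}

parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "y", "fatal")
}

#' Read a spontaneous-report table
#'
#' Reads a long-format delimited text file (one row per report x drug x
#' reaction combination) and aggregates it into one [notification()] record
#' per distinct report id. Multi-valued cells (ATC letters, seriousness
#' criteria) use `";"` as the internal separator. Demographics are taken from
#' the first row of each report id; unrecognized sex/age values map to
#' `"unknown"`. Ingredient labels are normalized with [normalize_ingredient()].
#'
#' @param path Path to a comma- or tab-delimited UTF-8 file with a header row.
#' @param schema Optional column mapping: a named character vector (names are
#'   the canonical fields `report_id`, `year`, `sex`, `age_group`, `drug`,
#'   `atc`, `role`, `reaction`, `seriousness`, `fatal`; values are the file's
#'   column names), or a path to a YAML file containing that mapping. `NULL`
#'   means the file already uses the canonical names.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A [report_set()]. An empty file yields an empty set with a warning;
#'   a missing mandatory column is a schema error.
#' @seealso [write_reports()]
#' @export
read_reports <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (length(first) > 0L && grepl("\t", first[1])) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty report file: ", path, call. = FALSE)
    return(report_set(provenance = path))
  }
  schema <- resolve_schema(schema, names(raw))
  long <- tibble::tibble(.rows = nrow(raw))
  for (canon in CANONICAL_COLUMNS) {
    long[[canon]] <- if (canon %in% names(schema)) raw[[schema[[canon]]]] else NA_character_
  }

  if (anyNA(long$report_id) || anyNA(long$drug) || anyNA(long$reaction)) {
    stop("schema error: missing values in report id, drug or reaction",
         call. = FALSE)
  }
  long$drug <- normalize_ingredient(long$drug)
  long$reaction <- trimws(gsub("[[:space:]]+", " ", long$reaction))
  role <- tolower(trimws(long$role))
  role[is.na(role) | !role %in% c("suspected", "concomitant")] <- "suspected"
  long$role <- role
  # parse each distinct ATC cell once
  atc_levels <- unique(long$atc)
  atc_parsed <- lapply(atc_levels, parse_atc)
  long$atc_list <- atc_parsed[match(long$atc, atc_levels)]

  id_f <- factor(long$report_id, levels = unique(long$report_id))
  first <- which(!duplicated(id_f))

  reactions <- lapply(split(long$reaction, id_f), function(r) sort(unique(r)))
  ser_rows <- strsplit(tolower(ifelse(is.na(long$seriousness), "",
                                      long$seriousness)), ";", fixed = TRUE)
  seriousness <- lapply(split(ser_rows, id_f), function(s)
    sort(intersect(unique(trimws(unlist(s, use.names = FALSE))),
                   SERIOUSNESS_CRITERIA)))
  fatal_row <- parse_logical(long$fatal)
  fatal <- as.logical(tapply(fatal_row, id_f, any))

  drug_key <- paste(long$report_id, long$drug, long$role, sep = "\x1f")
  drug_first <- !duplicated(drug_key)
  drugs <- lapply(split(which(drug_first), id_f[drug_first]), function(idx) {
    tibble::new_tibble(list(ingredient = long$drug[idx],
                            atc = long$atc_list[idx],
                            role = long$role[idx]), nrow = length(idx))
  })

  records <- tibble::tibble(
    report_id = as.character(levels(id_f)),
    year = suppressWarnings(as.integer(long$year[first])),
    sex = norm_enum(long$sex[first], SEX_LEVELS),
    age_group = ifelse(trimws(as.character(long$age_group[first])) %in% AGE_GROUPS,
                       trimws(as.character(long$age_group[first])), "unknown"),
    drugs = unname(drugs),
    reactions = unname(reactions),
    seriousness = unname(seriousness),
    fatal = unname(fatal)
  )
  report_set(records, provenance = path)
}

#' Write a report set as a long-format delimited table
#'
#' The inverse of [read_reports()]: each record expands to one row per
#' (drug, reaction) pair, with multi-valued cells joined by `";"`. The
#' round-trip `read_reports(write_reports(rs))` reproduces the same logical
#' records.
#'
#' @param rs A [report_set()].
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_reports <- function(rs, path, delim = ",") {
  stopifnot(inherits(rs, "report_set"))
  rec <- rs$records
  n <- nrow(rec)
  if (n == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      as.list(rep("", length(CANONICAL_COLUMNS))), CANONICAL_COLUMNS))[0, ]
    readr::write_delim(out, path, delim = delim, na = "")
    return(invisible(path))
  }
  # one output row per (drug, reaction) pair, drugs cycling fastest
  nd <- vapply(rec$drugs, nrow, integer(1))
  nr <- lengths(rec$reactions)
  ridx <- rep.int(seq_len(n), nd * nr)
  all_drugs <- dplyr::bind_rows(rec$drugs)
  offset <- cumsum(c(0L, nd[-n]))
  drug_rows <- unlist(lapply(seq_len(n), function(i)
    offset[i] + rep.int(seq_len(nd[i]), nr[i])), use.names = FALSE)
  reaction <- unlist(lapply(seq_len(n), function(i)
    rep(rec$reactions[[i]], each = nd[i])), use.names = FALSE)
  atc_str <- vapply(all_drugs$atc, paste, character(1), collapse = ";")
  serious_str <- vapply(rec$seriousness, paste, character(1), collapse = ";")
  out <- tibble::tibble(
    report_id = rec$report_id[ridx],
    year = rec$year[ridx],
    sex = rec$sex[ridx],
    age_group = rec$age_group[ridx],
    drug = all_drugs$ingredient[drug_rows],
    atc = atc_str[drug_rows],
    role = all_drugs$role[drug_rows],
    reaction = reaction,
    seriousness = serious_str[ridx],
    fatal = rec$fatal[ridx]
  )
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

record_key <- function(rec, fields) {
  parts <- lapply(fields, function(f) {
    col <- rec[[f]]
    if (f == "drugs") {
      vapply(col, function(d) {
        d <- d[order(d$ingredient, d$role), ]
        paste(d$ingredient, vapply(d$atc, paste, character(1), collapse = ";"),
              d$role, sep = "\r", collapse = "\n")
      }, character(1))
    } else if (is.list(col)) {
      vapply(col, function(v) paste(sort(as.character(v)), collapse = "\n"),
             character(1))
    } else {
      as.character(col)
    }
  })
  do.call(paste, c(parts, sep = "\x1f"))
}

#' Remove duplicate notifications
#'
#' Keeps the first occurrence (stable order) of every record whose key fields
#' are exactly equal. The default key is every field except `report_id` —
#' without access to a record-linkage engine, exact content equality is the
#' only defensible duplicate rule, and the key is exposed so users can narrow
#' it.
#'
#' @param rs A [report_set()].
#' @param key Character vector of record fields to compare (default: all
#'   except `report_id`).
#' @return A `report_set` with `deduplicated = TRUE` and `n_removed` set to
#'   the number of records dropped.
#' @export
deduplicate <- function(rs, key = NULL) {
  stopifnot(inherits(rs, "report_set"))
  fields <- setdiff(names(rs$records), "report_id")
  if (is.null(key)) key <- fields
  key <- intersect(key, names(rs$records))
  if (length(key) == 0L) stop("deduplication key must be nonempty", call. = FALSE)
  keep <- !duplicated(record_key(rs$records, key))
  report_set(rs$records[keep, ], provenance = rs$provenance,
             deduplicated = TRUE, n_removed = sum(!keep))
}
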