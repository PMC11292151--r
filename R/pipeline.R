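#' Configure an end-to-end analysis run
#'
#' Collects every input path and decision flag for [run_akd_pipeline()]:
#' ingest -> deduplicate -> case split -> descriptive tables ->
#' disproportionality -> bibliographic-score merge.
#'
#' @param reports Path to the long-format report table (see [read_reports()]).
#' @param out_dir Output directory (created if absent).
#' @param case_definition Path to a term-list file, or `NULL` for the shipped
#'   AKD definition.
#' @param biblio_scores Optional path to a bibliographic-score file (see
#'   [read_biblio_scores()]).
#' @param schema Optional column mapping passed to [read_reports()].
#' @param role Drug-role filter, `"suspected"` or `"any"`.
#' @param min_reports Minimum drug-and-event report count for the
#'   disproportionality table.
#' @param continuity Haldane-Anscombe correction for zero cells in [ror()].
#' @param ic_method `"approx"` or `"gamma"` (see [ic()]).
#' @param top_n Rows kept in the top-ingredient tables.
#' @param seed Seed recorded in the summary (any resampling diagnostics).
#' @param verbose Print stage progress?
#' @return An object of class `run_config`.
#' @export
run_config <- function(reports, out_dir, case_definition = NULL,
                       biblio_scores = NULL, schema = NULL,
                       role = c("suspected", "any"), min_reports = 3,
                       continuity = TRUE, ic_method = c("approx", "gamma"),
                       top_n = 10, seed = 1L, verbose = TRUE) {
  structure(list(reports = reports, out_dir = out_dir,
                 case_definition = case_definition,
                 biblio_scores = biblio_scores, schema = schema,
                 role = match.arg(role), min_reports = min_reports,
                 continuity = continuity, ic_method = match.arg(ic_method),
                 top_n = top_n, seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory. The configuration round-trips: writing
#' with [write_run_config()] and re-reading yields the same configuration.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  for (k in c("reports", "out_dir", "case_definition", "biblio_scores")) {
    vals[[k]] <- resolve(vals[[k]])
  }
  if (!is.null(vals$schema)) vals$schema <- unlist(vals$schema)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!is.null(vals$schema)) vals$schema <- as.list(vals$schema)
  yaml::write_yaml(vals, path)
  invisible(path)
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv_out <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Reads reports, deduplicates, splits cases against the case definition,
#' writes every descriptive table, runs the disproportionality screen, merges
#' bibliographic scores where available, and writes a machine-readable JSON
#' summary recording every count, denominator and decision flag used. Outputs
#' are deterministic for fixed inputs and configuration.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with the `report_set`s, every table, the
#'   disproportionality results, and the summary (also written to
#'   `summary.json` in the output directory).
#' @export
run_akd_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  rs <- stage("ingest", v, read_reports(config$reports, schema = config$schema))
  rs <- stage("deduplicate", v, deduplicate(rs))
  cd <- stage("case_definition", v, {
    if (is.null(config$case_definition)) akd_case_definition()
    else read_case_definition(config$case_definition)
  })
  parts <- stage("case_split", v, split_cases(rs, cd))
  cases <- parts$cases
  n_cases <- n_reports(cases)

  desc <- stage("descriptive_tables", v, {
    list(terms = term_freq(cases, cd),
         atc = atc_freq(cases, config$role),
         ingredients = ingredient_freq(cases, top_n = config$top_n,
                                       role = config$role),
         demographics = demographics(cases),
         seriousness = seriousness_table(cases),
         fatal = fatal_breakdowns(cases, config$role))
  })

  # comparator population = every report in the supplied set
  dispro <- stage("disproportionality", v,
    run_disproportionality(rs, cd, min_reports = config$min_reports,
                           role = config$role, continuity = config$continuity,
                           ic_method = config$ic_method))

  bs <- NULL
  if (!is.null(config$biblio_scores)) {
    bs <- stage("biblio_scores", v, read_biblio_scores(config$biblio_scores))
    dispro <- dplyr::left_join(dispro, bs, by = "ingredient")
  }

  files <- stage("write_outputs", v, {
    c(write_tsv_out(desc$terms$main, config$out_dir, "terms_main"),
      write_tsv_out(desc$terms$concomitant, config$out_dir, "terms_concomitant"),
      write_tsv_out(desc$atc, config$out_dir, "atc_classes"),
      write_tsv_out(desc$ingredients, config$out_dir, "top_ingredients"),
      write_tsv_out(desc$demographics$sex, config$out_dir, "sex"),
      write_tsv_out(desc$demographics$age_group, config$out_dir, "age_groups"),
      write_tsv_out(desc$seriousness$criteria, config$out_dir, "seriousness"),
      write_tsv_out(desc$fatal$atc, config$out_dir, "fatal_atc_classes"),
      write_tsv_out(desc$fatal$ingredients, config$out_dir, "fatal_ingredients"),
      write_tsv_out(dispro, config$out_dir, "signal_table"))
  })

  summary <- list(
    n_input = n_reports(rs) + rs$n_removed,
    n_duplicates_removed = rs$n_removed,
    n_reports = n_reports(rs),
    case_definition = cd$name,
    n_case_terms = length(cd$terms),
    n_cases = n_cases,
    n_noncases = n_reports(parts$noncases),
    n_serious = desc$seriousness$n_serious,
    serious_pct = desc$seriousness$serious_pct,
    n_fatal = desc$fatal$n_fatal,
    fatal_pct = desc$fatal$fatal_pct,
    n_drugs_tested = nrow(dispro),
    n_screened_in = sum(dispro$screened_in),
    role_filter = config$role,
    min_reports = config$min_reports,
    continuity = config$continuity,
    ic_method = config$ic_method,
    seed = config$seed,
    class_proportions = if (!is.null(bs) && nrow(bs) > 0L)
      class_proportions(bs) else NULL,
    outputs = basename(files)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (v) message("[done] ", n_cases, " cases, ", nrow(dispro),
                 " drugs tested, ", sum(dispro$screened_in), " screened in")
  invisible(list(reports = rs, cases = cases, noncases = parts$noncases,
                 case_definition = cd, descriptives = desc, dispro = dispro,
                 biblio = bs, summary = summary))
}
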