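test_that("ingredient normalization trims, folds case and orders combinations", {
  expect_equal(normalize_ingredient("  Omeprazole "), "omeprazole")
  expect_equal(normalize_ingredient("tenofovir disoproxil + emtricitabine"),
               "emtricitabine + tenofovir disoproxil")
  expect_equal(normalize_ingredient("Efavirenz+ Emtricitabine +tenofovir  disoproxil"),
               "efavirenz + emtricitabine + tenofovir disoproxil")
  expect_error(normalize_ingredient("   "), "empty")
  expect_error(normalize_ingredient(" + "), "empty")
})

test_that("normalization is idempotent and component-order invariant", {
  set.seed(11)
  comps <- c("abacavir", "Tenofovir Disoproxil", "EMTRICITABINE", "x 1",
             "zidovudine", "lamivudine")
  for (i in 1:50) {
    k <- sample(1:4, 1)
    raw <- paste(sample(comps, k), collapse = sample(c("+", " + ", " +"), 1))
    once <- normalize_ingredient(raw)
    expect_identical(normalize_ingredient(once), once)
    perm <- paste(sample(strsplit(once, " + ", fixed = TRUE)[[1]]),
                  collapse = "+")
    expect_identical(normalize_ingredient(perm), once)
  }
})

test_that("notification validates its invariants", {
  d <- drug_entry("omeprazole", "A")
  expect_error(notification("r1", d[0, ], "nausea"), "at least one drug")
  expect_error(notification("r1", d, character(0)), "at least one reaction")
  expect_error(notification("r1", d, "nausea", seriousness = "bogus"),
               "seriousness")
  r <- notification("r1", d, "nausea", sex = "Banana", age_group = "99-100")
  expect_equal(r$sex, "unknown")
  expect_equal(r$age_group, "unknown")
  # fatal flag is independent of the death seriousness criterion (lenient)
  r2 <- notification("r2", d, "nausea", fatal = TRUE)
  expect_true(r2$fatal)
  expect_length(r2$seriousness[[1]], 0)
})

test_that("report_set rejects duplicate ids and counts records", {
  d <- drug_entry("omeprazole", "A")
  expect_error(report_set(list(rec("a", d, "nausea"), rec("a", d, "rash"))),
               "duplicate report_id")
  rs <- report_set(list(rec("a", d, "nausea"), rec("b", d, "rash")))
  expect_equal(n_reports(rs), 2L)
})

test_that("reading aggregates long-format rows by report id", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "report_id,year,sex,age_group,drug,atc,role,reaction,seriousness,fatal",
    "r1,2020,male,45-64,Omeprazole,A,suspected,Acute kidney injury,hospitalization,false",
    "r1,2020,male,45-64,Furosemide,C,suspected,Oliguria,hospitalization,false",
    "r2,2019,female,>=75,tenofovir disoproxil,J,suspected,Acute kidney injury,death;hospitalization,true"
  ), path)
  rs <- read_reports(path)
  expect_equal(n_reports(rs), 2L)
  r1 <- rs$records[rs$records$report_id == "r1", ]
  expect_setequal(r1$drugs[[1]]$ingredient, c("omeprazole", "furosemide"))
  expect_setequal(r1$reactions[[1]], c("Acute kidney injury", "Oliguria"))
  r2 <- rs$records[rs$records$report_id == "r2", ]
  expect_equal(r2$drugs[[1]]$ingredient, "tenofovir disoproxil")
  expect_setequal(r2$seriousness[[1]], c("death", "hospitalization"))
  expect_true(r2$fatal)
})

test_that("schema mapping renames columns and flags missing mandatory ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,Medicine,PT", "x1,Vancomycin,Renal failure"), path)
  rs <- read_reports(path, schema = c(report_id = "ID", drug = "Medicine",
                                      reaction = "PT"))
  expect_equal(n_reports(rs), 1L)
  expect_equal(rs$records$drugs[[1]]$ingredient, "vancomycin")
  expect_error(read_reports(path, schema = c(report_id = "ID", drug = "Medicine")),
               "schema error")
  expect_error(read_reports(path), "schema error")
})

test_that("an empty file yields an empty set with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("report_id,drug,reaction", path)
  expect_warning(rs <- read_reports(path), "empty")
  expect_equal(n_reports(rs), 0L)
})

test_that("write/read round-trip preserves logical content", {
  rs <- random_report_set(40, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reports(rs, path)
  back <- read_reports(path)
  expect_equal(n_reports(back), n_reports(rs))
  ord <- match(rs$records$report_id, back$records$report_id)
  expect_false(anyNA(ord))
  for (i in seq_len(n_reports(rs))) {
    orig <- rs$records[i, ]
    got <- back$records[ord[i], ]
    expect_equal(got$year, orig$year)
    expect_equal(got$sex, orig$sex)
    expect_equal(got$age_group, orig$age_group)
    expect_setequal(got$reactions[[1]], orig$reactions[[1]])
    expect_setequal(got$seriousness[[1]], orig$seriousness[[1]])
    expect_equal(got$fatal, orig$fatal)
    od <- orig$drugs[[1]][order(orig$drugs[[1]]$ingredient, orig$drugs[[1]]$role), ]
    gd <- got$drugs[[1]][order(got$drugs[[1]]$ingredient, got$drugs[[1]]$role), ]
    expect_equal(gd$ingredient, od$ingredient)
    expect_equal(gd$role, od$role)
    expect_equal(lapply(gd$atc, sort), lapply(od$atc, sort))
  }
  # empty set -> header-only file that reads back empty
  empty_path <- withr::local_tempfile(fileext = ".csv")
  write_reports(report_set(), empty_path)
  expect_length(readLines(empty_path), 1L)
})

test_that("deduplication removes exactly the planted duplicates, stably", {
  rs <- random_report_set(30, seed = 3)
  # plant k duplicates: copies of existing records under fresh ids
  k <- 7
  set.seed(4)
  dup_rows <- rs$records[sample(30, k, replace = TRUE), ]
  dup_rows$report_id <- sprintf("DUP%02d", seq_len(k))
  withdup <- report_set(dplyr::bind_rows(rs$records, dup_rows))

  # brute-force pairwise duplicate count (first occurrence kept)
  fields <- setdiff(names(withdup$records), "report_id")
  n <- n_reports(withdup)
  is_dup <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      same <- TRUE
      for (f in fields) {
        vi <- withdup$records[[f]][[i]]; vj <- withdup$records[[f]][[j]]
        eq <- if (f == "drugs") {
          isTRUE(all.equal(vi[order(vi$ingredient, vi$role), ],
                           vj[order(vj$ingredient, vj$role), ],
                           check.attributes = FALSE))
        } else if (is.list(withdup$records[[f]])) {
          setequal(vi, vj) && length(vi) == length(vj)
        } else {
          identical(vi, vj)
        }
        if (!eq) { same <- FALSE; break }
      }
      if (same) { is_dup[i] <- TRUE; break }
    }
  }

  out <- deduplicate(withdup)
  expect_equal(out$n_removed, sum(is_dup))
  expect_gte(out$n_removed, k)  # at least the planted copies go
  expect_equal(n_reports(out) + out$n_removed, n)
  expect_identical(out$records$report_id,
                   withdup$records$report_id[!is_dup])
  # idempotence
  again <- deduplicate(out)
  expect_equal(again$n_removed, 0L)
  expect_identical(again$records, out$records)
})

test_that("deduplicating a duplicate-free set is the identity", {
  d1 <- drug_entry("omeprazole", "A")
  d2 <- drug_entry("furosemide", "C")
  rs <- report_set(list(rec("a", d1, "nausea"), rec("b", d2, "rash")))
  out <- deduplicate(rs)
  expect_equal(out$n_removed, 0L)
  expect_identical(out$records, rs$records)
  # two byte-identical records (apart from id) -> one survives
  rs2 <- report_set(list(rec("a", d1, "nausea"), rec("b", d1, "nausea")))
  out2 <- deduplicate(rs2)
  expect_equal(out2$n_removed, 1L)
  expect_equal(out2$records$report_id, "a")
})
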