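cd_akd <- akd_case_definition()

test_that("contingency cells count whole reports, one per cell on a handcrafted set", {
  d_drug <- drug_entry("vancomycin", "J")
  d_other <- drug_entry("paracetamol", "N")
  rs <- report_set(list(
    rec("a", d_drug, "Acute kidney injury"),   # drug + event
    rec("b", d_drug, "Nausea"),                # drug only
    rec("c", d_other, "Renal failure"),        # event only
    rec("d", d_other, "Headache")              # neither
  ))
  t <- build_table(rs, "Vancomycin", cd_akd)
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  expect_equal(t$N, 4)
  expect_equal(t$n_drug, 2)
  expect_equal(t$n_event, 2)
})

test_that("a drug listed twice on one report counts once", {
  dd <- dplyr::bind_rows(drug_entry("vancomycin", "J"),
                         drug_entry("Vancomycin ", "J"))
  rs <- report_set(list(rec("a", dd, "Anuria"),
                        rec("b", drug_entry("ibuprofen", "M"), "Rash")))
  t <- build_table(rs, "vancomycin", cd_akd)
  expect_equal(t$a, 1)
  expect_equal(t$n_drug, 1)
})

test_that("role filter: concomitant entries count only under role='any'", {
  dd <- drug_entry("vancomycin", "J", role = "concomitant")
  rs <- report_set(list(rec("a", dd, "Anuria"),
                        rec("b", drug_entry("ibuprofen", "M"), "Rash")))
  t_susp <- build_table(rs, "vancomycin", cd_akd, role = "suspected")
  expect_equal(t_susp$n_drug, 0)  # absent ingredient: a = b = 0, still valid
  t_any <- build_table(rs, "vancomycin", cd_akd, role = "any")
  expect_equal(t_any$a, 1)
})

test_that("cells match a brute-force double loop on random report sets", {
  for (seed in c(101, 202, 303)) {
    rs <- random_report_set(150, seed = seed)
    for (ingredient in c("drug1", "drug3", "drug6")) {
      for (role in c("suspected", "any")) {
        t <- build_table(rs, ingredient, cd_akd, role = role)
        o <- oracle_table(rs, ingredient, cd_akd, role = role)
        expect_equal(c(t$a, t$b, t$c, t$d), unname(o))
      }
    }
  }
})

test_that("ROR point estimate and Woolf interval follow the stated formulas", {
  # symmetric table: ROR exactly 1, interval straddles 1
  t1 <- contingency_table(10, 10, 10, 10)
  r1 <- ror(t1)
  expect_equal(r1$ror, 1)
  expect_lt(r1$ci_low, 1)
  expect_gt(r1$ci_high, 1)

  # hand computation via the stated formulas: a=10 b=90 c=100 d=9900
  # ROR = 10*9900/(90*100) = 11; CI = exp(log(11) -+ qnorm(0.975)*se)
  t2 <- contingency_table(10, 90, 100, 9900)
  r2 <- ror(t2)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r2$ror, 11)
  expect_equal(r2$ci_low, exp(log(11) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r2$ci_high, exp(log(11) + qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r2$ci_low, 5.56, tolerance = 1e-3)
  expect_equal(r2$ci_high, 21.77, tolerance = 1e-3)
})

test_that("zero cells: Haldane correction on all four cells, or an error", {
  t <- contingency_table(0, 10, 20, 1000)
  r <- ror(t)
  o <- oracle_ror(0, 10, 20, 1000)
  expect_equal(r$ror, unname(o["ror"]))
  expect_equal(r$ci_low, unname(o["lo"]))
  expect_error(ror(t, continuity = FALSE), "zero cell")
})

test_that("IC follows the shrunken log2 observed/expected formula", {
  # a equals E exactly -> IC = 0
  t0 <- contingency_table(10, 90, 90, 810)  # E = 100*100/1000 = 10
  expect_equal(ic(t0)$ic, 0)

  # frozen hand computation: N=2000, n_drug=100, n_event=200, a=40 -> E=10
  t1 <- contingency_table(40, 60, 160, 1740)
  i1 <- ic(t1)
  expect_equal(i1$expected, 10)
  expect_equal(i1$ic, log2(40.5 / 10.5))
  expect_equal(i1$ic, 1.9475, tolerance = 1e-4)
  expect_equal(i1$ic025, i1$ic - 3.3 / sqrt(40.5) - 2 / 40.5^1.5,
               tolerance = 1e-12)
  expect_equal(i1$ic025, 1.4212, tolerance = 1e-4)

  # observed deficit -> negative IC
  t2 <- contingency_table(0, 100, 500, 5000)
  expect_lt(ic(t2)$ic, 0)

  # zero margin is undefined
  expect_error(ic(contingency_table(0, 0, 5, 5)), "positive")
})

test_that("approximate and exact-gamma IC025 stay within 0.05 of each other", {
  # the deviation between the closed-form credibility bound and the exact
  # gamma quantile depends only on the observed count; it peaks near a = 20
  # at just under 0.05 log2 units and shrinks very slowly with a
  set.seed(5)
  for (i in 1:25) {
    a <- sample(3:2000, 1)
    e <- runif(1, 0.5, 200)
    t <- structure(list(a = a, b = 10, c = 10, d = 10,
                        N = 1000, n_drug = 100, n_event = 10 * e,
                        ingredient = NULL), class = "contingency_table")
    i_app <- ic(t, method = "approx")
    i_gam <- ic(t, method = "gamma")
    expect_equal(i_app$ic, i_gam$ic)
    expect_lt(abs(i_app$ic025 - i_gam$ic025), 0.05)
    expect_lte(i_gam$ic025, i_gam$ic)
    expect_lte(i_app$ic025, i_app$ic)
  }
})

test_that("IC antisymmetry: swapping observed and expected flips the sign", {
  # when the 0.5-shrunken numerator and denominator swap, IC negates
  t_fwd <- contingency_table(40, 60, 160, 1740)   # a=40, E=10
  t_rev <- contingency_table(10, 90, 790, 1110)   # a=10, E=100*800/2000=40
  expect_equal(ic(t_fwd)$expected, 10)
  expect_equal(ic(t_rev)$expected, 40)
  expect_equal(ic(t_fwd)$ic, -ic(t_rev)$ic)
})

test_that("ror and ic equal hand-formula recomputation on random small sets", {
  for (seed in 401:404) {
    rs <- random_report_set(180, seed = seed)
    res <- run_disproportionality(rs, cd_akd, min_reports = 1)
    n <- n_reports(rs)
    for (i in seq_len(nrow(res))) {
      o <- oracle_table(rs, res$ingredient[i], cd_akd, role = "suspected")
      expect_equal(c(res$a[i], res$b[i], res$c[i], res$d[i]), unname(o))
      orr <- oracle_ror(o["a"], o["b"], o["c"], o["d"])
      expect_equal(res$ror[i], unname(orr["ror"]), tolerance = 1e-12)
      expect_equal(res$ror_ci_low[i], unname(orr["lo"]), tolerance = 1e-12)
      expect_equal(res$ror_ci_high[i], unname(orr["hi"]), tolerance = 1e-12)
      oic <- oracle_ic(o["a"], o["a"] + o["b"], o["a"] + o["c"], n)
      expect_equal(res$ic[i], unname(oic["ic"]), tolerance = 1e-12)
      expect_equal(res$ic025[i], unname(oic["ic025"]), tolerance = 1e-12)
    }
  }
})

test_that("the screen gates on IC025 > 0 strictly, confirmed by ROR > 1", {
  res <- tibble::tibble(
    ingredient = c("stribild-like", "covid-vaccine-like", "boundary", "ror-fail"),
    ic025 = c(8.7, -2.0, 0, 2.0),
    ror = c(786.96, 0.24, 5, 0.9))
  out <- screen(res)
  expect_equal(out$screened_in, c(TRUE, FALSE, FALSE, FALSE))
  # gated-out rows are retained, not dropped
  expect_equal(nrow(out), 4)
})

test_that("ranking is by IC025 then ROR then name, and deterministic", {
  rs <- random_report_set(150, seed = 55)
  r1 <- run_disproportionality(rs, cd_akd, min_reports = 1)
  r2 <- run_disproportionality(rs, cd_akd, min_reports = 1)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$ic025) <= 0))
  # min_reports floor drops small-a drugs
  r3 <- run_disproportionality(rs, cd_akd, min_reports = 10)
  expect_true(all(r3$a >= 10))
  expect_true(all(r3$ingredient %in% r1$ingredient))
})

test_that("single-drug set yields a single result row", {
  rs <- report_set(list(
    rec("a", drug_entry("colistin", "J"), "Blood creatinine increased"),
    rec("b", drug_entry("colistin", "J"), "Acute kidney injury"),
    rec("c", drug_entry("colistin", "J"), "Anuria"),
    rec("d", drug_entry("colistin", "J"), "Nausea")))
  res <- run_disproportionality(rs, cd_akd)
  expect_equal(nrow(res), 1)
  expect_equal(res$ingredient, "colistin")
})

test_that("ROR interval narrows as all cells scale up", {
  widths <- vapply(c(1, 2, 5, 10, 50), function(k) {
    r <- ror(contingency_table(8 * k, 92 * k, 50 * k, 850 * k))
    log(r$ci_high) - log(r$ci_low)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
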