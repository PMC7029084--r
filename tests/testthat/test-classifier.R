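mk_t1 <- function(pass_c1 = TRUE, unimodal = TRUE, coverage = 99,
                  lenient = FALSE) {
  marginal <- coverage > 94 && coverage < 95
  cov_ok <- coverage >= 95 || (lenient && marginal)
  structure(list(trait = "tr",
                 variance_ratio = list(pass_c1 = pass_c1, insufficient = FALSE),
                 dip = NULL, coverage = coverage,
                 pass_unimodal = unimodal, pass_coverage = coverage >= 95,
                 marginal_coverage = marginal,
                 verdict_type1 = isTRUE(pass_c1) && isTRUE(unimodal) && cov_ok,
                 lenient = lenient, insufficient = FALSE),
            class = "type1_result")
}
mk_t2 <- function(r2 = TRUE, ols = TRUE, pgls = TRUE) {
  verdict <- if (is.na(pgls)) NA else isTRUE(r2) && isTRUE(ols) && isTRUE(pgls)
  structure(list(pass_r2 = r2, pass_ols_slope = ols, pass_pgls_slope = pgls,
                 verdict_type2 = verdict, degraded = FALSE),
            class = "type2_verdict")
}

test_that("all-pass yields type I+II; any failure breaks the conjunction", {
  row <- classify_trait(mk_t1(), mk_t2())
  expect_true(row$type_I); expect_true(row$type_II); expect_true(row$type_I_II)
  expect_equal(unname(row$marks), rep("pass", 6))
  row2 <- classify_trait(mk_t1(pass_c1 = FALSE), mk_t2())
  expect_false(row2$type_I); expect_false(row2$type_I_II)
  expect_true(row2$type_II)
  row3 <- classify_trait(mk_t1(FALSE, FALSE, 60), mk_t2(FALSE, FALSE, FALSE))
  expect_false(row3$type_I); expect_false(row3$type_II); expect_false(row3$type_I_II)
})

test_that("marginal coverage counts only under the lenient flag", {
  strict <- classify_trait(mk_t1(coverage = 94.5, lenient = FALSE), mk_t2())
  expect_equal(unname(strict$marks[["coverage"]]), "marginal")
  expect_false(strict$type_I)
  lenient <- classify_trait(mk_t1(coverage = 94.5, lenient = TRUE), mk_t2())
  expect_true(lenient$type_I)
})

test_that("unavailable components propagate to the verdicts", {
  row <- classify_trait(mk_t1(), mk_t2(pgls = NA))
  expect_equal(unname(row$marks[["pgls_slope"]]), "not_available")
  expect_true(is.na(row$type_II))
  expect_true(is.na(row$type_I_II))
  row2 <- classify_trait(NULL, mk_t2())
  expect_true(is.na(row2$type_I))
})

test_that("flipping any component from fail to pass never demotes a verdict", {
  combos <- expand.grid(c1 = c(TRUE, FALSE), uni = c(TRUE, FALSE),
                        cov = c(99, 80), r2 = c(TRUE, FALSE),
                        ols = c(TRUE, FALSE), pgls = c(TRUE, FALSE))
  verdict_of <- function(co) {
    r <- classify_trait(mk_t1(co$c1, co$uni, co$cov),
                        mk_t2(co$r2, co$ols, co$pgls))
    c(r$type_I, r$type_II, r$type_I_II)
  }
  for (i in seq_len(nrow(combos))) {
    base <- combos[i, ]
    v0 <- verdict_of(base)
    for (f in names(combos)) {
      up <- base
      up[[f]] <- if (f == "cov") 99 else TRUE
      v1 <- verdict_of(up)
      expect_true(all(v1 >= v0))
    }
  }
})

test_that("reports render deterministically in configuration order", {
  rows <- list(classify_trait(mk_t1(), mk_t2()),
               classify_trait(mk_t1(FALSE), mk_t2(), trait = "other"))
  rows[[2]]$trait <- "other"
  rep1 <- build_report(rows, "G")
  g1 <- report_grid(rep1)
  g2 <- report_grid(build_report(rows, "G"))
  expect_identical(g1, g2)
  expect_equal(colnames(g1), c("tr", "other"))
  expect_equal(unname(g1["Type I+II", ]), c("yes", "no"))
  # unavailable cells render as an en dash
  row_na <- classify_trait(mk_t1(), mk_t2(pgls = NA), trait = "na_tr")
  g3 <- report_grid(build_report(list(row_na), "G"))
  expect_equal(unname(g3["Slope PGLS", 1]), "–")
  expect_equal(unname(g3["Type I+II", 1]), "–")
})
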