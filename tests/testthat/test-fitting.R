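# Chi-square statistics, the internal-consistency report and the grid search.

test_that("chi_square_percent reproduces the published consistency statistics", {
  # reference pure-B: expected (65.4, -, 28.6) vs observed (14, -, 80)
  res_B <- chi_square_percent(c(14, 6, 80), c(65.381, 6, 28.619),
                              include = c(TRUE, FALSE, TRUE))
  expect_equal(res_B$chi2, 132.6, tolerance = 5e-3)
  expect_equal(res_B$df, 1)

  # reference pure-A: the tiny expected pure-B percentage dominates
  res_A <- chi_square_percent(c(14, 6, 80), c(14, 2.2221e-4, 86.0),
                              include = c(FALSE, TRUE, TRUE))
  expect_equal(res_A$chi2, 1.62e5, tolerance = 5e-3)

  # exact data give zero; additivity; masking invariance
  expect_equal(chi_square_percent(c(14, 6, 80), c(14, 6, 80))$chi2, 0)
  expect_equal(res_B$chi2, sum(res_B$contributions))
  with_mask <- chi_square_percent(c(14, 6, 80), c(65.381, 6, 28.619),
                                  include = c(TRUE, TRUE, TRUE))
  expect_equal(with_mask$chi2, res_B$chi2)  # fitted category contributes 0

  expect_error(chi_square_percent(c(14, 6, 80), c(65, 0, 35)), "positive")
  expect_error(chi_square_percent(c(14, 6), c(65, 35, 0)), "same length")
})

test_that("table1_consistency_report reproduces both references", {
  rep <- table1_consistency_report(paper_data())

  expect_equal(rep$ref_A$n, 8.3408, tolerance = 1e-4)
  expect_equal(rep$ref_A$expected_pct[["B"]], 2.2e-4, tolerance = 0.01)
  expect_equal(rep$ref_A$expected_pct[["Mix"]], 86.0, tolerance = 1e-4)
  expect_equal(rep$ref_A$chi2$chi2, 161996, tolerance = 5e-3)

  expect_equal(rep$ref_B$n, 1.8027, tolerance = 1e-4)
  expect_equal(rep$ref_B$expected_pct[["A"]], 65.4, tolerance = 1e-3)
  expect_equal(rep$ref_B$expected_pct[["Mix"]], 28.6, tolerance = 1e-3)
  expect_equal(rep$ref_B$chi2$chi2, 132.6, tolerance = 5e-3)

  # both wildly exceed the 1-df critical value 10.827: basic model rejected
  expect_true(rep$ref_A$chi2$significant)
  expect_true(rep$ref_B$chi2$significant)
  expect_equal(rep$ref_A$chi2$critical, 10.827)

  # data generated exactly from the basic model are self-consistent
  tr <- basic_expected_fractions(4, chimera_mix(0.3))
  synth <- observed_section_data(tr$f_A, tr$f_B, tr$f_mix, p = 0.3)
  rep2 <- table1_consistency_report(synth)
  expect_equal(rep2$ref_A$chi2$chi2, 0, tolerance = 1e-10)
  expect_equal(rep2$ref_B$chi2$chi2, 0, tolerance = 1e-10)
})

test_that("observed_section_data accepts both scales and validates sums", {
  d_pct <- observed_section_data(14, 6, 80, p = 0.21)
  d_frac <- observed_section_data(0.14, 0.06, 0.80, p = 0.21)
  expect_equal(d_pct$pct, d_frac$pct)
  expect_error(observed_section_data(14, 6, 70, p = 0.21), "sum to")
  expect_error(observed_section_data(14, -6, 92, p = 0.21), "non-negative")
})

test_that("chi2_at_point matches a manual recomputation and the zero case", {
  data <- paper_data()
  geom <- paper_geom()
  res <- chi2_at_point(19, 10, 62, data, geom)
  # manual path through poisson_fractions with cell-valued thresholds
  tr <- poisson_fractions(19, data$mix, geom,
                          scoring_thresholds(l_TA = 124, l_TB = 20))
  manual <- sum((data$pct - 100 * as.numeric(tr))^2 / (100 * as.numeric(tr)))
  expect_equal(res$chi2, manual, tolerance = 1e-12)
  expect_equal(res$df, 2)

  # observed equal to the model prediction gives chi2 = 0
  pred <- 100 * as.numeric(tr)
  d0 <- observed_section_data(pred[1], pred[2], pred[3] + (100 - sum(pred)),
                              p = 0.21)
  expect_lt(chi2_at_point(19, 10, 62, d0, geom)$chi2, 1e-6)
})

test_that("grid_search recovers exact model-generated data and is self-consistent", {
  # synthetic truth on the grid; small geometry keeps this fast
  mix <- chimera_mix(0.21)
  geom <- section_geometry(500, 50)
  truth <- list(lambda = 20, l_TB_pct = 11, l_TA_pct = 63)
  th <- scoring_thresholds(
    l_TA = gcfounders:::pct_to_cells(truth$l_TA_pct, geom$m),
    l_TB = gcfounders:::pct_to_cells(truth$l_TB_pct, geom$m))
  tr <- poisson_fractions(truth$lambda, mix, geom, th)
  v <- as.numeric(tr) / sum(as.numeric(tr))  # renormalize the tiny n=0 mass
  data <- observed_section_data(v[1], v[2], v[3], p = 0.21)

  gs <- grid_search(data, geom, lambda_range = 15:25,
                    l_TB_pct_range = 10:12, l_TA_pct_range = 60:65)
  expect_equal(gs$global_min$lambda, truth$lambda)
  expect_equal(gs$global_min$l_TB_pct, truth$l_TB_pct)
  expect_equal(gs$global_min$l_TA_pct, truth$l_TA_pct)
  expect_lt(gs$global_min$chi2, 1e-10)

  # every reported local minimum lies on the grid; global <= all values
  expect_true(all(gs$local_minima$lambda %in% 15:25))
  expect_lte(gs$global_min$chi2, min(gs$surface$chi2, na.rm = TRUE))

  # surface rows equal chi2_at_point re-evaluated independently
  idx <- c(1, 17, nrow(gs$surface))
  for (i in idx) {
    row <- gs$surface[i, ]
    expect_equal(row$chi2,
                 chi2_at_point(row$lambda, row$l_TB_pct, row$l_TA_pct,
                               data, geom)$chi2,
                 tolerance = 1e-9)
  }

  # single-point grid
  gs1 <- grid_search(data, geom, lambda_range = 20,
                     l_TB_pct_range = 11, l_TA_pct_range = 63)
  expect_equal(nrow(gs1$surface), 1L)
  expect_equal(gs1$global_min$lambda, 20)

  expect_error(grid_search(data, geom, lambda_range = integer(0)),
               "empty grid")
})

test_that("degenerate threshold grid points are skipped with a warning", {
  data <- paper_data()
  geom <- section_geometry(100, 10)  # 10-cell sections: 60% + 50% >= m
  expect_warning(
    gs <- grid_search(data, geom, lambda_range = 2:3,
                      l_TB_pct_range = c(10, 60), l_TA_pct_range = c(20, 50)),
    "skipped")
  expect_equal(gs$n_skipped, 2L)
  expect_true(all(is.finite(gs$global_min$chi2)))
})
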