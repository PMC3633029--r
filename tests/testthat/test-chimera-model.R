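# Unit and property tests for the analytic chimera model.

test_that("basic model fractions and inversion match closed forms", {
  mix <- chimera_mix(0.21)

  # single founder is always pure; symmetric two-founder case
  tr1 <- basic_expected_fractions(1, mix)
  expect_equal(tr1$f_A, 0.79)
  expect_equal(tr1$f_B, 0.21)
  expect_equal(tr1$f_mix, 0)
  tr2 <- basic_expected_fractions(2, chimera_mix(0.5))
  expect_equal(as.numeric(tr2), c(f_A = 0.25, f_B = 0.25, f_Mix = 0.5))

  # worked inversion: observed pure fractions 0.14 / 0.06 at p = 0.21
  n_A <- invert_founders(0.14, 0.79)
  n_B <- invert_founders(0.06, 0.21)
  expect_equal(n_A, 8.34, tolerance = 1e-3)
  expect_equal(n_B, 1.80, tolerance = 1e-2)
  expect_equal(round(n_A), 8)
  expect_equal(round(n_B), 2)
  expect_equal(invert_founders(0.3, 0.3), 1)

  # expected percentages at the inverted founder numbers
  expect_equal(100 * basic_expected_fractions(n_B, mix)$f_A, 65.4,
               tolerance = 0.0008)
  expect_equal(100 * (1 - 0.06 - basic_expected_fractions(n_B, mix)$f_A),
               28.6, tolerance = 0.002)
  expect_equal(100 * (1 - 0.14 - basic_expected_fractions(n_A, mix)$f_B),
               86.0, tolerance = 1e-4)

  expect_error(basic_expected_fractions(0, mix), "positive")
  expect_error(invert_founders(1, 0.79), "strictly inside")
  expect_error(invert_founders(0.14, 0), "strictly inside")
  expect_error(chimera_mix(1.2), "\\[0, 1\\]")
})

test_that("pure-section probabilities match trivial closed forms", {
  mix <- chimera_mix(0.21)
  geom <- section_geometry(10, 4)
  th <- scoring_thresholds(l_TA = 1, l_TB = 1)

  # k = 0: truly pure-A GC always yields a pure-A section
  for (n in 1:4) {
    expect_equal(pure_A_section_prob(n, 0, mix, geom, th), 0.79^n)
    expect_equal(pure_B_section_prob(n, n, mix, geom, th), 0.21^n)
  }

  # whole-GC section with zero threshold can never look pure
  whole <- section_geometry(10, 10)
  th0 <- scoring_thresholds(l_TA = 0, l_TB = 0)
  expect_equal(pure_A_section_prob(2, 1, mix, whole, th0), 0)
  expect_equal(pure_B_section_prob(2, 1, mix, whole, th0), 0)

  expect_error(pure_A_section_prob(2, 3, mix, geom, th), "\\[0, n\\]")
  expect_error(
    fixed_n_fractions(2, mix, geom, scoring_thresholds(l_TA = 2, l_TB = 2)),
    "degenerate")
})

test_that("P_A / P_B / fixed-n fractions equal exhaustive enumeration", {
  # frozen worked value: M=10, m=4, n=2, k=1, p=0.21, threshold 1
  mix <- chimera_mix(0.21)
  geom <- section_geometry(10, 4)
  th <- scoring_thresholds(l_TA = 1, l_TB = 1)
  pa <- pure_A_section_prob(2, 1, mix, geom, th)
  expect_equal(pa, 0.3318 * 55 / 210)        # binomial weight x 55/210
  expect_equal(pa, 0.0869, tolerance = 1e-4)
  expect_equal(pure_B_section_prob(2, 1, mix, geom, th), pa)  # r = s = 5

  tr <- fixed_n_fractions(2, mix, geom, th)
  expect_equal(tr$f_A, 0.79^2 + pa)
  expect_equal(tr$f_A, 0.71100, tolerance = 1e-5)
  expect_equal(tr$f_B, 0.13100, tolerance = 1e-5)
  expect_equal(tr$f_mix, 0.15800, tolerance = 1e-5)

  # systematic oracle-equivalence sweep at M <= 12
  configs <- expand.grid(M = c(8, 12), m = c(3, 6), n = c(1, 3, 4),
                         l = 0:2, p = c(0.21, 0.5))
  configs <- configs[2 * configs$l < configs$m, ]  # keep thresholds valid
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    geom_i <- section_geometry(cf$M, cf$m)
    th_i <- scoring_thresholds(l_TA = cf$l, l_TB = cf$l)
    mix_i <- chimera_mix(cf$p)
    for (k in 0:cf$n) {
      expect_equal(pure_A_section_prob(cf$n, k, mix_i, geom_i, th_i),
                   oracle_pure_A(cf$n, k, cf$p, cf$M, cf$m, cf$l),
                   tolerance = 1e-12)
      expect_equal(pure_B_section_prob(cf$n, k, mix_i, geom_i, th_i),
                   oracle_pure_B(cf$n, k, cf$p, cf$M, cf$m, cf$l),
                   tolerance = 1e-12)
    }
    tr_i <- fixed_n_fractions(cf$n, mix_i, geom_i, th_i)
    expect_equal(as.numeric(tr_i),
                 oracle_fixed_n(cf$n, cf$p, cf$M, cf$m, cf$l, cf$l),
                 tolerance = 1e-12)
  }
})

test_that("the log-space hypergeometric sum agrees with stats::phyper", {
  # third route, independent of both the package sum and the enumeration
  for (M in c(50, 5000)) {
    m <- M / 10
    for (r in c(0, 1, M / 5, M / 2)) {
      for (l in c(0, 5, 20)) {
        expect_equal(
          gcfounders:::hyper_at_most(l, r, M, m),
          stats::phyper(l, r, M - r, m),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("extended model reduces to the basic model without sampling error", {
  th0 <- scoring_thresholds(0, 0)
  for (p in c(0.1, 0.21, 0.5)) {
    mix <- chimera_mix(p)
    for (n in 1:10) {
      geom <- section_geometry(40, 40)  # m = M: the section is the GC
      basic <- basic_expected_fractions(n, mix)
      ext <- fixed_n_fractions(n, mix, geom, th0)
      expect_equal(as.numeric(ext), as.numeric(basic), tolerance = 1e-12)
    }
  }
})

test_that("fixed-n triple normalizes to 1 and Poisson triple to 1 - exp(-lambda)", {
  mix <- chimera_mix(0.21)
  geom <- section_geometry(60, 20)
  th <- scoring_thresholds(l_TA = 5, l_TB = 2)
  for (n in c(1, 2, 7, 20)) {
    tr <- fixed_n_fractions(n, mix, geom, th)
    expect_equal(tr$f_A + tr$f_B + tr$f_mix, 1, tolerance = 1e-12)
    expect_gte(tr$f_mix, 0)
  }
  for (lam in c(0.5, 3, 19)) {
    tr <- poisson_fractions(lam, mix, geom, th)
    expect_equal(tr$f_A + tr$f_B + tr$f_mix, 1 - exp(-lam),
                 tolerance = 1e-11)
  }
  expect_error(poisson_fractions(0, mix, geom, th), "positive")
})

test_that("f_A grows with the overlook threshold and F_A falls with lambda", {
  mix <- chimera_mix(0.21)
  geom <- section_geometry(500, 50)
  f_A <- vapply(0:10, function(lb) {
    fixed_n_fractions(5, mix, geom, scoring_thresholds(l_TB = lb))$f_A
  }, numeric(1))
  expect_true(all(diff(f_A) >= 0))

  # paper-scale configuration, coarse lambda grid over [1, 60]
  geom_p <- section_geometry(5000, 100)
  th_p <- scoring_thresholds(l_TB = 10)
  F_A <- vapply(c(1, 5, 10, 20, 40, 60), function(lam) {
    poisson_fractions(lam, mix, geom_p, th_p)$f_A
  }, numeric(1))
  expect_true(all(diff(F_A) < 0))
})

test_that("inner hypergeometric sums stay in [0, 1] at production scale", {
  for (r in c(0, 1, 500, 2500, 4999, 5000)) {
    for (l in c(0, 20, 124, 199)) {
      v <- gcfounders:::hyper_at_most(l, r, 5000, 200)
      expect_gte(v, 0)
      expect_lte(v, 1 + 1e-9)
    }
  }
})

test_that("r-rounding convention has negligible leverage at the fitted optimum", {
  # floor / nearest / ceil for r = k*M/n shift the model triple only a little
  mix <- chimera_mix(0.21)
  geom <- section_geometry(5000, 200)
  th <- scoring_thresholds(l_TA = 128, l_TB = 22)
  triples <- lapply(c("floor", "nearest", "ceil"), function(mode) {
    as.numeric(poisson_fractions(23, mix, geom, th, r_mode = mode))
  })
  for (tr in triples) expect_true(all(is.finite(tr)))
  spread <- apply(do.call(rbind, triples), 2, function(v) diff(range(v)))
  expect_lt(max(spread), 0.01)
})

test_that("find_lambda_crossing round-trips and flags unbracketed targets", {
  # F_A is only monotone decreasing once the missing n = 0 Poisson mass is
  # negligible, so bracket away from lambda ~ 0
  mix <- chimera_mix(0.21)
  geom <- section_geometry(500, 50)
  th <- scoring_thresholds(l_TB = 5)
  target <- poisson_fractions(8, mix, geom, th)$f_A
  lam <- find_lambda_crossing(target, mix, geom, th, bracket = c(3, 60))
  expect_equal(as.numeric(lam), 8, tolerance = 1e-4)
  expect_error(find_lambda_crossing(0.999, mix, geom, th, bracket = c(3, 60)),
               "not bracketed")
})
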