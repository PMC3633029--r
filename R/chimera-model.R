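# Analytic section-classification probabilities for two-phenotype chimeric
# germinal centers: basic binomial seeding model and the extended model with
# hypergeometric section sampling, scoring-error thresholds and Poisson
# founder numbers.

#' Expected section fractions under the basic binomial model
#'
#' Under the basic model a GC seeded by `n` founders drawn from a pool with
#' type-B fraction `p` is pure-A with probability `q^n`, pure-B with `p^n`
#' and mixed otherwise. Sections are assumed to reflect the whole GC (no
#' sampling or scoring error). `n` may be real-valued: the model is routinely
#' inverted to non-integer founder numbers before rounding.
#'
#' @param n Founder count (real, `> 0`).
#' @param mix A [chimera_mix()] (or a bare `p`).
#' @return A `fraction_triple` with components summing to 1.
#' @examples
#' basic_expected_fractions(2, chimera_mix(0.5))
#' @export
basic_expected_fractions <- function(n, mix) {
  if (!inherits(mix, "chimera_mix")) mix <- chimera_mix(mix)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("founder count `n` must be a single positive number")
  }
  f_A <- mix$q^n
  f_B <- mix$p^n
  fraction_triple(f_A, f_B, 1 - f_A - f_B, model = "basic", n = n)
}

#' Invert a pure-section fraction to a founder number
#'
#' Solves `base^n = f_pure` for `n`, i.e. `n = log(f_pure) / log(base)`.
#' With `base = q` this inverts the pure-A fraction; with `base = p` the
#' pure-B fraction. The result is real-valued; round for reporting.
#'
#' @param f_pure Observed pure-section fraction, strictly inside `(0, 1)`.
#' @param base The corresponding pool fraction (`q` or `p`), in `(0, 1)`.
#' @return Real-valued founder number estimate.
#' @examples
#' invert_founders(0.14, 0.79)  # ~8.34 founders
#' invert_founders(0.06, 0.21)  # ~1.80 founders
#' @export
invert_founders <- function(f_pure, base) {
  for (nm in c("f_pure", "base")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x <= 0 || x >= 1) {
      stop("`", nm, "` must lie strictly inside (0, 1), got ", format(x))
    }
  }
  log(f_pure) / log(base)
}

# Number of type-B cells in the expanded GC given k of n founders are type B.
# Rounded half away from zero; clamped into [0, M] for safety.
gc_type_b_count <- function(k, n, M, r_mode = c("nearest", "floor", "ceil")) {
  r_mode <- match.arg(r_mode)
  x <- k * M / n
  r <- switch(r_mode,
    nearest = round_half_away(x),
    floor = floor(x),
    ceil = ceiling(x)
  )
  pmin(pmax(r, 0), M)
}

# P(a section of m cells contains at most l_max of the `special` marked cells
# among M), i.e. the hypergeometric lower tail, evaluated as an explicit
# log-space sum of binomial coefficients. Terms outside the feasible range
# [max(0, m - (M - special)), min(l_max, special)] are zero; an empty range
# yields probability 0.
hyper_at_most <- function(l_max, special, M, m) {
  lo <- max(0, m - (M - special))
  hi <- min(l_max, special)
  if (hi < lo) return(0)
  l <- lo:hi
  p <- sum(exp(lchoose(M - special, m - l) + lchoose(special, l) -
                 lchoose(M, m)))
  min(p, 1)
}

#' Probability that a GC with k type-B founders yields an apparently pure section
#'
#' `pure_A_section_prob()` gives the probability that a GC seeded by `n`
#' founders of which `k` are type B both arises (binomial weight
#' `C(n,k) p^k q^(n-k)`) and yields a section scored pure-A, i.e. a section
#' whose type-B cell count does not exceed the overlook threshold `l_TB`.
#' The section is a uniform draw of `m` of the GC's `M` cells, of which
#' \code{r = round(k*M/n)} are type B, so the section composition is
#' hypergeometric. `pure_B_section_prob()` is the mirror image: the section's
#' type-A count must not exceed `l_TA`. In both, `k` counts type-B founders.
#'
#' @param n Founder count (positive integer).
#' @param k Number of type-B founders among the `n`, `0 <= k <= n`.
#' @param mix A [chimera_mix()].
#' @param geom A [section_geometry()].
#' @param thresholds A [scoring_thresholds()].
#' @param r_mode Rounding convention for the type-B cell count `k*M/n`
#'   (default nearest integer, half away from zero).
#' @return A probability in `[0, 1]`.
#' @examples
#' pure_A_section_prob(2, 1, chimera_mix(0.21), section_geometry(10, 4),
#'                     scoring_thresholds(l_TB = 1))
#' @export
pure_A_section_prob <- function(n, k, mix, geom, thresholds,
                                r_mode = "nearest") {
  if (!is_count(n, min = 1)) stop("`n` must be a positive integer")
  if (!is_count(k) || k > n) stop("`k` must be an integer in [0, n]")
  check_thresholds(thresholds, geom)
  r <- gc_type_b_count(k, n, geom$M, r_mode)
  stats::dbinom(k, n, mix$p) * hyper_at_most(thresholds$l_TB, r, geom$M, geom$m)
}

#' @rdname pure_A_section_prob
#' @export
pure_B_section_prob <- function(n, k, mix, geom, thresholds,
                                r_mode = "nearest") {
  if (!is_count(n, min = 1)) stop("`n` must be a positive integer")
  if (!is_count(k) || k > n) stop("`k` must be an integer in [0, n]")
  check_thresholds(thresholds, geom)
  s <- geom$M - gc_type_b_count(k, n, geom$M, r_mode)
  stats::dbinom(k, n, mix$p) * hyper_at_most(thresholds$l_TA, s, geom$M, geom$m)
}

#' Expected section fractions under the extended model, fixed founder number
#'
#' Sums the apparently-pure probabilities over founder compositions:
#' `f_A(n) = sum_{k=0}^{n-1} P_A(n,k)`, `f_B(n) = sum_{k=1}^{n} P_B(n,k)`,
#' `f_Mix = 1 - f_A - f_B`. A truly pure-B GC (`k = n`) is never scored
#' pure-A and vice versa, per the summation limits. With `m = M` and zero
#' thresholds this reduces exactly to [basic_expected_fractions()].
#'
#' @inheritParams pure_A_section_prob
#' @return A `fraction_triple` summing to 1.
#' @export
fixed_n_fractions <- function(n, mix, geom, thresholds, r_mode = "nearest") {
  if (!is_count(n, min = 1)) stop("`n` must be a positive integer")
  check_thresholds(thresholds, geom)
  n <- as.integer(n)
  k <- 0:n
  r <- gc_type_b_count(k, n, geom$M, r_mode)
  w <- stats::dbinom(k, n, mix$p)
  hA <- vapply(r, function(ri) hyper_at_most(thresholds$l_TB, ri, geom$M, geom$m),
               numeric(1))
  hB <- vapply(geom$M - r,
               function(si) hyper_at_most(thresholds$l_TA, si, geom$M, geom$m),
               numeric(1))
  f_A <- sum(w[k < n] * hA[k < n])
  f_B <- sum(w[k > 0] * hB[k > 0])
  f_mix <- 1 - f_A - f_B
  # guard against -1e-17-scale floating-point residue; f_Mix >= 0 holds
  # mathematically whenever l_TA + l_TB < m
  if (f_mix < 0 && f_mix > -1e-9) f_mix <- 0
  fraction_triple(f_A, f_B, f_mix, model = "fixed_n", n = n)
}

# Truncation point for the Poisson mixture: smallest n with cumulative mass
# >= 1 - tail_tol, hard-capped at 500.
poisson_n_max <- function(lambda, tail_tol = 1e-12, cap = 500L) {
  n <- stats::qpois(1 - tail_tol, lambda)
  while (stats::ppois(n, lambda) < 1 - tail_tol && n < cap) n <- n + 1L
  min(as.integer(n), cap)
}

# Fixed-n fraction tables for n = 1..n_max; f_A depends only on l_TB and f_B
# only on l_TA, which grid_search() exploits by caching columns per threshold.
fixed_n_tables <- function(n_max, mix, geom, thresholds, r_mode = "nearest") {
  f <- vapply(seq_len(n_max), function(n) {
    tr <- fixed_n_fractions(n, mix, geom, thresholds, r_mode)
    c(tr$f_A, tr$f_B)
  }, numeric(2))
  list(f_A = f[1, ], f_B = f[2, ])
}

#' Expected section fractions under Poisson-distributed founder numbers
#'
#' Mixes the fixed-n fractions over a Poisson founder-number distribution
#' with mean `lambda`: `F_X = sum_{n>=1} Pois(n; lambda) f_X(n)`. The `n = 0`
#' term (a GC that never forms) is omitted and the triple is deliberately not
#' renormalized, so its components sum to `1 - exp(-lambda)`.
#'
#' @param lambda Mean founder number, `> 0`.
#' @param tail_tol The infinite sum is truncated at the smallest `n` whose
#'   cumulative Poisson mass reaches `1 - tail_tol` (hard cap `n = 500`).
#' @inheritParams pure_A_section_prob
#' @return A `fraction_triple` summing to `1 - exp(-lambda)` within `tail_tol`.
#' @export
poisson_fractions <- function(lambda, mix, geom, thresholds,
                              tail_tol = 1e-12, r_mode = "nearest") {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single positive number")
  }
  check_thresholds(thresholds, geom)
  n_max <- poisson_n_max(lambda, tail_tol)
  tab <- fixed_n_tables(n_max, mix, geom, thresholds, r_mode)
  w <- stats::dpois(seq_len(n_max), lambda)
  F_A <- sum(w * tab$f_A)
  F_B <- sum(w * tab$f_B)
  F_mix <- sum(w * (1 - tab$f_A - tab$f_B))
  fraction_triple(F_A, F_B, F_mix, model = "poisson",
                  lambda = lambda, n_max = n_max)
}

#' Solve for the Poisson mean at which F_A crosses a target value
#'
#' Finds `lambda` with `F_A(lambda) = target_F_A` by bisection on
#' `bracket`, assuming (and spot-checking) that `F_A` is monotone decreasing
#' in `lambda` over the bracket.
#'
#' @param target_F_A Target pure-A section fraction (scale of fractions).
#' @param bracket Search interval for `lambda`.
#' @param tol Convergence tolerance on `|F_A(lambda) - target|`.
#' @inheritParams poisson_fractions
#' @return The crossing `lambda`, with the achieved `F_A` as attribute
#'   `"F_A"`.
#' @export
find_lambda_crossing <- function(target_F_A, mix, geom, thresholds,
                                 bracket = c(0.5, 100), tol = 1e-8,
                                 tail_tol = 1e-12) {
  check_thresholds(thresholds, geom)
  stopifnot(length(bracket) == 2L, bracket[1] > 0, bracket[1] < bracket[2])
  # f_A(n) does not depend on lambda: tabulate once up to the bracket's
  # heaviest truncation and reuse for every bisection evaluation.
  n_hi <- poisson_n_max(bracket[2], tail_tol)
  tab <- fixed_n_tables(n_hi, mix, geom, thresholds)
  F_A <- function(lambda) {
    n_max <- poisson_n_max(lambda, tail_tol)
    sum(stats::dpois(seq_len(n_max), lambda) * tab$f_A[seq_len(n_max)])
  }
  probe <- seq(bracket[1], bracket[2], length.out = 5)
  vals <- vapply(probe, F_A, numeric(1))
  if (any(diff(vals) >= 0)) {
    stop("F_A is not monotone decreasing over the bracket; cannot bisect")
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- vals[1]; f_hi <- vals[5]
  if (target_F_A > f_lo || target_F_A < f_hi) {
    stop(sprintf(
      "target F_A = %.6g not bracketed: F_A(%g) = %.6g, F_A(%g) = %.6g",
      target_F_A, lo, f_lo, hi, f_hi))
  }
  f_mid <- NA_real_
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    f_mid <- F_A(mid)
    if (abs(f_mid - target_F_A) < tol || (hi - lo) < 1e-12) break
    if (f_mid > target_F_A) lo <- mid else hi <- mid
  }
  structure(mid, F_A = f_mid)
}
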