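#' Two-phenotype B-cell pool composition
#'
#' Describes the chimeric B-cell pool from which germinal centers (GCs) are
#' seeded: a fraction `p` of the pool carries phenotype B and the remaining
#' `q = 1 - p` carries phenotype A.
#'
#' @param p Fraction of phenotype-B cells in the seeding pool, in `[0, 1]`.
#' @return An object of class `chimera_mix` with fields `p` and `q`.
#' @examples
#' chimera_mix(0.21)
#' @export
chimera_mix <- function(p) {
  if (!is_prob(p)) {
    stop("`p` must be a single number in [0, 1], got ", deparse(p))
  }
  structure(list(p = p, q = 1 - p), class = "chimera_mix")
}

#' @export
print.chimera_mix <- function(x, ...) {
  cat(sprintf("<chimera_mix> p (type B) = %.4g, q (type A) = %.4g\n", x$p, x$q))
  invisible(x)
}

#' Germinal center and section geometry
#'
#' @param M Total number of B cells in one GC (positive integer).
#' @param m Number of B cells in one histological section, `1 <= m <= M`.
#' @return An object of class `section_geometry`.
#' @examples
#' section_geometry(M = 5000, m = 200)
#' @export
section_geometry <- function(M, m) {
  if (!is_count(M, min = 1)) stop("`M` must be a positive integer")
  if (!is_count(m, min = 1)) stop("`m` must be a positive integer")
  if (m > M) stop("section size `m` (", m, ") cannot exceed GC size `M` (", M, ")")
  structure(list(M = as.integer(M), m = as.integer(m)),
            class = "section_geometry")
}

#' @export
print.section_geometry <- function(x, ...) {
  cat(sprintf("<section_geometry> M = %d cells/GC, m = %d cells/section\n",
              x$M, x$m))
  invisible(x)
}

#' Scoring-error thresholds for section classification
#'
#' A section with at most `l_TB` type-B cells is scored "pure A" and one with
#' at most `l_TA` type-A cells is scored "pure B" (minority cells below the
#' threshold are overlooked, e.g. mistaken for unstained T cells). The two
#' thresholds must satisfy `l_TA + l_TB < m` or a section could be scored pure
#' for both types at once; that joint invariant is checked against a
#' [section_geometry()] wherever the thresholds are used.
#'
#' @param l_TA Maximum number of type-A cells overlooked when scoring pure-B.
#' @param l_TB Maximum number of type-B cells overlooked when scoring pure-A.
#' @return An object of class `scoring_thresholds`.
#' @examples
#' scoring_thresholds(l_TA = 124, l_TB = 20)
#' @export
scoring_thresholds <- function(l_TA = 0, l_TB = 0) {
  if (!is_count(l_TA)) stop("`l_TA` must be a non-negative integer")
  if (!is_count(l_TB)) stop("`l_TB` must be a non-negative integer")
  structure(list(l_TA = as.integer(l_TA), l_TB = as.integer(l_TB)),
            class = "scoring_thresholds")
}

#' @export
print.scoring_thresholds <- function(x, ...) {
  cat(sprintf("<scoring_thresholds> l_TA = %d, l_TB = %d cells\n",
              x$l_TA, x$l_TB))
  invisible(x)
}

# Joint invariant between thresholds and geometry.
check_thresholds <- function(thresholds, geom) {
  if (thresholds$l_TA + thresholds$l_TB >= geom$m) {
    stop("degenerate thresholds: l_TA + l_TB = ",
         thresholds$l_TA + thresholds$l_TB, " >= m = ", geom$m,
         " (a section could be scored pure for both types)")
  }
  invisible(TRUE)
}

#' Founder-number (seeding) models
#'
#' Either every GC is seeded by exactly `n` founder B cells, or founder
#' numbers vary between GCs following a Poisson distribution with mean
#' `lambda` (GCs that receive zero founders never form and are excluded).
#'
#' @param n Founder count per GC (positive integer).
#' @param lambda Mean founder number for the Poisson model (`> 0`).
#' @return An object of class `seeding_model` with fields `mode` ("fixed" or
#'   "poisson") and `n` or `lambda`.
#' @examples
#' seeding_fixed(2)
#' seeding_poisson(23)
#' @export
seeding_fixed <- function(n) {
  if (!is_count(n, min = 1)) stop("fixed founder count `n` must be a positive integer")
  structure(list(mode = "fixed", n = as.integer(n)), class = "seeding_model")
}

#' @rdname seeding_fixed
#' @export
seeding_poisson <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("Poisson mean `lambda` must be a single positive number")
  }
  structure(list(mode = "poisson", lambda = lambda), class = "seeding_model")
}

#' @export
print.seeding_model <- function(x, ...) {
  if (x$mode == "fixed") {
    cat(sprintf("<seeding_model> fixed n = %d founders/GC\n", x$n))
  } else {
    cat(sprintf("<seeding_model> Poisson, mean <n> = %.4g founders/GC\n",
                x$lambda))
  }
  invisible(x)
}

# Constructor for the (f_A, f_B, f_Mix) result records.
fraction_triple <- function(f_A, f_B, f_mix, model, ...) {
  structure(list(f_A = f_A, f_B = f_B, f_mix = f_mix, model = model, ...),
            class = "fraction_triple")
}

#' @export
print.fraction_triple <- function(x, ...) {
  cat(sprintf("<fraction_triple> [%s] f_A = %.6g, f_B = %.6g, f_Mix = %.6g (sum %.6g)\n",
              x$model, x$f_A, x$f_B, x$f_mix, x$f_A + x$f_B + x$f_mix))
  invisible(x)
}

# as.numeric() dispatches through as.double for primitives
#' @export
as.double.fraction_triple <- function(x, ...) {
  c(f_A = x$f_A, f_B = x$f_B, f_Mix = x$f_mix)
}

#' Observed section-classification data
#'
#' Packages the experimentally observed percentages of GC sections scored
#' pure-A, pure-B and mixed together with the known pool mixing fraction.
#' Inputs summing to about 100 are taken as percentages and inputs summing to
#' about 1 as fractions; anything else is rejected (the two conventions are
#' otherwise indistinguishable).
#'
#' @param pct_A,pct_B,pct_Mix Observed shares of sections scored pure-A,
#'   pure-B and mixed, as percentages (sum ~ 100) or fractions (sum ~ 1).
#' @param p Fraction of phenotype-B cells in the pool, or a [chimera_mix()].
#' @param n_sections Optional total number of sections scored.
#' @return An object of class `observed_section_data` with percentages in
#'   `$pct` (named `A`, `B`, `Mix`) and the pool in `$mix`.
#' @examples
#' observed_section_data(14, 6, 80, p = 0.21)
#' observed_section_data(0.14, 0.06, 0.80, p = 0.21)  # same thing
#' @export
observed_section_data <- function(pct_A, pct_B, pct_Mix, p,
                                  n_sections = NULL) {
  v <- c(A = pct_A, B = pct_B, Mix = pct_Mix)
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)) || any(v < 0)) {
    stop("observed shares must be three finite non-negative numbers")
  }
  s <- sum(v)
  if (abs(s - 100) <= 0.5) {
    pct <- v
  } else if (abs(s - 1) <= 0.005) {
    pct <- 100 * v
  } else {
    stop("observed shares sum to ", format(s),
         "; expected ~100 (percentages) or ~1 (fractions)")
  }
  mix <- if (inherits(p, "chimera_mix")) p else chimera_mix(p)
  if (!is.null(n_sections) && !is_count(n_sections, min = 1)) {
    stop("`n_sections` must be a positive integer")
  }
  structure(list(pct = pct, mix = mix, n_sections = n_sections),
            class = "observed_section_data")
}

#' @export
print.observed_section_data <- function(x, ...) {
  cat(sprintf(
    "<observed_section_data> p = %.4g; pure-A %.4g%%, pure-B %.4g%%, mixed %.4g%%",
    x$mix$p, x$pct[["A"]], x$pct[["B"]], x$pct[["Mix"]]))
  if (!is.null(x$n_sections)) cat(sprintf(" (%d sections)", x$n_sections))
  cat("\n")
  invisible(x)
}
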