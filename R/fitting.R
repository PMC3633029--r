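# Chi-square consistency statistics and grid-search fitting of the extended
# model's (<n>, l_TA, l_TB) to observed section-classification percentages.

# Critical values: chi2 at p = 0.001 for 1 and 2 df.
CHI2_CRIT_1DF <- 10.827
CHI2_CRIT_2DF <- 13.815

#' Chi-square goodness of fit on the percent scale
#'
#' Computes `chi2 = sum (obs - exp)^2 / exp` over the included categories,
#' with observed and expected values both on the percent (0-100) scale; the
#' percent scale is the convention under which the published consistency
#' statistics are reproduced. A category whose expected value was fixed to
#' equal its observed value contributes zero and may equivalently be masked.
#'
#' @param observed,expected Numeric vectors of category percentages.
#' @param include Logical mask of categories to include (default all).
#' @param critical Reference critical value stored in the result (default
#'   the p = 0.001 value for `df = included - 1`).
#' @return An object of class `chi_square_result` with fields `chi2`, `df`,
#'   `contributions`, `critical` and `significant` (chi2 > critical).
#' @examples
#' # pure-B and mixed categories predicted from the pure-A reference
#' chi_square_percent(c(14, 6, 80), c(14, 2.2e-4, 86.0),
#'                    include = c(FALSE, TRUE, TRUE))
#' @export
chi_square_percent <- function(observed, expected, include = NULL,
                               critical = NULL) {
  if (length(observed) != length(expected)) {
    stop("`observed` and `expected` must have the same length")
  }
  include <- include %||% rep(TRUE, length(observed))
  if (length(include) != length(observed)) {
    stop("`include` mask length must match the categories")
  }
  if (any(include & (!is.finite(expected) | expected <= 0))) {
    bad <- which(include & (!is.finite(expected) | expected <= 0))
    stop("expected value must be positive in included categories (category ",
         paste(bad, collapse = ", "), ")")
  }
  contrib <- rep(0, length(observed))
  contrib[include] <- (observed[include] - expected[include])^2 /
    expected[include]
  names(contrib) <- names(observed)
  df <- sum(include) - 1L
  critical <- critical %||% stats::qchisq(0.999, max(df, 1L))
  chi2 <- sum(contrib)
  structure(list(chi2 = chi2, df = df, contributions = contrib,
                 observed = observed, expected = expected, include = include,
                 critical = critical, significant = chi2 > critical),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("<chi_square_result> chi2 = %.6g (df = %d, critical %.4g: %s)\n",
              x$chi2, x$df, x$critical,
              if (x$significant) "REJECT" else "consistent"))
  invisible(x)
}

#' Internal-consistency report for the basic binomial model
#'
#' Checks whether an observed (pure-A, pure-B, mixed) triple is internally
#' consistent with the basic model: the founder number is fixed by inverting
#' one observed pure fraction (the reference), the other two categories are
#' predicted from it, and a chi-square over those two categories is compared
#' with the critical value 10.827 (p = 0.001, 1 df). Both references (pure-A
#' and pure-B) are reported.
#'
#' @param data An [observed_section_data()].
#' @return An object of class `consistency_report`: a list with one entry per
#'   reference (`ref_A`, `ref_B`), each holding the inverted founder number
#'   `n`, the expected percentages and a `chi_square_result`.
#' @examples
#' table1_consistency_report(observed_section_data(14, 6, 80, p = 0.21))
#' @export
table1_consistency_report <- function(data) {
  stopifnot(inherits(data, "observed_section_data"))
  p <- data$mix$p; q <- data$mix$q
  obs <- data$pct
  f_A <- obs[["A"]] / 100; f_B <- obs[["B"]] / 100

  one_ref <- function(reference) {
    if (reference == "A") {
      n <- invert_founders(f_A, q)
      expected <- c(A = obs[["A"]], B = 100 * p^n,
                    Mix = 100 * (1 - f_A - p^n))
      include <- c(FALSE, TRUE, TRUE)
    } else {
      n <- invert_founders(f_B, p)
      expected <- c(A = 100 * q^n, B = obs[["B"]],
                    Mix = 100 * (1 - f_B - q^n))
      include <- c(TRUE, FALSE, TRUE)
    }
    chi2 <- chi_square_percent(obs, expected, include,
                               critical = CHI2_CRIT_1DF)
    list(reference = reference, n = n, n_rounded = round_half_away(n),
         expected_pct = expected, chi2 = chi2)
  }

  structure(list(ref_A = one_ref("A"), ref_B = one_ref("B"), data = data),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  obs <- x$data$pct
  cat("Internal-consistency check of the basic binomial model\n")
  cat(sprintf("  observed: pure-A %.4g%%, pure-B %.4g%%, mixed %.4g%% (p = %.4g)\n",
              obs[["A"]], obs[["B"]], obs[["Mix"]], x$data$mix$p))
  for (ref in list(x$ref_A, x$ref_B)) {
    cat(sprintf("  reference pure-%s: n = %.4g (~%d founders)\n",
                ref$reference, ref$n, as.integer(ref$n_rounded)))
    e <- ref$expected_pct
    cat(sprintf("    expected: A %.4g%%, B %.4g%%, Mix %.4g%%\n",
                e[["A"]], e[["B"]], e[["Mix"]]))
    cat(sprintf("    chi2 = %.6g vs critical %.4g (1 df, p = 0.001): %s\n",
                ref$chi2$chi2, ref$chi2$critical,
                if (ref$chi2$significant) "INCONSISTENT" else "consistent"))
  }
  invisible(x)
}

#' Chi-square of the extended model at one parameter point
#'
#' Evaluates the Poisson-mixture model at mean founder number `lambda` with
#' scoring thresholds given as percentages of the section size `m`
#' (converted to cells by rounding), converts the predicted triple to
#' percent, and returns the three-category chi-square against the observed
#' percentages (df = 2, critical 13.815 at p = 0.001).
#'
#' @param lambda Mean founder number.
#' @param l_TB_pct,l_TA_pct Scoring thresholds as percent of `m`.
#' @param data An [observed_section_data()].
#' @param geom A [section_geometry()].
#' @param tail_tol Poisson truncation tolerance (see [poisson_fractions()]).
#' @return A `chi_square_result` with the model triple attached as
#'   attribute `"triple"`.
#' @export
chi2_at_point <- function(lambda, l_TB_pct, l_TA_pct, data, geom,
                          tail_tol = 1e-12) {
  stopifnot(inherits(data, "observed_section_data"))
  thresholds <- scoring_thresholds(l_TA = pct_to_cells(l_TA_pct, geom$m),
                                   l_TB = pct_to_cells(l_TB_pct, geom$m))
  tr <- poisson_fractions(lambda, data$mix, geom, thresholds,
                          tail_tol = tail_tol)
  expected <- 100 * c(A = tr$f_A, B = tr$f_B, Mix = tr$f_mix)
  res <- chi_square_percent(data$pct, expected, critical = CHI2_CRIT_2DF)
  attr(res, "triple") <- tr
  res
}

#' Grid search of the extended model's chi-square surface
#'
#' Evaluates the three-category chi-square of the Poisson-mixture model over
#' a grid of mean founder numbers and percent scoring thresholds, and reports
#' the full surface, its global minimum and all local minima (grid points
#' whose chi-square does not exceed any of their up-to-six axis neighbors).
#' Grid points with degenerate thresholds (`l_TA + l_TB >= m` after percent
#' to cell conversion) are skipped with a warning tally.
#'
#' @param data An [observed_section_data()].
#' @param geom A [section_geometry()].
#' @param lambda_range Integer mean founder numbers to scan (default 1..40).
#' @param l_TB_pct_range,l_TA_pct_range Threshold grids in percent of `m`
#'   (defaults 10..15 and 50..65, step 1).
#' @param tail_tol Poisson truncation tolerance.
#' @return An object of class `grid_search_result`: `surface` (a data.frame
#'   with columns `lambda`, `l_TB_pct`, `l_TA_pct`, `chi2`), `global_min`
#'   (one surface row), `local_minima` (surface rows sorted by chi2) and
#'   `n_skipped`.
#' @examples
#' \dontrun{
#' gs <- grid_search(observed_section_data(14, 6, 80, p = 0.21),
#'                   section_geometry(5000, 200))
#' gs$global_min
#' }
#' @export
grid_search <- function(data, geom, lambda_range = 1:40,
                        l_TB_pct_range = 10:15, l_TA_pct_range = 50:65,
                        tail_tol = 1e-12) {
  stopifnot(inherits(data, "observed_section_data"))
  if (!length(lambda_range) || !length(l_TB_pct_range) ||
      !length(l_TA_pct_range)) {
    stop("empty grid: every range must contain at least one value")
  }
  mix <- data$mix
  n_max_glob <- poisson_n_max(max(lambda_range), tail_tol)

  # f_A(n) depends only on l_TB and f_B(n) only on l_TA: tabulate one column
  # per distinct threshold cell count instead of one per threshold pair.
  tb_cells <- pct_to_cells(l_TB_pct_range, geom$m)
  ta_cells <- pct_to_cells(l_TA_pct_range, geom$m)
  fA_tab <- lapply(unique(tb_cells), function(lb) {
    vapply(seq_len(n_max_glob), function(n) {
      fixed_n_fractions(n, mix, geom, scoring_thresholds(l_TB = lb))$f_A
    }, numeric(1))
  })
  names(fA_tab) <- as.character(unique(tb_cells))
  fB_tab <- lapply(unique(ta_cells), function(la) {
    vapply(seq_len(n_max_glob), function(n) {
      fixed_n_fractions(n, mix, geom, scoring_thresholds(l_TA = la))$f_B
    }, numeric(1))
  })
  names(fB_tab) <- as.character(unique(ta_cells))

  grid <- expand.grid(lambda = lambda_range, l_TB_pct = l_TB_pct_range,
                      l_TA_pct = l_TA_pct_range, KEEP.OUT.ATTRS = FALSE)
  pois_w <- lapply(lambda_range, function(lam) {
    nm <- poisson_n_max(lam, tail_tol)
    stats::dpois(seq_len(nm), lam)
  })
  names(pois_w) <- as.character(lambda_range)

  n_skipped <- 0L
  grid$chi2 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    lb <- pct_to_cells(grid$l_TB_pct[i], geom$m)
    la <- pct_to_cells(grid$l_TA_pct[i], geom$m)
    if (la + lb >= geom$m) {
      n_skipped <- n_skipped + 1L
      next
    }
    w <- pois_w[[as.character(grid$lambda[i])]]
    idx <- seq_along(w)
    fA <- sum(w * fA_tab[[as.character(lb)]][idx])
    fB <- sum(w * fB_tab[[as.character(la)]][idx])
    fM <- sum(w * (1 - fA_tab[[as.character(lb)]][idx] -
                     fB_tab[[as.character(la)]][idx]))
    expected <- 100 * c(A = fA, B = fB, Mix = fM)
    grid$chi2[i] <- chi_square_percent(data$pct, expected)$chi2
  }
  if (n_skipped > 0) {
    warning(n_skipped, " grid point(s) skipped (degenerate thresholds)")
  }
  if (all(is.na(grid$chi2))) stop("every grid point was degenerate")

  local_min <- find_local_minima(grid, lambda_range, l_TB_pct_range,
                                 l_TA_pct_range)
  global <- grid[which.min(grid$chi2), , drop = FALSE]
  structure(list(surface = grid, global_min = global,
                 local_minima = local_min, n_skipped = n_skipped,
                 geom = geom, data = data),
            class = "grid_search_result")
}

# Local minima: chi2 <= all up-to-6 axis-adjacent neighbors (ties allowed),
# NA (skipped) neighbors ignored.
find_local_minima <- function(grid, lambdas, tbs, tas) {
  arr <- array(NA_real_, dim = c(length(lambdas), length(tbs), length(tas)))
  arr[cbind(match(grid$lambda, lambdas), match(grid$l_TB_pct, tbs),
            match(grid$l_TA_pct, tas))] <- grid$chi2
  is_min <- array(FALSE, dim = dim(arr))
  d <- dim(arr)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- arr[i, j, k]
    if (is.na(v)) next
    nb <- c(
      if (i > 1) arr[i - 1, j, k], if (i < d[1]) arr[i + 1, j, k],
      if (j > 1) arr[i, j - 1, k], if (j < d[2]) arr[i, j + 1, k],
      if (k > 1) arr[i, j, k - 1], if (k < d[3]) arr[i, j, k + 1]
    )
    nb <- nb[!is.na(nb)]
    is_min[i, j, k] <- !length(nb) || v <= min(nb)
  }
  idx <- which(is_min, arr.ind = TRUE)
  out <- data.frame(lambda = lambdas[idx[, 1]], l_TB_pct = tbs[idx[, 2]],
                    l_TA_pct = tas[idx[, 3]],
                    chi2 = arr[idx])
  out[order(out$chi2), , drop = FALSE]
}

#' @export
print.grid_search_result <- function(x, n = 5, ...) {
  g <- x$global_min
  cat(sprintf(
    "Chi-square grid search over %d points (%d skipped)\n",
    nrow(x$surface), x$n_skipped))
  cat(sprintf(
    "  global minimum: chi2 = %.4g at <n> = %g, l_TB = %g%%, l_TA = %g%%\n",
    g$chi2, g$lambda, g$l_TB_pct, g$l_TA_pct))
  k <- min(n, nrow(x$local_minima))
  cat(sprintf("  top %d local minima:\n", k))
  print(utils::head(x$local_minima, k), row.names = FALSE)
  invisible(x)
}
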