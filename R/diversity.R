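# Clonal richness estimation from clone-abundance samples of single GC
# sections: a Yule-Simon mixed-Poisson unseen-species estimator and the
# abundance-based coverage estimator (ACE) for comparison.

#' Clone-abundance sample
#'
#' Wraps the per-clone observed abundances of one GC sample and derives the
#' summary statistics used by the richness estimators: the number of
#' distinct clones `S_obs`, the total count `N` and the frequency-of-
#' frequencies histogram `f_k` (number of clones seen exactly `k` times).
#'
#' @param counts Integer vector of per-clone abundances, each `>= 1`.
#' @param name Optional sample label (used in report tables).
#' @return An object of class `abundance_sample`.
#' @examples
#' abundance_sample(c(1, 1, 2, 3, 12), name = "B8")
#' @export
abundance_sample <- function(counts, name = NULL) {
  if (!is.numeric(counts) || !length(counts) || any(!is.finite(counts)) ||
      any(counts < 1) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` must be a non-empty vector of positive integers")
  }
  counts <- as.integer(round(counts))
  fk <- table(counts)
  structure(list(counts = counts, S_obs = length(counts),
                 N = sum(counts),
                 f_k = stats::setNames(as.integer(fk), names(fk)),
                 name = name),
            class = "abundance_sample")
}

#' @export
print.abundance_sample <- function(x, ...) {
  cat(sprintf("<abundance_sample>%s S_obs = %d clones, N = %d cells\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$S_obs, x$N))
  invisible(x)
}

#' Yule-Simon distribution
#'
#' The Yule-Simon distribution `P(K = k) = rho * B(k, rho + 1)` for
#' `k = 1, 2, ...` is a heavy-tailed clone-size model (tail `~ k^-(rho+1)`);
#' its mean is `rho / (rho - 1)` for `rho > 1`. `ryule()` samples by
#' inverting the closed-form survival function `P(K > k) = k * B(k, rho+1)`.
#'
#' @param k Positive integer clone sizes.
#' @param rho Shape exponent, `> 0`.
#' @param n Number of draws.
#' @param cap Largest value representable by the sampler's lookup table;
#'   draws beyond it (tail mass `~ cap^-rho`) are clamped to `cap`.
#' @return `yule_pmf()`: probabilities; `ryule()`: integer draws.
#' @examples
#' yule_pmf(1:5, rho = 2)
#' @export
yule_pmf <- function(k, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("`rho` must be a single positive number")
  }
  if (any(k < 1 | abs(k - round(k)) > 1e-8)) {
    stop("`k` must contain positive integers")
  }
  exp(log(rho) + lbeta(k, rho + 1))
}

# log survival P(K > k) = k * B(k, rho + 1).
yule_lsurv <- function(k, rho) log(k) + lbeta(k, rho + 1)

#' @rdname yule_pmf
#' @export
ryule <- function(n, rho, cap = 5e4) {
  cdf <- cumsum(yule_pmf(seq_len(cap), rho))
  findInterval(stats::runif(n), cdf) + 1L
}

# Control parameters for the Yule richness fit.
yule_control <- function(rho_bounds = c(1.01, 50), D_cap_factor = 1e4,
                         tol = 1e-8, c_cap = 5e4) {
  list(rho_bounds = rho_bounds, D_cap_factor = D_cap_factor, tol = tol,
       c_cap = c_cap)
}

# Log-likelihood of the two-stage model: D latent clones with i.i.d.
# Yule(rho) sizes; a clone of latent size c is observed Poisson with mean
# a*c where a = N / (D * mu(rho)), mu = rho/(rho-1); unseen clones (count 0)
# enter through p0 = E[exp(-a c)]. The Yule expectation is truncated at
# c_max with an analytic bound on the discarded tail. `ux`/`wx` are the
# unique observed counts and their multiplicities; S = sum(wx).
# Latent clone-size grid for the Yule expectation: exact support up to
# `exact`, then geometrically spaced bins up to c_max whose Yule mass is
# taken from the closed-form survival function S(c) = c * B(c, rho + 1)
# and assigned to the bin's geometric midpoint. Returns representative
# sizes `c` and their log-masses `logw` (conditional terms sum to ~1).
yule_c_grid <- function(rho, c_max, exact = 1000L) {
  if (c_max <= exact) {
    cs <- seq_len(c_max)
    return(list(c = cs, logw = log(rho) + lbeta(cs, rho + 1)))
  }
  cs <- seq_len(exact)
  logw <- log(rho) + lbeta(cs, rho + 1)
  br <- unique(round(exp(seq(log(exact), log(c_max), length.out = 120))))
  if (length(br) > 1) {
    surv <- exp(yule_lsurv(br, rho))
    mass <- surv[-length(surv)] - surv[-1]
    keep <- mass > 0
    mid <- sqrt(br[-length(br)] * br[-1])
    cs <- c(cs, mid[keep])
    logw <- c(logw, log(mass[keep]))
  }
  list(c = cs, logw = logw)
}

yule_loglik <- function(D, rho, ux, wx, S, N, ctrl) {
  mu <- rho / (rho - 1)
  a <- N / (D * mu)
  # The Poisson term for count x peaks at latent size c = x/a: keep the
  # grid well past the largest such peak and past the bulk of exp(-a c).
  c_max <- as.integer(min(ctrl$c_cap,
                          max(500, ceiling((2 * max(ux) + 30) / a))))
  grid <- yule_c_grid(rho, c_max)
  p0 <- sum(exp(grid$logw - a * grid$c)) +
    exp(yule_lsurv(c_max, rho) - a * c_max)  # tail bound
  p0 <- min(max(p0, 1e-300), 1 - 1e-12)
  acs <- a * grid$c
  log_px <- vapply(ux, function(x) {
    v <- grid$logw + stats::dpois(x, acs, log = TRUE)
    mx <- max(v)
    mx + log(sum(exp(v - mx)))
  }, numeric(1))
  lgamma(D + 1) - lgamma(D - S + 1) - lgamma(S + 1) +
    (D - S) * log(p0) + sum(wx * log_px)
}

#' Yule-based unseen-species richness estimate
#'
#' Estimates the total number of clones `D` present in the sampled cell
#' aggregate from the observed (zero-truncated) clone abundances, under a
#' two-stage model: the `D` clones have i.i.d. Yule-Simon(`rho`) latent
#' sizes, and a clone of latent size `c` contributes a Poisson-distributed
#' observed count with mean `N c / (D mu(rho))` (so the expected total count
#' is `N`). Clones with observed count zero are unseen; their probability
#' `p0 = E[exp(-N c / (D mu))]` links `D` to the observed clone number via
#' `S_obs ~ Binomial(D, 1 - p0)`. The profile likelihood over `D` (inner
#' 1-D optimization of `rho`) is maximized; the estimate therefore
#' satisfies `D_hat >= S_obs` by construction.
#'
#' @param sample An [abundance_sample()] (or a bare counts vector).
#' @param control Optimization settings from `yule_control()`: `rho` bounds
#'   (default 1.01-50), the cap `D <= D_cap_factor * S_obs` (default 1e4)
#'   and convergence tolerance.
#' @return An object of class `diversity_estimate` with fields `method`
#'   ("yule"), `D_hat`, `rho_hat`, `converged`, `boundary`, `p0`,
#'   `log_lik` and the input summary.
#' @examples
#' yule_estimate(abundance_sample(c(4, 2, 1, 1, 1, 3)))
#' @export
yule_estimate <- function(sample, control = yule_control()) {
  if (!inherits(sample, "abundance_sample")) {
    sample <- abundance_sample(sample)
  }
  counts <- sample$counts
  S <- sample$S_obs
  N <- sample$N
  ctrl <- control
  D_max <- ctrl$D_cap_factor * S
  tab <- table(counts)
  ux <- as.integer(names(tab))
  wx <- as.integer(tab)

  profile <- function(logD) {
    D <- exp(logD)
    opt <- stats::optimize(
      function(rho) yule_loglik(D, rho, ux, wx, S, N, ctrl),
      interval = ctrl$rho_bounds, maximum = TRUE, tol = 1e-3)
    list(ll = opt$objective, rho = opt$maximum)
  }

  lo <- log(S)
  hi <- log(D_max)
  outer <- stats::optimize(function(logD) profile(logD)$ll,
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-3)
  # optimize() never probes the boundary itself: compare explicitly.
  cand_logD <- c(outer$maximum, lo)
  cand <- lapply(cand_logD, profile)
  best <- which.max(vapply(cand, `[[`, numeric(1), "ll"))
  D_hat <- max(exp(cand_logD[best]), S)
  rho_hat <- cand[[best]]$rho
  ll <- cand[[best]]$ll

  at_lower <- D_hat <= S * (1 + 1e-6)
  at_upper <- D_hat >= 0.99 * D_max
  all_singletons <- all(counts == 1L) && S > 1L
  mu <- rho_hat / (rho_hat - 1)
  a <- N / (D_hat * mu)
  cs <- seq_len(as.integer(min(ctrl$c_cap, max(1000, ceiling(30 / a)))))
  p0 <- sum(yule_pmf(cs, rho_hat) * exp(-a * cs))

  structure(list(method = "yule", D_hat = D_hat, rho_hat = rho_hat,
                 converged = !(at_upper || all_singletons),
                 boundary = at_lower || at_upper,
                 p0 = p0, log_lik = ll,
                 S_obs = S, N = N, name = sample$name),
            class = "diversity_estimate")
}

#' Abundance-based coverage estimator (ACE)
#'
#' Standard nonparametric richness estimator. Clones with abundance at most
#' `rare_cutoff` form the rare class used to estimate sample coverage
#' `C_ACE = 1 - f1 / N_rare`; the estimate is
#' `S_ACE = S_abund + S_rare / C_ACE + (f1 / C_ACE) * gamma^2` with the
#' coefficient-of-variation correction `gamma^2` floored at zero. When every
#' rare clone is a singleton (`C_ACE = 0`) the bias-corrected Chao1
#' estimator is used instead and flagged.
#'
#' @param sample An [abundance_sample()] (or a bare counts vector).
#' @param rare_cutoff Abundance at or below which a clone counts as rare
#'   (default 10, the standard choice).
#' @return An object of class `diversity_estimate` with fields `method`
#'   ("ace" or "chao1" on fallback), `D_hat`, `coverage`, `gamma2`.
#' @examples
#' ace_estimate(abundance_sample(c(1, 1, 2, 3, 12)))
#' @export
ace_estimate <- function(sample, rare_cutoff = 10) {
  if (!inherits(sample, "abundance_sample")) {
    sample <- abundance_sample(sample)
  }
  counts <- sample$counts
  rare <- counts <= rare_cutoff
  S_rare <- sum(rare)
  S_abund <- sum(!rare)
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  N_rare <- sum(counts[rare])

  if (S_rare == 0L) {
    est <- list(D_hat = sample$S_obs, coverage = 1, gamma2 = 0,
                method = "ace")
  } else if (f1 == S_rare) {
    # All rare clones are singletons: coverage 0, fall back to Chao1
    # (bias-corrected form, defined even when f2 = 0).
    D_hat <- sample$S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    est <- list(D_hat = D_hat, coverage = 0, gamma2 = NA_real_,
                method = "chao1")
  } else {
    C_ace <- 1 - f1 / N_rare
    k <- seq_len(rare_cutoff)
    fk <- vapply(k, function(kk) sum(counts == kk), numeric(1))
    gamma2 <- max(
      S_rare / C_ace * sum(k * (k - 1) * fk) / (N_rare * (N_rare - 1)) - 1,
      0)
    D_hat <- S_abund + S_rare / C_ace + f1 / C_ace * gamma2
    est <- list(D_hat = D_hat, coverage = C_ace, gamma2 = gamma2,
                method = "ace")
  }
  structure(list(method = est$method, D_hat = est$D_hat,
                 coverage = est$coverage, gamma2 = est$gamma2,
                 converged = TRUE, boundary = est$D_hat <= sample$S_obs,
                 S_obs = sample$S_obs, N = sample$N, name = sample$name),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate>%s method = %s: S_obs = %d, D_hat = %.4g",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$method, x$S_obs, x$D_hat))
  if (!is.null(x$rho_hat)) cat(sprintf(", rho_hat = %.4g", x$rho_hat))
  if (!x$converged) cat("  [not converged]")
  if (isTRUE(x$boundary)) cat("  [boundary]")
  cat("\n")
  invisible(x)
}

#' Per-GC richness report table
#'
#' Applies both richness estimators to each sample and lays the results out
#' one row per GC: observed clone number, Yule and ACE estimates, and flags.
#'
#' @param samples A list of [abundance_sample()] objects (names are used as
#'   GC labels when the samples carry none).
#' @param control Passed to [yule_estimate()].
#' @param rare_cutoff Passed to [ace_estimate()].
#' @return A data.frame with columns `gc`, `observed`, `yule_D`, `yule_rho`,
#'   `ace_D`, `flags`, carrying the full estimate objects as attribute
#'   `"estimates"`.
#' @export
tabulate_gc_estimates <- function(samples, control = yule_control(),
                                  rare_cutoff = 10) {
  if (inherits(samples, "abundance_sample")) samples <- list(samples)
  if (!length(samples)) stop("at least one sample is required")
  labels <- names(samples) %||% rep(NA_character_, length(samples))
  rows <- vector("list", length(samples))
  ests <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!inherits(s, "abundance_sample")) s <- abundance_sample(s)
    label <- s$name %||% labels[i]
    if (is.na(label) || !nzchar(label)) label <- paste0("GC", i)
    yu <- yule_estimate(s, control)
    ac <- ace_estimate(s, rare_cutoff)
    flags <- c(
      if (!yu$converged) "yule_not_converged",
      if (yu$boundary) "yule_boundary",
      if (ac$method == "chao1") "ace_chao1_fallback"
    )
    rows[[i]] <- data.frame(
      gc = label, observed = s$S_obs,
      yule_D = yu$D_hat, yule_rho = yu$rho_hat, ace_D = ac$D_hat,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
    ests[[i]] <- list(yule = yu, ace = ac)
  }
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- ests
  out
}

#' Simulate a clone-abundance sample from the Yule richness model
#'
#' Draws one sample from exactly the generative model fitted by
#' [yule_estimate()]: `D` clones with i.i.d. Yule(`rho`) latent sizes, each
#' observed as a Poisson count with mean `N c / (D mu(rho))`; clones with
#' zero observed count are dropped. Used for parameter-recovery validation.
#'
#' @param D True total clone number.
#' @param rho Yule exponent (`> 1` so the mean clone size is finite).
#' @param N Target expected total observed count.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return An [abundance_sample()]; samples in which no clone was observed
#'   are re-drawn (the estimator needs `S_obs >= 1`).
#' @export
simulate_abundance_sample <- function(D, rho, N, seed = NULL) {
  stopifnot(is_count(D, min = 1), rho > 1, N > 0)
  with_seed(seed, {
    mu <- rho / (rho - 1)
    repeat {
      c_lat <- ryule(D, rho)
      x <- stats::rpois(D, N * c_lat / (D * mu))
      if (any(x > 0)) break
    }
    abundance_sample(x[x > 0])
  })
}
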