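# Monte-Carlo forward simulator of GC seeding / expansion / sectioning /
# scoring (a brute-force oracle for the analytic model) and a synthetic
# stained-section renderer on a hexagonal lattice.

#' Monte-Carlo simulation configuration
#'
#' @param mix A [chimera_mix()].
#' @param seeding A [seeding_fixed()] or [seeding_poisson()] model.
#' @param geom A [section_geometry()].
#' @param thresholds A [scoring_thresholds()].
#' @param n_gcs Number of replicate GCs to simulate (one section each).
#' @param seed RNG seed; the caller's RNG state is preserved.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(mix, seeding, geom, thresholds, n_gcs,
                              seed = NULL) {
  stopifnot(inherits(mix, "chimera_mix"), inherits(seeding, "seeding_model"),
            inherits(geom, "section_geometry"),
            inherits(thresholds, "scoring_thresholds"))
  if (!is_count(n_gcs, min = 1)) stop("`n_gcs` must be a positive integer")
  check_thresholds(thresholds, geom)
  structure(list(mix = mix, seeding = seeding, geom = geom,
                 thresholds = thresholds, n_gcs = as.integer(n_gcs),
                 seed = seed),
            class = "simulation_config")
}

# Founder numbers per GC; Poisson draws are conditioned on n >= 1 by
# rejection (a GC with no founders never forms).
draw_founder_numbers <- function(n_gcs, seeding) {
  if (seeding$mode == "fixed") {
    return(rep.int(seeding$n, n_gcs))
  }
  n <- stats::rpois(n_gcs, seeding$lambda)
  while (any(zero <- n == 0L)) {
    n[zero] <- stats::rpois(sum(zero), seeding$lambda)
  }
  n
}

#' Monte-Carlo simulation of section classification
#'
#' For each replicate GC: draw the founder number `n` (fixed, or Poisson
#' conditioned on `n >= 1`), the type-B founder count `k ~ Binomial(n, p)`,
#' expand to \code{r = round(k*M/n)} type-B cells, draw the section's type-B
#' cell count from `Hypergeometric(M, r, m)`, and score the section pure-A
#' if that count is at most `l_TB`, pure-B if the type-A count is at most
#' `l_TA`, and mixed otherwise. Empirical fractions are over all simulated
#' GCs (all of which have `n >= 1`); to compare with the unrenormalized
#' Poisson-model triple, multiply by the returned `norm = 1 - exp(-lambda)`.
#'
#' @param config A [simulation_config()].
#' @param detail If `TRUE`, the per-GC classification vector is returned in
#'   `$classes` (factor with levels A, B, Mix).
#' @return An object of class `section_simulation`: `fractions` (named A, B,
#'   Mix, summing to 1), `tallies`, `n_gcs`, `norm` and the seed used.
#' @examples
#' cfg <- simulation_config(chimera_mix(0.21), seeding_fixed(2),
#'                          section_geometry(10, 4),
#'                          scoring_thresholds(1, 1), n_gcs = 1000, seed = 1)
#' simulate_sections(cfg)
#' @export
simulate_sections <- function(config, detail = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$geom
  th <- config$thresholds
  with_seed(config$seed, {
    n <- draw_founder_numbers(config$n_gcs, config$seeding)
    k <- stats::rbinom(config$n_gcs, n, config$mix$p)
    r <- gc_type_b_count(k, n, g$M)
    b_in_section <- stats::rhyper(config$n_gcs, r, g$M - r, g$m)
    cls <- ifelse(b_in_section <= th$l_TB, "A",
                  ifelse(g$m - b_in_section <= th$l_TA, "B", "Mix"))
    cls <- factor(cls, levels = c("A", "B", "Mix"))
    tallies <- table(cls)
    norm <- if (config$seeding$mode == "poisson") {
      1 - exp(-config$seeding$lambda)
    } else {
      1
    }
    structure(list(
      fractions = stats::setNames(as.numeric(tallies) / config$n_gcs,
                                  c("A", "B", "Mix")),
      tallies = stats::setNames(as.integer(tallies), c("A", "B", "Mix")),
      n_gcs = config$n_gcs, norm = norm, seed = config$seed,
      classes = if (detail) cls else NULL),
      class = "section_simulation")
  })
}

#' @export
print.section_simulation <- function(x, ...) {
  f <- x$fractions
  cat(sprintf(
    "<section_simulation> %d GCs: pure-A %.4g, pure-B %.4g, mixed %.4g (norm %.4g)\n",
    x$n_gcs, f[["A"]], f[["B"]], f[["Mix"]], x$norm))
  invisible(x)
}

#' Package a simulated dataset as observed section data
#'
#' Runs [simulate_sections()] and wraps the empirical percentages together
#' with the pool mixing fraction as an [observed_section_data()], ready for
#' the fitting module (end-to-end recovery experiments).
#'
#' @param config A [simulation_config()].
#' @return An [observed_section_data()].
#' @export
generate_observed_dataset <- function(config) {
  sim <- simulate_sections(config)
  f <- sim$fractions
  observed_section_data(100 * f[["A"]], 100 * f[["B"]], 100 * f[["Mix"]],
                        p = config$mix, n_sections = config$n_gcs)
}

# Roughly circular patch of a pointy-top hexagonal lattice with `n` sites,
# chosen nearest the origin (deterministic tie-break by row, then column).
hex_lattice <- function(n) {
  half <- ceiling(sqrt(n))  # generous bounding box
  rows <- -half:half
  grid <- expand.grid(row = rows, col = -half:half)
  grid$x <- grid$col + ifelse(grid$row %% 2 == 0, 0, 0.5)
  grid$y <- grid$row * sqrt(3) / 2
  d <- grid$x^2 + grid$y^2
  grid <- grid[order(d, grid$row, grid$col), , drop = FALSE]
  out <- grid[seq_len(n), c("row", "col", "x", "y"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a synthetic stained GC section
#'
#' Emulates an immunofluorescence image of one GC section: `total_cells`
#' positions on a hexagonal lattice, of which a fraction `b_cell_fraction`
#' are B cells (the rest are unstained non-B cells such as T cells);
#' a fraction `type_A_fraction` of the B cells carry phenotype A, and only
#' those receive a positive stain intensity. Non-homogeneous staining is
#' modeled as `base * lognormal(0, sdlog)` clipped to `[0, 1]`.
#'
#' @param type_A_fraction Fraction of B cells of type A, in `[0, 1]`.
#' @param total_cells Lattice size (default 202 cells).
#' @param b_cell_fraction Fraction of lattice positions holding B cells
#'   (default 0.8; the remainder are non-B cells).
#' @param stain_base,stain_sdlog Stain-intensity model parameters.
#' @param seed RNG seed (caller's RNG state preserved).
#' @param png_file Optional path; when given, a raster rendering is written
#'   there via [grDevices::png()].
#' @return A data.frame of class `section_image` with columns `row`, `col`,
#'   `x`, `y`, `cell_type` (`"B_A"`, `"B_B"`, `"non_B"`) and `intensity`,
#'   with counts recorded in attribute `"meta"`.
#' @examples
#' img <- render_section(0.4, seed = 7)
#' attr(img, "meta")
#' @export
render_section <- function(type_A_fraction, total_cells = 202,
                           b_cell_fraction = 0.8, stain_base = 0.85,
                           stain_sdlog = 0.3, seed = NULL, png_file = NULL) {
  if (!is_prob(type_A_fraction)) stop("`type_A_fraction` must be in [0, 1]")
  if (!is_prob(b_cell_fraction)) stop("`b_cell_fraction` must be in [0, 1]")
  if (!is_count(total_cells, min = 1)) {
    stop("`total_cells` must be a positive integer")
  }
  lattice <- hex_lattice(total_cells)
  n_b <- as.integer(round_half_away(b_cell_fraction * total_cells))
  n_a <- as.integer(round_half_away(type_A_fraction * n_b))
  with_seed(seed, {
    cell_type <- rep("non_B", total_cells)
    b_idx <- sample.int(total_cells, n_b)
    a_idx <- if (n_a > 0) sample(b_idx, n_a) else integer(0)
    cell_type[b_idx] <- "B_B"
    cell_type[a_idx] <- "B_A"
    intensity <- numeric(total_cells)
    intensity[a_idx] <- pmin(pmax(
      stain_base * stats::rlnorm(n_a, 0, stain_sdlog), 0), 1)
    out <- cbind(lattice,
                 data.frame(cell_type = cell_type, intensity = intensity,
                            stringsAsFactors = FALSE))
    class(out) <- c("section_image", "data.frame")
    attr(out, "meta") <- list(total_cells = total_cells, n_b_cells = n_b,
                              n_type_A = n_a, n_type_B = n_b - n_a,
                              n_non_b = total_cells - n_b,
                              type_A_fraction = type_A_fraction,
                              b_cell_fraction = b_cell_fraction,
                              seed = seed)
    if (!is.null(png_file)) {
      grDevices::png(png_file, width = 640, height = 640, bg = "black")
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(out$x, out$y, asp = 1, axes = FALSE, xlab = "", ylab = "",
           pch = 19, cex = 2.2,
           col = grDevices::rgb(0, out$intensity, 0))
    }
    out
  })
}
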