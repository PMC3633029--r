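# Independent oracles used across the suite. These deliberately share no
# code with the package internals: section probabilities are obtained by
# exhaustive enumeration of all C(M, m) sections.

# P(a uniformly drawn section of m of M cells contains at most l_max of the
# `special` marked cells), by enumerating every section.
enum_pure_prob <- function(M, m, special, l_max) {
  sections <- utils::combn(M, m)
  hits <- apply(sections, 2, function(idx) sum(idx <= special) <= l_max)
  mean(hits)
}

# round-half-away-from-zero, re-derived independently
oracle_round <- function(x) trunc(x + sign(x) * 0.5)

# Enumeration-based P_A(n, k) / P_B(n, k) (Eq. 5 / Eq. 6 structure):
# binomial founder weight times the enumerated section probability.
oracle_pure_A <- function(n, k, p, M, m, l_TB) {
  r <- oracle_round(k * M / n)
  choose(n, k) * p^k * (1 - p)^(n - k) * enum_pure_prob(M, m, r, l_TB)
}

oracle_pure_B <- function(n, k, p, M, m, l_TA) {
  s <- M - oracle_round(k * M / n)
  choose(n, k) * p^k * (1 - p)^(n - k) * enum_pure_prob(M, m, s, l_TA)
}

oracle_fixed_n <- function(n, p, M, m, l_TA, l_TB) {
  f_A <- sum(vapply(0:(n - 1), oracle_pure_A, numeric(1),
                    n = n, p = p, M = M, m = m, l_TB = l_TB))
  f_B <- sum(vapply(1:n, oracle_pure_B, numeric(1),
                    n = n, p = p, M = M, m = m, l_TA = l_TA))
  c(f_A = f_A, f_B = f_B, f_Mix = 1 - f_A - f_B)
}

# Convenience constructors for the paper-scale configuration.
paper_data <- function() observed_section_data(14, 6, 80, p = 0.21)
paper_geom <- function() section_geometry(5000, 200)
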