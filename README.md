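# gcfounders

Estimating the clonal diversity of germinal centers (GCs) from
immunohistological sections of two-phenotype chimeric animals.

## The problem

GCs are the micro-anatomical sites where B cells proliferate, hypermutate
and are selected during antibody responses. The number of B-cell clones
that found a GC cannot be observed directly. The classical indirect
estimate uses chimeric animals whose B-cell pool mixes two allotype-marked
populations (phenotype A at fraction *q*, phenotype B at *p* = 1 − *q*):
GC sections are scored pure-A, pure-B or mixed, and under the basic
binomial seeding model

```
f_A = q^n,   f_B = p^n,   f_Mix = 1 - q^n - p^n
```

one observed pure fraction is inverted to the founder number *n*. Applied
to the benchmark chimera dataset (*p* = 0.21; 14% / 6% / 80% pure-A /
pure-B / mixed) this gives the classical "oligoclonal" answer of 2–8
founders — but the model then mispredicts the remaining categories by
chi-square statistics of 132.6 and ~1.6 × 10⁵, so model and data are
mutually inconsistent.

`gcfounders` implements the consistency test and an extended model in
which a section shows only *m* of the GC's *M* B cells (hypergeometric
sampling), up to `l_TB` / `l_TA` minority cells are overlooked when
scoring a section pure (measurement error), and founder numbers vary
across GCs following a Poisson law with mean ⟨n⟩. The probability that a
GC seeded by *k* type-B founders among *n* yields a section scored pure-A
is

```
P_A(n,k) = C(n,k) p^k q^(n-k) * sum_{l = max(0, m-s)}^{min(l_TB, r)}
           C(s, m-l) C(r, l) / C(M, m)
```

with *r* = round(*kM/n*) type-B and *s* = *M* − *r* type-A cells, and
symmetrically for P_B. Fitting (⟨n⟩, l_TB, l_TA) by chi-square grid
search reconciles the same data with an average of **19–23 founders per
GC** — about an order of magnitude above the classical figure. The
package also provides Yule–Simon and ACE unseen-species estimators for
clone-abundance samples from single GC sections (the direct,
sequencing-based approach), a Monte-Carlo simulator that validates the
analytic probabilities, and a synthetic stained-section renderer.

## Worked example

```r
library(gcfounders)

observed <- observed_section_data(14, 6, 80, p = 0.21)

# 1. the basic model is internally inconsistent
table1_consistency_report(observed)
#> Internal-consistency check of the basic binomial model
#>   observed: pure-A 14%, pure-B 6%, mixed 80% (p = 0.21)
#>   reference pure-A: n = 8.341 (~8 founders)
#>     expected: A 14%, B 0.0002222%, Mix 86%
#>     chi2 = 161996 vs critical 10.83 (1 df, p = 0.001): INCONSISTENT
#>   reference pure-B: n = 1.803 (~2 founders)
#>     expected: A 65.38%, B 6%, Mix 28.62%
#>     chi2 = 132.624 vs critical 10.83 (1 df, p = 0.001): INCONSISTENT

# 2. the extended model fits the same data
geom <- section_geometry(M = 5000, m = 200)
grid_search(observed, geom)
#> Chi-square grid search over 3840 points (0 skipped)
#>   global minimum: chi2 = 0.004881 at <n> = 23, l_TB = 11%, l_TA = 64%
#>   top 5 local minima:
#>  lambda l_TB_pct l_TA_pct        chi2
#>      23       11       64 0.004880959
#>      19       10       62 0.026859048
#>      28       12       65 0.033093305
#>      20       10       63 0.056143278
#>      22       11       63 0.086244601
```

The two leading minima (⟨n⟩ = 23 and ⟨n⟩ = 19, chi-square 0.0049 and
0.027, both far below the 13.815 critical value at p = 0.001, 2 df) are
the fitted founder-number estimates; the associated scoring errors are
10–11% of the section for one population and 62–64% for the other —
plausible given that only one population is stained and 10–20% of GC
cells are unstained T cells.

```r
# 3. richness estimation for a clone-abundance sample of one GC section
tabulate_gc_estimates(list(B8 = abundance_sample(c(9, 5, 3, 2, 1, 1, 1, 1))))
#>   gc observed   yule_D yule_rho    ace_D flags
#> 1 B8        8 9.848262  1.90071 14.10929
```

Here 8 distinct clones were observed in a 23-cell sample; from the
singleton-heavy abundance pattern the Yule unseen-species estimator infers
roughly 10 clones in the sampled aggregate (with a heavy-tail exponent
rho ~ 1.9), ACE about 14. Estimates refer to the sampled aggregate only —
a small part of one section of a whole GC — so they are lower bounds on GC
diversity.

## Command line

```sh
Rscript -e 'gcfounders::gc_cli()' consistency --p 0.21 --A 14 --B 6 --Mix 80 --out-dir out
Rscript -e 'gcfounders::gc_cli()' fit --p 0.21 --A 14 --B 6 --Mix 80 --M 5000 --m 200 --out-dir out
Rscript -e 'gcfounders::gc_cli()' diversity --input clones.tsv --out-dir out
Rscript -e 'gcfounders::gc_cli()' simulate --lambda 23 --l-TB 22 --l-TA 128 --seed 1 --out-dir out
Rscript -e 'gcfounders::gc_cli()' render --type-A-fraction 0.4 --seed 1 --out-dir out
```

Every subcommand writes machine-readable JSON/TSV next to its console
report; stochastic runs echo their seed. `inst/cli/gcfounders` is an
equivalent `Rscript` launcher.

## Further reading

See the methods vignette
(`vignettes/estimating-gc-clonal-diversity.Rmd`) for the model's
assumptions, the numerical conventions (rounding of r = kM/n, Poisson
truncation, chi-square scale), the Yule estimator's two-stage likelihood
and its validation by parameter recovery, and known limitations.
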