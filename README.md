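# dcfsim

Structured-coalescent simulation and statistics for the question: **can
ancient population structure mimic Neandertal–human hybridization?**

Modern Eurasians share more derived alleles with Neandertals than Africans
do.  The two classic explanations are (i) hybridization after modern humans
left Africa and (ii) structure in the ancestral African population that
persisted across the Neandertal split.  Two statistics dominate the debate,
and this package computes both, from genotype tables or directly from
simulated genealogies:

* **Patterson's D** over a (chimp, Neandertal, African, European) panel:
  `D = (n_ABBA − n_BABA) / (n_ABBA + n_BABA)`, counted over biallelic sites
  where the Neandertal differs from the chimp and exactly one of the
  African/European chromosomes matches the Neandertal.
* **The doubly conditioned frequency spectrum (dcfs)**: over sites where
  the Neandertal differs from the chimp *and* the African chromosome
  carries the chimp allele, the distribution of the Neandertal-allele count
  `i = 1..nE` in a European panel (`nE = 10`, five diploids, by default).

The package is for population geneticists who want to explore how the
*spatial coarseness* of a demographic model changes what these statistics
can distinguish.  It provides three demographic models — a spatially
structured stepping-stone chain cut in two by the Neandertal split, a
two-population ancient-structure model, and a clean-split model with an
optional admixture pulse — an exact event-driven structured-coalescent
simulator (Rcpp), infinite-sites mutation dropping, an exact
(simulation-free) branch-expectation of D for the spatial model, and a
calibration layer that sweeps parameter grids, subsets them by
`|D − 0.0457| ≤ 0.0020` (the empirical African/European reference value and
window), and ranks them by R² against an observed dcfs.  A synthetic-data
module generates pseudo-observed spectra with multinomial sampling noise,
so the whole pipeline runs without any genome data.

The headline behaviour it reproduces: the fine-grained spatial model, with
**no hybridization**, matches the empirical D *and* produces dcfs shapes
rich in rare alleles — the very signature that a two-population
representation of ancient structure misses and that an admixture pulse
restores.  The dcfs therefore has limited power to separate the two
histories once structure is modelled at a finer spatial scale.

## A worked example

```r
library(dcfsim)

params <- spatial_params()        # documented defaults, k = 10 demes
demog  <- build_spatial_model(params)
demog
#> <demography> spatial model: 16 demes, 79 events
#>   free parameters (8): k_demes, n_anc, m0, n_mod, m, t_modern, t_exit, founder_size
#>   outgroup split: 240000 generations

# exact branch-expectation Patterson's D (no simulation, no MC noise)
expected_patterson_d(params)$d
#> [1] 0.04588

# a pseudo-observed dcfs: 20,000 doubly conditioned loci drawn from the
# model's own branch-length expectation
po <- generate_pseudo_observed(
  pseudo_observed_spec(params, n_dc_sites = 20000, n_trees = 20000, seed = 1))
po$dcfs
#> <dcfs> 10 classes, weight 20000
#>      1      2      3      4      5      6      7      8      9     10
#> 0.1608 0.1342 0.1169 0.1096 0.1088 0.0932 0.0819 0.0637 0.0652 0.0658

# sweep the ancestral migration rate and rank by fit to the observed dcfs
spec    <- sweep_spec(params, grid = list(m0 = params$m0 * 4^(-1:1)),
                      n_trees = 20000, seed = 2)
records <- run_sweep(spec)
rank_by_r2(records, po$dcfs)[, c("m0", "d", "r2")]
#>         m0       d   r2
#> 3 8.40e-04 -0.0178 97.7
#> 2 2.10e-04  0.0259 96.3
#> 1 5.25e-05  0.0661 91.2
```

The spectrum decreases from class 1 (16% of doubly conditioned loci are
singletons in the European panel) to the top classes — the rare-allele-rich
shape.  The `d` column above is the Monte Carlo branch estimate, whose
standard error at 20,000 trees (≈0.01) is wider than the 0.0020 subsetting
window; that is why the D filter in the calibration workflow is applied to
the exact expectation:

```r
m0_grid <- params$m0 * 4^(-2:2)
d_exact <- sapply(m0_grid, function(m0)
  expected_patterson_d(spatial_params(m0 = m0))$d)
round(d_exact, 5)
#> [1] 0.07745 0.06916 0.04588 0.01264 0.00032
abs(d_exact - 0.0457) <= 0.0020
#> [1] FALSE FALSE  TRUE FALSE FALSE
```

The calibrated default (`m0 = 0.00021`) predicts D within 0.0002 of the
empirical value with no hybridization in the model at all.  See the
vignette (`vignettes/dcfs-methods.Rmd`) for the models, the exact-D
computation, and every default's rationale; `inst/cli/dcfsim.R` is a thin
command-line wrapper (simulate / dcfs / dstat / calibrate / synth) over the
same functions.

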