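# gbsdiv

Genetic diversity analysis of highly incomplete SNP genotype data — an
empirical-assessment toolkit.

Genotyping-by-sequencing (GBS) delivers genome-wide SNP genotypes for
diversity panels at low cost, but with up to 90% of the genotype calls
missing and, for non-model organisms, no marker order to lean on for
haplotype-based imputation. Anyone running a routine diversity analysis on
such data must decide, at every missing level, between analysing the
incomplete matrix with missing-aware estimators and imputing genotypes
first with a map-independent method. `gbsdiv` provides the machinery to
make that comparison empirically, for curators and population geneticists
working with crop or other germplasm panels:

* **Missing-data simulation** — mask a prescribed fraction of all cells
  uniformly at random (`apply_random_missing`), and draw the
  lines × markers subsamples used by each assessment run
  (`subsample_genotypes`).
* **Three map-independent imputers** — random-forest regression
  (`impute_rf`), probabilistic PCA fitted by EM over observed entries
  (`impute_ppca`), and NIPALS PCA whose regressions skip missing cells
  (`impute_nipals`), each followed by the genotype binning rule
  (`bin_estimates`: estimate ≤ 1.5 → genotype 1, (1.5, 2.5] → 2,
  > 2.5 → 3).
* **Missing-aware diversity statistics** — per-locus allele frequencies
  from observed genotypes only, pooled observed/expected heterozygosity
  and inbreeding coefficient (`het_stats`: Ho = N₂/n, He = 1 − p² − q²,
  F = (He − Ho)/He), and one-level AMOVA Φst on squared allele-count
  distances with an L/L_valid rescaling that compensates missing loci
  (`amova_phi`: Φst = Va/(Va + Vw)).
* **Topology accuracy** — simple-matching distances (`smc_distance`),
  neighbor-joining trees (`nj_tree`), and unrooted four-taxon splits with
  a tie-to-star rule (`quartet_split`, `same_topology`) for one
  representative line per group.
* **An assessment harness** (`run_assessment`) sweeping missing levels ×
  methods × simulation runs, reporting means, SDs, relative biases versus
  each run's own original subsample, topology accuracy and an
  imputation-accuracy breakdown by original genotype class.
* **A synthetic generator** (`generate_population`, `crop_preset`) with
  Balding–Nichols group differentiation, an inbreeding F-model and three
  minor-allele-frequency regimes, emulating maize-, rice- and wheat-like
  diversity panels so everything above is testable without downloads.

## A worked example

```r
library(gbsdiv)

pop <- generate_population(crop_preset("wheat", n_markers = 2000, seed = 1))
het_stats(pop$genotypes)
#> diversity_summary over 2000 loci: Ho = 0.0030 (0.30%), He = 0.1501, F = 0.9768
amova_phi(pop$genotypes, pop$groups)
#> AMOVA: 340 lines in 4 groups
#>   SS among  =   4132.056 (df = 3)
#>   SS within = 197953.882 (df = 336)
#>   Va = 9.2730, Vw = 589.1485, Phi_ST = 0.0155 (1.55%)

at <- run_assessment(pop$genotypes, pop$groups,
  assessment_config(missing_levels = c(0.1, 0.5, 0.9), n_runs = 10,
                    n_lines = 60, n_markers = 300,
                    methods = c("NONE", "PP"), seed = 1))
at
#> assessment_table: 3 level(s) x 3 method(s), 10 run(s); 0 failed
#>   missing_level   method  ho_mean he_mean f_mean phi_st_mean topology_accuracy
#> 1           0.1     NONE 0.002879  0.1499 0.9758    0.014926                70
#> 2           0.1 ORIGINAL 0.002872  0.1497 0.9760    0.015009                NA
#> 3           0.1       PP 0.012867  0.1435 0.9401    0.014199                70
#> 4           0.5     NONE 0.003071  0.1488 0.9747    0.020449                60
#> 5           0.5 ORIGINAL 0.003206  0.1520 0.9734    0.015658                NA
#> 6           0.5       PP 0.059617  0.1240 0.7130    0.016530                60
#> 7           0.9     NONE 0.002960  0.1226 0.9711    0.006961                30
#> 8           0.9 ORIGINAL 0.003067  0.1478 0.9754    0.014231                NA
#> 9           0.9       PP 0.092539  0.1368 0.3123    0.009379                20
#>   m_pct_mean
#> 1        NaN
#> 2        NaN
#> 3      82.93
#> 4        NaN
#> 5        NaN
#> 6      80.94
#> 7        NaN
#> 8        NaN
#> 9      78.16
```

Reading the table: this wheat-like panel is almost completely selfing
(Ho ≈ 0.3%, F ≈ 0.98) with mild four-group structure (Φst ≈ 1.5%).
Without imputation (`NONE`) the expected heterozygosity estimate drifts
downward as missingness grows (0.150 → 0.123 at 90% missing) while Φst
stays level-invariant within noise — the missing-aware distance rescaling
at work. Imputation (`PP`) fills cells convincingly (≈ 80% of masked
genotypes recovered) yet inflates observed heterozygosity by an order of
magnitude and collapses the inbreeding coefficient (0.98 → 0.31 at 90%
missing): high per-cell accuracy does not translate into unbiased
diversity estimates. Topology accuracy of the four group representatives
decays with the missing level. `write_assessment(at, dir)` exports
`summary.csv`, `per_run.csv` and `accuracy.csv`.

A command-line front end with `simulate`, `mask`, `impute`, `stats`,
`tree` and `assess` subcommands is installed at
`system.file("cli", "gbsdiv", package = "gbsdiv")`.

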