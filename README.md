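# sompmf

Disentangling multiannual, multisite air-quality panels in a single
elaboration: a batch **self-organizing map** (SOM) compresses hourly
pollutant data (benzene, toluene, PM10, NO, NO2) into a codebook of
recurrent profiles; **Ward clustering** with **Davies–Bouldin** model
selection classifies the codebook into "air types"; per-sample
**quantization errors** flag outlier events such as desert-dust
intrusions; and uncertainty-weighted **positive matrix factorization**
(PMF) with bootstrap validation — run on the codebook, not the raw data —
apportions emission sources.  The package is aimed at air-quality and
chemometrics practitioners who need to screen several years and several
stations at once without splitting the data first.

## The method in brief

For a panel $X$ (site-hours × 5 pollutants, autoscaled), batch SOM
training iterates

$$m_i \leftarrow \frac{\sum_j h_{c(j),i}\,x_j}{\sum_j h_{c(j),i}},\qquad
h_{c,i} = e^{-d^2(c,i)/2\sigma^2},$$

on a hexagonal grid sized by the $5\sqrt{N}$ heuristic (41 × 22 = 902
nodes at the intended scale of ~32,000 site-hours).  The codebook is cut
into $k$ air types by Ward (`ward.D2`) linkage, $k$ chosen by the
Davies–Bouldin index over $k = 2..10$.  PMF factorizes the
concentration-scale codebook as $X \approx GF$, $G, F \ge 0$, minimizing
$Q = \sum_{ij}((x_{ij} - (GF)_{ij})/u_{ij})^2$ with
$u_{ij} = \max(\mathrm{rel}_j x_{ij}, \mathrm{floor}_j)$ (defaults: 10.9%
Ben/Tol, 10% PM10, 6.2% NO/NO2).  The factor count is scanned over 4..6
and selected by bootstrap/replication stability.  A seeded synthetic
generator with five planted sources and six planted activity regimes
serves as the recovery oracle for the whole chain.

## Worked example

```r
library(sompmf)

sim <- simulate_panel(sim_config(), seed = 1)   # the synthetic world
sim$panel
#> <aq_panel> 32256 site-hours, 4 sites (A1, A2, B1, B2)
#>   variables: Ben, Tol, PM10, NO, NO2
#>   span: 2018-03-09T00:00 .. 2023-05-03T23:00
#>   missing cells: 3139

res <- run_pipeline(sim$panel, grid = som_grid(12, 8), epochs = 40,
                    n_starts = 10, n_boot = 30, seed = 1)
res$som
#> <som_model> 12 x 8 hexagonal, 96 nodes, scale=autoscaled
#>   qe=0.3072  te=0.0787  dme=0.1844
res$clusters
#> <cluster_solution> k=6 (Davies-Bouldin 0.6555)
#>   sizes: 24, 22, 16, 15, 13, 6
res$pmf_scan$table[, c("k", "Q", "q_ratio", "min_cold_rate", "stable")]
#>   k            Q  q_ratio min_cold_rate stable
#> 1 4 2.533598e+02 3.333681           1.0   TRUE
#> 2 5 4.794414e-07       NA           1.0   TRUE
#> 3 6 4.727368e-07       NA           0.2  FALSE
round(res$fingerprint, 1)
#>          Ben  Tol PM10   NO  NO2
#> factor1 20.5 60.9 18.3  1.1  5.5
#> factor2  3.4  1.4 60.9  2.4  4.7
#> factor3 54.7 26.3  5.1  1.9  2.2
#> factor4  8.6  5.3  7.1  2.0 52.4
#> factor5 12.8  6.0  8.6 92.6 35.2
sum(res$outlier_flags)
#> [1] 2238
```

Reading the output: the SOM compressed ~32k hours into 96 recurrent
profiles with mean quantization error 0.31 (autoscaled units) and 7.9%
topographic error; Davies–Bouldin selects six air types (the generator
planted six regimes); the factor scan keeps five factors — six is
rejected because cold restarts reproduce its factors in only 20% of runs —
and the species fingerprint identifies them: a toluene-rich mixed source
(factor 1), near-pure PM10 dust (2), the benzene/toluene industrial
source (3), NO2-dominated aged combustion (4) and NO-dominated traffic
(5), matching the five planted profiles.  `res$crosstab` links each factor
to the air-type cluster its top-contributing nodes occupy, and
`res$outliers` lists the flagged hours (the injected dust episodes top
the ranking) with their timestamps and clusters.

A command-line front end with `simulate`, `preprocess`, `som`, `cluster`,
`pmf` and `report` subcommands lives at
`system.file("scripts/sompmf-cli.R", package = "sompmf")`.

## Package layout

* `R/panel.R`, `R/impute.R`, `R/scale.R` — panel I/O, cleaning, iterative
  PCA imputation, autoscaling
* `R/grid.R`, `R/som.R` — hex grids, map-size heuristic, batch SOM,
  quality metrics, U-matrix, QE outliers
* `R/cluster.R` — Ward linkage, Davies–Bouldin selection, cluster tests
* `R/pmf.R` — uncertainties, weighted-NMF PMF solver, factor-count scan,
  bootstrap, fingerprints, factor–cluster crosstabs
* `R/report.R` — daily cluster prevalence and outlier timelines
* `R/simulate.R` — the seeded synthetic world
* `vignettes/air-type-source-apportionment.Rmd` — models, assumptions,
  numerical choices, limitations
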