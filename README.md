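# dcindex

Quantifying how consistently a population of unmarked animals uses an array
of sites over time.

Wildlife surveys routinely yield a site-by-time matrix of counts — how many
individuals were seen at each territory, shoreline stretch, or point-count
station in each year. Two populations with identical densities can differ
profoundly in *where* those individuals are from year to year: one reuses
the same sites, the other reshuffles. **Distributional consistency (DC)**
scores that temporal stability on a 0–1 scale while controlling for changes
in regional population size, needing no marked individuals. It is aimed at
survey biologists, movement ecologists, and managers who want a
fidelity-like signal out of ordinary survey data.

## The index

For a matrix with $y$ time steps and per-step population sizes $N_t$ (row
sums), and for each level of consistency $k = 2, \dots, y$:

* $M_k = \sum_i \min_{t \in i} N_t$ over all $\binom{y}{k}$ subsets $i$ of
  time steps — the maximum possible instances of $k$-step consistent site
  use, given the observed population sizes;
* $O_k$ — the observed instances: per site, with counts sorted
  $c_{(1)} \ge \dots \ge c_{(y)}$, exactly $c_{(k)} - c_{(k+1)}$ individual
  slots were occupied in exactly $k$ steps; summed over sites;
* $\bar O_k = \sum_{q \ge 0} O_{k+q} \binom{k+q}{k}$ — observed instances
  adjusted for patterns nested inside higher levels (equivalently: the sum
  over sites and $k$-subsets of the minimum count in the subset);
* $R_k = \bar O_k / M_k$, and $\mathrm{DC} = \operatorname{mean}_k R_k$
  over the levels with $M_k > 0$.

DC is 1 for a population that occupies exactly the same sites every step, 0
when no site is ever reused, and is invariant to the ordering of rows and
columns, to never-used sites, and to uniform count scaling. Presence/absence
surveys of territorial species are handled by the same code path as counts
of grouped individuals.

Beyond the index itself the package provides multi-scale analysis
(`aggregate_sites()`, `subset_region()`, `dc_scale_curve()`), Monte Carlo
studies of survey-error robustness with a regression-based correction for
presence/absence data (`run_group_error_study()`,
`run_territorial_error_study()`, `correct_dc()`), a dispersal simulation
linking individual movement rates to DC (`simulate_dispersal()`, whose
fitted regression `predict()`s dispersal rates from measured DC), delimited
text I/O (`read_survey_matrix()`), and a command-line interface
(`dc_cli()`, wrapped by `inst/cli/dcsurvey`).

## Worked example

A 4-year presence/absence survey of 16 territories with yearly populations
9, 9, 8, 8 (shipped both as `dc_example_matrix("territorial")` and as
`inst/extdata/territorial_example.csv`):

```r
library(dcindex)
fit <- dc(dc_example_matrix("territorial"))
summary(fit)
#> Distributional consistency: per-level decomposition
#>   (M = maximum possible instances, O = observed, O_adj = observed
#>    adjusted for nesting in higher levels, R = O_adj / M)
#>
#>  k  M O O_adj      R
#>  2 49 7    25 0.5102
#>  3 32 4     8 0.2500
#>  4  8 1     1 0.1250
#>
#> DC = 0.2951
```

Reading the table: across the 6 possible year pairs, at most 49 instances
of two-year site reuse were possible given the yearly populations, and 25
were realised (7 sites used in exactly two years, plus the pairs nested in
the 3- and 4-year sites), so $R_2 = 25/49 \approx 0.51$; one site was used
in all four years out of a possible 8, so $R_4 = 0.125$. The mean of the
three ratios gives DC = 0.295 — a rather inconsistent distribution.

Estimating a dispersal rate from survey data:

```r
sim <- simulate_dispersal(dispersal_rates = c(0.1, 0.3, 0.5), n_reps = 5,
                          seed = 11)
sim
#> DC dispersal simulation
#>   100 individuals, 100 sites, 25 steps (DC over last 10), 5 reps x 3 rates
#>   1/DC = 0.9284 + 7.708 * rate   (R^2 = 0.9872)
predict(sim, c(0.8, 0.4, 0.2))  # DC values -> implied per-step dispersal
#> [1] 0.042 0.204 0.528
```

The same computations from the shell:

```sh
inst/cli/dcsurvey dc --input inst/extdata/territorial_example.csv
inst/cli/dcsurvey simulate --study dispersal --seed 1 --output dispersal.csv
```

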