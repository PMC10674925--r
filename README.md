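# adheretraj

Longitudinal medication-adherence trajectories from pharmacy dispensing
records.

Claims and dispensing databases record *when* a patient picked up a drug and
*how many days of supply* they received, but not whether they took it. A
single annual adherence number (a proportion of days covered) hides the
dynamics that matter clinically: a patient who refills perfectly for six
months and then stops looks identical to one who refills erratically all
year. `adheretraj` implements the trajectory view for incident users of a
chronic medication (the motivating case is sacubitril/valsartan in heart
failure, ATC C09DX04):

1. **CMA9 adherence estimation.** For each patient, every inter-refill
   interval `[t_i, t_{i+1})` is assigned the availability ratio
   `r_i = min(1, s_i / (t_{i+1} - t_i))`, where `s_i` is the supply dispensed
   at `t_i` plus carryover from the previous interval; excess supply
   `max(0, s_i - (t_{i+1} - t_i))` carries forward, and supply that would run
   past the end of the 365-day observation window is discarded. Overall
   CMA9 is the mean daily ratio; the trajectory is its mean in 12 contiguous
   30-day windows.
2. **Group-based trajectory modeling.** The 12-dimensional window vectors
   are clustered with k-means for longitudinal data (k-means++ starts,
   Lloyd iterations, empty-cluster re-seeding), and the number of groups is
   chosen by maximizing the Calinski–Harabasz criterion
   `CH = (B/(k-1)) / (W/(n-k))` over k = 2…6. Clusters are labeled
   `high`, `partial_drop_off`, `moderate`, `low` by deterministic rules on
   their centroids.
3. **Group profiling.** Age-adjusted Charlson comorbidity index (weights
   1/2/3/6 plus age-decade points), polypharmacy classes (≤4 / 5–9 / ≥10
   drugs), persistence (days on treatment under a 30-day grace rule), and
   switching to other heart-failure drug classes (C03/C07/C09) binned by
   time from the index date.
4. **Determinants of membership.** Multinomial logistic regression of group
   membership (reference: high adherence) with forward-backward stepwise
   selection on likelihood-ratio tests at p < 0.05, reported as odds ratios
   with Wald 95% CIs and a forest plot.

Because real regional claims databases cannot be redistributed, the package
ships a seeded **synthetic-cohort generator** whose four refill archetypes
are calibrated so the group CMA9 means land on 0.91 / 0.63 / 0.54 / 0.17,
whose mixture weights are 42.6 / 19.6 / 19.3 / 18.4 %, and whose group
membership follows a multinomial logit with plantable covariate effects —
so the entire pipeline is testable end to end.

## Worked example

```r
library(adheretraj)

res <- run_pipeline(generator = generator_config(2000, seed = 7), seed = 7)
res
#> Adherence-trajectory pipeline run
#>   patients: 2000 | selected k: 4
#> # A tibble: 4 x 5
#>   label                n   pct cma_mean cma_sd
#>   <chr>            <int> <dbl>    <dbl>  <dbl>
#> 1 high               862  43.1    0.908 0.0397
#> 2 partial_drop_off   411  20.6    0.618 0.0785
#> 3 moderate           357  17.8    0.538 0.0344
#> 4 low                370  18.5    0.169 0.0199
```

Four trajectory groups are recovered: 43.1 % of patients keep near-complete
medication availability all year (mean CMA9 0.908); 20.6 % start high and
drop off after about six months (0.618); 17.8 % hover around half coverage
(0.538); 18.5 % stop after one or two fills (0.169). `res$clusters$ch_by_k`
shows the Calinski–Harabasz score peaking at k = 4, `res$group_summary`
adds persistence and switching columns, and `res$effects` holds the
odds-ratio table of the stepwise multinomial model.

Individual stages compose with the pipe:

```r
co   <- generate_cohort(generator_config(500, seed = 1))
traj <- cma_trajectories(co$events, cohort = co$patients)
fit  <- select_k(traj, seed = 1)
tidy(fit)                  # per-cluster sizes and centroid means
autoplot(fit, traj)        # spaghetti plot by group
```

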