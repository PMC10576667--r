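# presymscan

Geo-epidemiology of the years *before* clinical onset. Many
neurodegenerative diseases — amyotrophic lateral sclerosis is the motivating
case — have a pathogenic process that begins years or decades before the
first symptom. A spatial cluster analysis of where patients live *at
diagnosis* can therefore miss the places where the relevant exposures
happened. `presymscan` implements the full pipeline for scanning a cohort's
**residential histories** backwards in time:

1. **Location at offset** — for each patient, the municipality of residence
   exactly *k* years before their onset (k = 0…50), from interval-coded
   residence records.
2. **Population at risk** — because onsets are asynchronous, the population
   assigned to offset *k* is the mean of the populations of the distinct
   calendar years `onset year − k` observed in the cohort. Early totals
   exist only at census years (1951/1961/1971/1981) and are imputed by
   spreading each inter-census difference evenly across the interval;
   later years carry full sex × age strata
   (0–24, 25–34, …, 75–84, ≥85) and expected counts are obtained by
   indirect standardization. Offsets whose contributing years lack strata
   fall back to a crude rate.
3. **Circular spatial scan** — a Kulldorff-type scan over circles of
   growing radius around every municipality centroid, capped at 25% of the
   population at risk, using the conditional Poisson log-likelihood ratio

   `LLR = c·log(c/E) + (C−c)·log((C−c)/(C−E))`, `RR = (c/E) / ((C−c)/(C−E))`

   with observed in-zone cases `c`, expected `E`, total `C`. Significance
   comes from Monte Carlo replication (default R = 999) of the case map
   under the expected-count multinomial; `p = (1 + #{replicate max ≥
   observed}) / (1 + R)`. High- and low-incidence scans run as separate
   tracks, and secondary clusters are reported non-overlapping.
4. **Dwelling co-occurrence null** — a bespoke Monte Carlo for the
   observation that several *unrelated* patients had lived in the same
   dwelling: patients are repeatedly reallocated over a city's dwelling
   stock with probability proportional to resident capacity (each patient
   drawing 3–4 distinct dwellings, mean 3.6, never the same one twice),
   and the number of dwellings receiving exactly two / exactly three
   distinct patients is tallied per iteration (default 2000). Tail
   probabilities of the observed pair/trio counts follow, with a
   capacity-stratified restriction analysis (e.g. excluding the top 20%
   of co-occurrence dwellings by capacity and re-running the null on the
   restricted stock).
5. **Synthetic registries** — generators for a region (heavy-tailed
   municipality sizes, one metropolis, census-structured counts), a cohort
   (per-offset residence multinomial with an optionally implanted
   elevated-risk zone active in a chosen pre-onset window, realistic move
   process and history truncation) and a city dwelling registry
   (heavy-tailed capacities summing exactly to the configured residents),
   so the whole pipeline can be exercised and validated without
   confidential registry data.

## Worked example

Implant a 2.5× risk zone active 2–9 years before onset, then scan at
onset and at offset 5:

```r
library(presymscan)
reg <- generate_region(n_municipalities = 40, total_population = 400000,
                       growth_sd = 0, sdlog = 0.8, seed = 2024)
cl  <- cluster_spec(c("M0007", "M0019", "M0017", "M0022"),
                    multiplier = 2.5, window = c(2, 9))
coh <- generate_cohort(reg, n_cases = 1200, cluster = cl, seed = 7)
ts  <- timeshift_scan(coh$patients, coh$residences, reg$population,
                      reg$municipalities, offsets = c(0, 5), R = 999,
                      seed = 11)
ts
#> Time-shifted scan over offsets 0-5 years before onset
#>  offset center n_members   c      E    RR     p
#>       0  M0037         1  41  29.88 1.385 0.822
#>       5  M0007         4 333 165.38 2.411 0.001
```

At onset (offset 0, outside the implanted window) the most likely cluster
is an unremarkable fluctuation (p = 0.82); at offset 5 the scan recovers
exactly the four implanted municipalities, with 333 observed cases against
165.4 expected (RR 2.41, p = 0.001). The LLR/RR arithmetic on the printed
counts of a real cluster — 150 observed, 105 expected, 1124 total — gives
`relative_risk(150, 105, 1124)` = 1.4946 (1.49 at two decimals) and
`poisson_llr(150, 105, 1124)` = 9.51.

The dwelling null at city scale (39,184 dwellings housing 870,474
residents, 373 patients, 2000 iterations) runs in about a second:

```r
regis <- generate_dwelling_registry(seed = 5)   # mean capacity 22.2
null  <- run_null(regis, n_patients = 373, R = 2000, seed = 8)
null
#> Dwelling co-occurrence null: 2000 iterations, 373 patients over 39184 dwellings
#>   pair-dwellings:  mean 49.27  range 25-80
#>   trio-dwellings:  mean 2.98  range 0-10
cooccurrence_probability(null, observed_pairs = 51, observed_trios = 3)
#> P_pairs P_trios
#>  0.4135  0.5755
```

Observing 51 pair-dwellings is unremarkable against this synthetic stock
(P = 0.41). The restriction analysis asks the sharper question — were the
co-occurrences in *small* dwellings?  Excluding the top 20% of the 51
observed pair-dwellings by capacity leaves 41 of them, sets the capacity
ceiling at the largest kept dwelling, and re-runs the null over the
restricted stock only (`restrict_and_rerun()`), typically shrinking the
tail probability sharply when the observed co-occurrences sit below the
capacities that generate chance pairs.

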