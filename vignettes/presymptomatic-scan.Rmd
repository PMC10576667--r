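---
title: "Scanning residential histories for presymptomatic disease clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning residential histories for presymptomatic disease clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presymscan)
```

## The problem

For diseases whose pathogenic process precedes the clinical onset by years
— motor neuron disease is the archetype — the residence at diagnosis is a
poor proxy for where an environmental exposure may have acted. This
package analyses a cohort's *residential histories*: for every offset
$k = 0, 1, \dots, 50$ years before each patient's onset it asks where the
cohort lived, reconstructs the matching population at risk, and runs a
circular spatial scan. A second, finer-grained analysis asks whether
unrelated patients co-resided in the same *dwellings* more often — or in
smaller dwellings — than a capacity-weighted chance model predicts.

## Locations at an offset

A history is an ordered, non-overlapping, gap-free set of intervals
(dwelling, municipality, start, end). The location at offset $k$ is the
municipality of the interval containing the date exactly $k$ calendar
years before onset; February 29 maps to February 28 in non-leap years (the
date arithmetic is otherwise undefined, and this convention loses at most
one day). Histories that do not reach back $k$ years yield a missing
location: those patients are dropped from the numerator at that offset,
and the population denominator is *not* reduced — no correction for
differential missingness is attempted, because the missingness mechanism
of a real registry is unknown. Reported completeness profiles
(`completeness_profile()`) make the extent of this visible per offset.

## Populations at risk and expected counts

Onsets are asynchronous, so offset $k$ maps each patient to calendar year
$\text{onset year} - k$. The population at risk at offset $k$ is the
unweighted arithmetic mean of the populations of the *distinct* calendar
years so obtained. The unweighted-over-distinct-years reading is the
package default; a patient-count-weighted mean is available
(`weight_years = TRUE`) because the two readings differ slightly whenever
the onset-year distribution is uneven.

Census material is sparse early on: totals exist only at the census years
(1951, 1961, 1971, 1981 by default) and intermediate years are imputed by
spreading each inter-census difference evenly across the interval —
piecewise-linear interpolation that reproduces the anchors exactly.
Interpolated values are carried as reals; expected counts are real-valued
anyway, and rounding would break the conservation property below.

From 1982 onwards full sex × age-class strata
(0–24, 25–34, 35–44, 45–54, 55–64, 65–74, 75–84, ≥85) are available and
expected counts use indirect standardization: global stratum rates
$r_s = \text{cases}_s / \text{pop}_s$ applied to each municipality's
stratum populations, $E_i = \sum_s \text{pop}_{is} r_s$. When rates are
derived from the same snapshot, $\sum_i E_i$ equals the case total to
floating precision — the conservation the scan's conditional null
requires. The crude-versus-adjusted switch is all-or-nothing per offset:
if *any* contributing calendar year lacks strata the whole offset uses a
single crude rate, since mixing adjusted and crude expectations across
years within one offset has no defensible definition.

## The circular scan

Candidate zones are circles around each municipality centroid: the
municipalities sorted by centroid distance, accumulated while the zone
population stays within a cap (default 25% of the total at risk).
Distance ties are ordered by municipality id for determinism, but a zone
boundary never splits a tie group — every reported zone is exactly the
set of centroids within its radius. Duplicate member sets from different
centers are merged. Coordinates are planar meters by default; a lon/lat
mode with great-circle distances is available.

The test statistic is the conditional Poisson log-likelihood ratio
$$\mathrm{LLR} = c \log\frac{c}{E} + (C - c)\log\frac{C - c}{C - E},$$
gated by direction (high: $c > E$; low: $c < E$) with the $0\log 0 = 0$
convention, maximized over zones. Monte Carlo replicates redistribute the
$C$ cases over municipalities with probabilities $E_i / C$ — the standard
conditional null for this statistic — and
$p = (1 + \#\{\text{replicate max} \ge \text{observed}\}) / (1 + R)$ with
$R = 999$ by default. High and low scans are separate tests by default
(two result tracks) because excess and deficit clusters are distinct
scientific claims; secondary clusters are reported in descending LLR among
zones disjoint from all higher-ranked ones, each compared against the same
null-max distribution.

Offsets are processed independently: one master seed spawns a per-offset
replicate seed (reported in the output, so any single offset can be
reproduced alone), and no multiplicity correction is applied across the 51
offsets — the per-offset p-values are reported as such and should be read
accordingly.

## The dwelling co-occurrence null

The sharper, dwelling-level analysis needs its own chance model: given a
city's dwelling stock (identifier and resident capacity), what is the
probability that reshuffled patients produce the observed number of
dwellings housing exactly two, or exactly three, distinct patients?

Each simulated patient draws an address count from a configurable law —
default $3 + \mathrm{Bernoulli}(0.6)$, i.e. 3 or 4 addresses with mean
3.6, matching the observed mean number of address changes; a fractional
mean number of "rounds" has no direct sampling interpretation, so it is
realized as this two-point law, and any empirical address-count
distribution can be substituted. The patient then occupies that many
*distinct* dwellings, each draw with probability proportional to resident
capacity; a draw landing on a dwelling already held is redrawn. The
redraw-on-collision rule is distributionally identical to successive
capacity-weighted sampling without replacement, and the test suite checks
the simulated pair/trio distributions against exact enumeration of that
scheme on small configurations. Capacity acts purely as a sampling
weight: simulated rounds are not aligned in time, so no hard simultaneous
occupancy cap is imposed.

Tail probabilities use the raw convention $P = \#\{\text{iterations with
count} \ge \text{observed}\}/R$ by default — so $P$ can reach 0 and
equals 1 at observed 0 — with a $+1$-corrected variant available.

The restriction analysis stratifies by dwelling size: in quantile mode the
top fraction of *observed* co-occurrence dwellings by capacity is excluded
(exclusion count rounded down — excluding the top 20% of 51 dwellings
removes 10 and keeps 41 — with capacity ties broken toward exclusion of
the larger, then by identifier), the ceiling is the largest kept capacity,
observed counts are recounted among dwellings at or below the ceiling, and
the null is re-simulated over the restricted stock only. In a sparse
stock, chance co-occurrences concentrate in large dwellings (pair mass
scales with squared capacity share), so observed co-occurrences that sit
in small dwellings become *less* probable as the ceiling tightens — the
phenomenon the restriction is designed to expose. The converse can hold in
dense configurations (few dwellings per patient), where removing a
dominant dwelling redistributes collisions into pairs; the monotonicity
test fixture is deliberately sparse for this reason.

## What the synthetic generators emulate

The generators provide study-shaped inputs, not copies of any real
registry:

* **Region** (`generate_region`): heavy-tailed (log-normal) municipality
  sizes with one metropolis forced to ~20% of the regional total
  (mirroring a region dominated by one city); totals at decadal census
  years then annual; a *single regional* sex/age pyramid applied to every
  municipality. The shared pyramid keeps indirect standardization
  exercised while making municipality totals a sufficient statistic for
  case locations; per-municipality pyramids would add realism but no new
  code paths. All counts are integer and conserve the configured totals
  exactly (largest-remainder apportionment).
* **Cohort** (`generate_cohort`): onset years uniform over the study
  window; sex/age strata drawn from pyramid × incidence weights (default
  late-peaked, male-skewed); genetic status with ~9% known positives and
  ~19% missing. Residential trajectories are built backwards from onset:
  at each offset the marginal municipality distribution is exactly
  multinomial with probabilities ∝ population (× the implanted
  relative-risk multiplier inside the cluster's member set during its
  active window). Temporal coherence comes from a yearly move hazard
  ($1 - e^{-1/\text{mean stay}}$, mean stay 50/3.6 years so a full
  history averages 3.6 changes) combined with a maximal-coupling
  carry-over step between consecutive offsets: movers redraw from the new
  target, stayers keep their municipality with probability
  $\min(1, \pi_k(m)/\pi_{k-1}(m))$ and otherwise redraw from the excess
  mass. The coupling preserves the per-offset multinomial *exactly* —
  which is what the recovery and calibration tests rely on — at the cost
  of a small number of extra moves concentrated at window boundaries.
  Histories are left-truncated by a missingness curve (defaults 0.6% at
  onset, 10.5% at 40 years, 19.7% at 50, linearly interpolated) and never
  precede birth.
* **Dwelling registry** (`generate_dwelling_registry`): log-normal
  capacities, each ≥ 1, apportioned to sum exactly to the configured
  residents (defaults 39,184 dwellings, 870,474 residents, mean ≈ 22.2).

What passing tests on these fixtures do *not* show: real census counts
are not largest-remainder-perfect; real pyramids vary by municipality (so
real standardization shifts expected counts in ways the shared-pyramid
fixtures cannot produce); real move processes are age- and
life-course-structured rather than memoryless; and real dwelling-capacity
distributions are not log-normal. The fixtures validate the machinery and
its statistical calibration, not any substantive claim about a real
region.

## Numerical and design choices

* Apportionment of continuous shares to integer counts uses the
  largest-remainder rule with positional tie-breaks — deterministic and
  exactly conserving.
* Zones with $E \le 0$ or $E \ge C$ score LLR 0 rather than erroring
  inside the vectorized scan (the exported scalar `poisson_llr()` keeps
  the strict contract); they cannot be clusters.
* `scan_once()` requires $\sum E = C$ to 10⁻⁶ relative — a violated
  conservation indicates a standardization bug upstream and is refused,
  not repaired.
* A municipality whose own population exceeds the zone cap yields no
  zone; this is reported as a warning, not an error, because it is
  expected in very small regions.
* Dwellings with four or more patients are counted in their own bucket,
  never folded into trios.
* Patients with missing genetic status remain eligible for
  shared-dwelling counting by default (only known positives are
  excluded); `include_missing_genetic = FALSE` tightens this.
* Seeds are mandatory wherever randomness enters; derived per-offset
  seeds stay below $2^{31}$.

## Problem sizes

The shipped tests run the calibration study at 400 null datasets
(40 municipalities, 300 cases, $R = 199$), the recovery study at 20
seeds (1200 cases, multiplier 2.5, window 2–9, $R = 999$), and the
dwelling-null enumeration checks at $R = 20{,}000$ on 2–4 dwellings —
sizes chosen so the full suite completes in about a minute while leaving
each check statistically sharp. City-scale dwelling nulls (39k dwellings,
373 patients, $R = 2000$) run in about a second.

## A small end-to-end run

```{r example}
reg <- generate_region(12, total_population = 60000, sdlog = 0.8,
                       growth_sd = 0, seed = 3)
cl <- cluster_spec(reg$municipalities$municipality_id[2:3],
                   multiplier = 3, window = c(2, 9))
coh <- generate_cohort(reg, 300, cluster = cl, seed = 4)
ts <- timeshift_scan(coh$patients, coh$residences, reg$population,
                     reg$municipalities, offsets = c(0, 5), R = 199,
                     seed = 5)
ts
```

```{r dwellings}
regis <- generate_dwelling_registry(500, 10000, seed = 6)
null <- run_null(regis, n_patients = 30, R = 500, seed = 7)
null
cooccurrence_probability(null, observed_pairs = 4, observed_trios = 0)
```

## Known limitations

Only circular zones are scanned (irregular clusters are smeared or
missed); per-offset analyses are not corrected for testing 51 offsets;
missing histories thin the numerator without adjusting the denominator;
and the dwelling null treats capacity as a time-invariant sampling weight,
ignoring occupancy dynamics. These mirror the analysis design this package
operationalizes, and each is surfaced in the relevant function's
documentation.
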