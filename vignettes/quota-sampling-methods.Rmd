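---
title: "Census-anchored quota sampling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census-anchored quota sampling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratquota)
```

`stratquota` operationalises a recruitment strategy for populations that
standard probability samples miss: quota sampling stratified on a census
profile, with quotas filled through community services and public spaces
rather than at residential addresses.  This vignette documents the models
behind each stage, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data tests do and do not
establish about field behaviour.

## The sampling frame and apportionment

The frame is the cross of four age bands (16--24, 25--44, 45--64, 65+;
closed on the left, so a 25th birthday moves a person up a band; minimum
eligible age 16), two genders, and five socioeconomic categories:
full-time worker, student, unemployed, homeless, and a residual `general`
category holding the census mass outside the four named groups (part-time
workers, retirees, carers).  The residual is a first-class stratum
because its quotas are recruited somewhere concrete: public spaces.

A `census_profile` stores each stratum's share of the eligible
population.  Shares may be entered as fractions or percentages; the scale
is auto-detected from the sum (near 1 vs near 100) because published
tables print percentages.  In strict mode the shares must sum to 1 within
`1e-6` — a deficit usually means the residual stratum was forgotten, and
the error reports it.  `normalize = TRUE` rescales instead, for profiles
assembled from rounded published figures.

Integer targets for a sample of size $n$ are $t_s = \mathrm{round}(n
p_s)$ under **largest-remainder (Hamilton) apportionment**: floor every
raw quota $n p_s$, then give the leftover units to the largest fractional
remainders.  This was chosen over independent rounding because it
conserves the total exactly — a fixed field target such as "700 surveys"
should apportion to quotas that sum to 700 — and it satisfies the quota
property $|t_s - n p_s| < 1$.  Ties among equal remainders are broken
deterministically by stratum sort order (gender, then age band, then
SES), so identical inputs always produce identical targets.  A
`round_half_even` alternative is available for comparison; it may drift
from the total and warns when it does.  Hamilton apportionment can in
principle exhibit non-monotone paradoxes across *changing totals*; within
a fixed total, doubling a stratum's share never lowers its target, a
property the test suite checks by enumeration against a brute-force
oracle.

## Randomized site allocation

Each organisation reports how many clients it currently serves per
stratum; pooled, these form the *table of potential participants*.  For
each stratum independently, the target is drawn uniformly **without
replacement** from the pooled units across eligible sites; a site's quota
is the number of units drawn from it.  Per-site quotas are therefore
multivariate hypergeometric with mean

$$E[q_{site}] = t_s \cdot \frac{a_{site}}{\sum_{site'} a_{site'}},$$

which the tests verify against an exhaustive enumeration oracle on small
instances.  Sampling units from the pooled table (rather than iterating
sites) was chosen because it weights sites by the clientele they actually
serve, without further configuration.

Eligibility: a stratum may be allocated to sites whose eligibility set
contains its SES category *and* that currently serve clients in it, plus
every general (public-space) site — anyone can be encountered at a mall
or festival.  Strata with no eligible site are flagged and recorded as
unmet, never silently dropped: for every stratum and every seed,
$\sum_{site} q_{site,s} + \mathrm{unmet}_s = t_s$.

**General sites and capacity.**  Public spaces have no client lists; they
carry a per-stratum `capacity` (default 500) — the number of recruits a
site like a shopping centre can realistically absorb per stratum.
Making capacity per-stratum (rather than a shared budget) keeps the
without-replacement invariant, quota $\le$ availability, uniform across
service and general sites.  Residual-category targets are spread over
general sites proportionally to capacity with largest-remainder rounding
(deterministic, since there is no client table to randomise over), while
*shortfall spill* from under-covered named strata uses the same random
draw as the main allocation.  Spill is on by default; switching it off
converts uncovered demand into recorded unmet counts.

**Reproducibility.**  Every random step runs under an explicit seed and
restores the caller's RNG state.  Daily rebalancing derives a fresh seed
deterministically from (base seed, day index), so a whole field campaign
of corrections replays from one integer.  Rebalancing recomputes
remaining targets as $\max(0, t_s - \text{recruited}_s)$, flags
over-recruited strata, and re-runs the allocator; completed surveys are
never clawed back.

## Monitoring and attrition

Ingest validates one row per survey attempt: under-16s are rejected with
reason `eligibility`, durations must be positive, and an incompleteness
reason must be present exactly when the status is incomplete.  Malformed
rows go to a rejects table, not an abort — in the field, one bad row
should not stall a day's sync.  Incomplete attempts are excluded from all
strata counts and representativeness analyses; the analysable sample is
`final_n = commenced − incompletes`.  Because anonymous surveys record no
names, re-participation is undetectable in principle; the package ships
only a clearly-labelled heuristic screen for identical
(site, date, demographics) groups.

## Representativeness

Sample percentages are always recomputed from counts — published
narrative percentages can disagree with their own tables, counts win.
The per-cell comparison reports the **signed** gap
$\mathrm{diff}_c = 100\,n_c/n - \mathrm{census}_c$, computed on unrounded
percentages and rounded last (to 2 decimals).  Rounding order matters:
with rounded-first arithmetic a cell can shift by 0.01 pp, which is why
the report also keeps the unrounded table.  Categorical marginals
(language at home, Year-10 completion) are percentages of non-missing
completes.  The median income band uses the lower-median convention for
even counts, which is deterministic and conservative for coarse ordered
bands.  Pyramid data negate the female side so females plot left, males
right.

When recruitment lands exactly on target with no shortfall, the only gap
between sample and census shares is integer rounding, bounded by roughly
$100 \cdot k/(2n)$ percentage points across $k$ cells — about 0.57 pp for
8 gender × age cells at $n = 700$.  The end-to-end tests assert this
bound.

## Engagement analysis

Contacts are tallied per channel with Facebook messages itemised
separately (not folded into texts).  Effort comparisons between
participating and declining organisations use Welch's unequal-variance
$t$ with Welch–Satterthwaite degrees of freedom, computed by direct
formula (and cross-checked against `stats::t.test` in the suite);
organisations with zero logged contacts contribute zeros rather than
being dropped, since "no contact needed" is information.  By default only
contacts flagged as preceding the organisation's agreement or refusal
count, the flag being set at ingest by comparing contact dates to the
letter-of-support date.  When both groups are constant and equal the
statistic is 0 with $p = 1$ by convention.

## The synthetic community generator

`community_spec()` fixes the simulated study conditions once:

* eligible population 1,863 (so a 706-person sample is 37.9% of it),
  census shares from the bundled gender × age profile;
* an SES split per age band (students concentrated in 16--24, full-time
  work peaking mid-life, 85% of the 65+ band residual) — censuses do not
  publish this three-way cross-tabulation, so the split is the package's
  own fixed, documented choice;
* a roster of nine services plus two public spaces with per-stratum
  client coverage probabilities, and a 0.3 public-space attendance rate;
* attrition 24/730 per commenced survey, reasons split 12/4/8 across
  leaving for time reasons / technical problems / discomfort;
* log-normal durations with meanlog 2.6084 and sdlog 0.4108 minutes
  (mean 14.77, SD 6.33);
* residence shares 89.1 / 5.7 / 1.4 / 3.8 percent across town,
  Indigenous community, parkland/scrub, other;
* ages uniform within bands with the open 65+ band truncated at 90;
* a synthetic weekly-income band distribution whose cumulative 50% falls
  in the \$400--599 band, consistent with a census median of \$420.

Population strata are multinomial; service membership is independent
Bernoulli(coverage) per individual per site, so individuals can attend
several services, as in reality.  Recruitment samples distinct attendee
ids per (site, stratum) quota and tracks them globally, so no synthetic
individual completes twice — a bookkeeping capability the corresponding
anonymous field study lacks.  Organisation tables default to 77
approached / 32 participating with 16 and 19 referrers among
participants and decliners, and contact logs to 610/539/33/34/1 contacts
per channel; referral structure is a simple random digraph, deliberately
*not* a realistic social network.

**What passing tests show — and don't.**  The generator draws strata
memberships independently from the stated census shares, applies
attrition independently of stratum, and gives every stratum honest
service coverage.  Real communities violate all three: attendance
clusters within families and services, attrition correlates with
demographics, and some strata avoid services altogether.  Passing
parameter-recovery tests therefore demonstrates that the *pipeline's
arithmetic and sampling mechanics* are correct under the stated model,
not that a field deployment will hit census margins.  The optional
stratum-dependent attrition mode exists precisely to probe monitor
behaviour when the independence assumption breaks.

## Problem sizes and numerical conventions

The test suite exercises apportionment on 200 random frames against a
brute-force oracle; allocator invariants over 1,000+ seeded runs on small
registries with the hypergeometric mean checked against exhaustive
enumeration of an 8-unit instance; census recovery end-to-end on a
100,000-person synthetic community at $n = 700$; and the attrition
funnel as a mean over 500 replicate recruitment runs of a 730-person
quota (binomial standard-error bound).  These sizes give Monte-Carlo
standard errors comfortably inside the asserted 3-SE bands while keeping
a full run to a few minutes.

Degenerate inputs have defined behaviour throughout: single-stratum
profiles are valid; a zero target or empty registry allocates nothing
and says so; a lone duration yields an undefined SD rather than zero;
empty logs tally zeros.  Proportion sums use tolerance `1e-6`,
income-band sums `1e-4` (published distributions are rounded), and
floating-point comparisons in tests use the formula-level tolerances
stated there (`1e-10` for the Welch statistic).

## Known limitations

* Quota sampling is non-probability sampling: no design weights, design
  effects or inferential representativeness tests are provided, and none
  would be meaningful without a probability model for site attendance.
* The allocator treats per-site client counts as current and accurate;
  stale service data degrade allocation quality in ways the package
  cannot detect.
* Eligibility defaults per site type are editable configuration, not
  validated facts about any real service system.
* The engagement analysis compares means; with heavily skewed contact
  counts a rank-based comparison may be more appropriate, and the per-org
  table is exposed so users can run one.
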