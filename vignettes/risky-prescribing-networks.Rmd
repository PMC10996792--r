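---
title: "Methods: shared-patient prescriber networks and homophily in risky prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shared-patient prescriber networks and homophily in risky prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnet)
```

# The scientific problem

Concurrent exposure to opioids (O), benzodiazepines (B) and
sedative-hypnotics (S) in older patients raises overdose risk well beyond
any one class alone. Physicians largely control these exposures, and
physicians are embedded in informal professional networks revealed by the
patients they share. `rxnet` implements a complete analysis chain for
asking whether *risky prescribing clusters on that network* — whether
physicians with similar prescribing behavior are more likely to share
patients than chance and their own prevalence would predict (homophily),
both at the level of dyads and of closed triangles.

Because prescription claims data of this kind is patient-identifiable and
cannot be redistributed, the package ships a synthetic claims generator
that reproduces the *statistical structure* the analysis relies on, with
ground truth for every latent quantity. All methods are exercised, tested
and calibrated on that generator; they apply unchanged to real
claims-shaped tables.

# The analysis chain

## Shared-patient network construction

A visit by the same patient to physician *i* on a day strictly earlier
than a visit to physician *j* is directed evidence of a professional
relationship *i* → *j*. We count, for each ordered pair, the number of
distinct patients providing such evidence, then binarize to an
undirected edge only where **both** directions have weight at least 1
(mutual ties at threshold 0). Same-day visits to two physicians carry no
direction and create no evidence; this avoids fabricating order where
none is observed. Whether *any* strictly ordered pair of visit days
counts, or only consecutive ones, is a convention the data does not
decide; we default to any ordered pair (the weaker, more inclusive
reading) and expose `consecutive = TRUE` as a flag.

The network is then restricted to physicians with at least one fill in
the three monitored classes, and reduced to its largest connected
component (LCC). Equal-sized components are disambiguated by the
lexicographically smallest member name, so the reduction is
deterministic. Region sub-networks keep an edge only when both endpoints
are assigned (by plurality of their distinct patients, ties broken by
the lexicographically smallest region label) to the same region, and are
*not* re-restricted to their own LCCs.

## Prescription states and transitions

Fills of the same drug are merged into exposure episodes under a 20%
buffer rule: a subsequent fill starting no later than the current
exposure end plus 0.2 × (the *preceding fill's* days supply) is a
refill, regardless of which physician signed it, and the episode keeps
its initiating physician. The buffer deliberately references the
preceding fill's supply rather than the accumulated episode length; one
consequence, worth knowing when reasoning about the operation, is that
re-merging episodes rendered back as single long fills can only coarsen
(never split) the result, because the rendered supply is at least the
final fill's.

Each patient's year — a single 365-day integer grid, half-open intervals
`[start, start + supply)` — is then segmented at every episode boundary
into intervals labeled by the set of active classes, and each set maps
to one of 2³ = 8 prescription states, numbered in tier order:

| state | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 |
|-------|---|---|---|---|---|---|---|---|
| classes | none | O | B | S | OB | OS | BS | OBS |
| drugs | 0 | 1 | 1 | 1 | 2 | 2 | 2 | 3 |

The tiers (0/1/2/3 concurrent classes) are substantive; the order
*within* a tier is a fixed convention. Every index below depends only on
the drug counts and on column 8, with one caveat: pure class switches
(e.g. state 2 → 3, possible when one class ends the same day another
begins) sit above or below the matrix diagonal purely by labeling
convention. We follow the diagonal split literally — a transition to a
higher-numbered state counts as prescribing, to a lower-numbered one as
deprescribing — and note that such zero-net-change switches are rare in
practice and carry zero weight in every drug-count-weighted index.

Prescribing transitions are attributed to the physician(s) initiating
the episode(s) that start at the boundary; *N* same-day initiators share
the transition with weight 1/*N* each.

## Deprescribing attribution

Deprescribing generates no claim, so it is inferred: an episode longer
than 30 days (strictly) with **no later same-drug episode** in the year
is a candidate discontinuation. The patient's latest encounter strictly
before the episode's end day is the candidate deprescribing visit, and
the attribution stands only if the end follows that visit within 30 days
(inclusive); all physicians seen on that day are co-responsible with
equal weights. A visit on the end day itself does not qualify — the
supply is already exhausted. Episodes ending at a state boundary with no
qualifying visit still emit the patient's state transition, with empty
responsibility; such unattributed discontinuations shape trajectories
but enter no physician's responsibility matrix. Both 30-day thresholds
are arguments (`min_length`, `max_gap`) for sensitivity analysis.

## Responsibility matrices and prescribing indexes

Each physician *k* accumulates an 8×8 transition responsibility count
matrix *C(k)*, with `C[i, j]` the weighted number of patient transitions
*i* → *j* attributed to *k*. Prescribing mass sits above the diagonal,
deprescribing below, the diagonal is identically zero, and summing the
matrices over physicians recovers the total attributed weight exactly.

Six scalar indexes summarize a matrix. With `dc(s)` the drug count of
state `s` and weights `w_ij = |dc(i) - dc(j)|^alpha` (with 0⁰ = 1):

* **I0, I1** — the prescribing-deprescribing balance
  `(P - D)/(P + D)` with `P`/`D` the weighted above/below-diagonal
  sums, for α = 0 (every transition equal) and α = 1 (weighted by drugs
  changed). Bounded in (−1, 1]. The α-weight uses the *absolute*
  drug-count difference: the defining expression read literally without
  the absolute value would make every above-diagonal α = 1 term
  negative and violate the stated bounds, so the absolute value is the
  only reading consistent with them.
* **IOBS** — share of the physician's total transition mass that moved
  patients *into* state 8; **IeverOBS** — its binarization (any such
  mass, however fractional, counts).
* **Ipresc2mr / Idepresc2mr** — among same-direction mass, the fraction
  changing ≥ 2 drug classes. With no deprescribing mass the
  deprescribing variant is defined as 0 (its explicit zero convention);
  every other index with an empty denominator is `NA` ("undefined"),
  never silently zero, and physicians with undefined values are dropped
  (with a logged count) from any model using that attribute.

## Dyad-independent ERGMs

The exponential random graph model
`Pr(A = a | x) ∝ exp{Σ_p η_p g_p(a, x)}` is fit only with
dyad-independent statistics — edges, nodefactor, nodecov, uniform and
differential nodematch, absdiff — for which the likelihood factorizes
into independent per-dyad Bernoulli terms with success probability
`logistic(η · change statistics)`. The factorized logistic fit is
therefore the *exact* MLE, not an approximation; `fit_ergm()` computes
it by iteratively reweighted least squares with standard errors from the
observed information. Triadic model terms (triangles, k-stars) are
rejected by design: they are exactly the terms that drive ERGM
degeneracy, and triadic structure is handled descriptively instead
(below). `exact_small_graph_loglik()` exposes the normalizing constant
by brute enumeration on up to 5 nodes, which the test suite uses to
verify the factorization identity and the MLE.

For a binary attribute, the design containing edges, nodefactor and
*both* differential nodematch columns is always rank-deficient by
exactly one — the 0-level match column equals edges − nodefactor +
1-level match — so only uniform homophily is identifiable alongside a
main effect. `check_identifiability()` detects this numerically
(singular values below 1e−8 × the largest are treated as zero) and
names the collinear set; `fit_ergm()` refuses such designs rather than
silently dropping a column. The theorem presumes each level occurs on
at least two nodes; a level with a single carrier degenerates its match
column to zero and adds a separate, trivial rank drop.

Categorical nodefactor terms drop a reference level, by default the
most frequent (ties broken alphabetically), configurable per term.

## Triadic homophily and the permutation test

Two attribute-restricted statistics, for a node attribute `x` in [0, 1]:

* `tri1` — Σ over closed triangles of `x_i x_j x_k`, divided by the
  number of closed triangles: the (weighted) share of triangles whose
  three members all carry the attribute.
* `tri2` — Σ over *closed* 2-stars of `x_i x_j x_k` divided by the same
  sum over **all** 2-stars (center, unordered neighbor pair): an
  attribute-restricted transitivity. Each triangle contributes three
  closed 2-stars, one per center.

Both are counted over unordered configurations; any consistent ordered
convention cancels in the ratios. With all `x = 1`, `tri1 = 1` and
`tri2` equals the global clustering coefficient exactly. Continuous
attributes enter after min-max standardization to [0, 1]; no
thresholding. `tri1` is undefined on triangle-free graphs and `tri2`
when no 2-star carries attribute weight; undefined is reported as `NA`,
never 0.

Because these ratios are not ERGM statistics, significance comes from an
attribute-redistribution (partial permutation) test: the graph stays
fixed and the attribute vector is permuted uniformly over nodes,
preserving the attribute's empirical distribution and the entire
topology. The default is 30 permutations with a one-sided "greater"
alternative and the raw proportion p-value (granularity 1/30 at the
default; the add-one `(b+1)/(m+1)` correction is a flag); the test suite
calibrates with 99 permutations over hundreds of replicates. Null draws
on which the statistic is undefined are scored as 0 — no homophilic
structure — which is conservative for the "greater" alternative. The
null preserves density and degree *distribution by construction* (the
graph is untouched) but not the joint distribution of attribute and
degree; degree-preserving rewiring nulls are out of scope.

# The synthetic generator: what it emulates and what it does not

`generate_cohort()` draws, deterministically given a seed:

* **Physicians** with specialty (five categories), region (uniform over
  `n_regions`) and a latent risky-prescribing propensity
  `risk ~ Beta(2, 5)` — right-skewed, mean ≈ 0.29, so most physicians
  are low-risk with a heavy-prescribing tail.
* **Patient panels**: each patient gets a primary physician (weighted
  4:1 toward their own region) plus extras drawn with weight
  `exp(-homophily_strength × |risk difference from the primary|)`,
  again region-weighted. This plants dyadic homophily on the latent
  propensity with tunable strength; strength 0 produces assortativity
  statistically indistinguishable from 0.
* **Encounters**: ~1.5 routine visits per patient-physician pair on
  uniform days, plus one encounter at every fill start (fills imply
  visits, exactly).
* **Fills**: a pair generates a prescription with probability
  `0.15 + 0.45 × risk`; high-risk physicians escalate to a second or
  third class with probability `risky_escalation_rate × risk` per step,
  co-prescribed at the same visit half the time (so some transitions
  add ≥ 2 classes at once, as real same-visit co-prescriptions do) and
  at a follow-up within 20 days otherwise. Supplies are 30/60/90 days
  (probabilities 0.5/0.3/0.2); refill chains continue with probability
  `refill_rate` per step (max 4 fills), each next start inside the 20%
  buffer, signed by the initiator 80% of the time. Drug products are
  unique per patient, so one chain per patient-drug.
* **Planted deprescribing**: each episode longer than 40 days ending by
  day 350 is, with probability `deprescribe_rate`, terminated by a
  visit 3–10 days before its end; the generator removes other routine
  encounters from the window (and skips planting when a fill-day visit
  would intrude), making that visit the patient's final qualifying
  contact by construction. The planted (physician, visit day, end day)
  triples are returned as ground truth, which is how attribution
  sensitivity is measured rather than assumed.

Defaults — 150 physicians, 600 patients, 4 regions, homophily strength
2, refill rate 0.6, escalation rate 0.5, deprescribe rate 0.4 — produce
a mutual prescribing LCC of ~150 nodes with density ~0.09, about 2 fills
per episode, and >100 planted deprescribing events: large enough for
every stage to be exercised and small enough that the whole chain runs
in seconds.

What the generator does **not** emulate: demographics and comorbidity,
dose or strength (no MME), claim-level payment fields, multi-year
enrollment, seasonal prescribing, or realistic degree heavy tails
(panels are light-tailed Poisson). Consequently, passing tests show the
*methods* are correct and calibrated — exact oracle agreement,
identifiability detection, nominal CI coverage, permutation
super-uniformity, attribution sensitivity on recoverable ground truth —
not that real claims data would show any particular homophily level.
Real-data effect sizes at realistic network scale (tens of thousands of
physicians) cannot be reproduced from this package's synthetic scale,
and sparse indexes (notably the ≥ 2-drug deprescribing fraction) can be
entirely zero in a small cohort, in which case their homophily model is
reported as non-estimable rather than forced.

# Numerical choices

* Rank tolerance 1e−8 (relative, singular values); enumeration
  normalization verified to 1e−12; `glm.fit` convergence tightened to
  1e−12 so exact-MLE comparisons hold at 1e−6.
* Coefficients with |estimate| > 15 on a logit scale are flagged
  divergent (perfect separation; e.g. an empty or complete graph under
  an edges term).
* Index undefined-vs-zero conventions as above; weighted (fractional)
  responsibility flows through all indexes unrounded.
* Deterministic tie-breaks throughout (component selection, region
  plurality, nodefactor reference levels), so identical inputs
  reproduce identical outputs byte for byte.

# Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` run the default 150 × 600 cohort
with seed 2014. The acceptance script re-simulates that cohort, then
checks coefficient recovery on 50 networks of 300 nodes each (~45k
dyads per fit) and reports triadic permutation tests with 199
permutations. The test suite uses 100 random graphs up to 30 nodes for
the brute-force triad oracle, full enumeration up to 5 nodes (1024
graphs) for the ERGM oracle, 100 replicates for CI coverage and 500 for
permutation calibration. These sizes were chosen to give each
statistical check enough replication to be meaningful at interactive
runtimes.

# Known limitations

* Deprescribing attribution is a heuristic; its measured sensitivity is
  against *planted* events designed to be recoverable. Real
  discontinuations without a proximate visit are systematically
  unattributable from claims alone.
* The ERGM layer is exact but only for dyad-independent models;
  dyad-dependent phenomena are addressed descriptively via `tri1`/`tri2`,
  not modeled.
* The permutation null fixes the graph; it tests attribute arrangement,
  not co-evolution of ties and attributes.
* Year-boundary censoring is not adjusted: exposures are clipped at day
  365 and transitions at the boundary are not emitted.
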