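# rxnet — shared-patient prescriber networks and homophily in risky prescribing

Concurrent prescribing of opioids (O), benzodiazepines (B) and
sedative-hypnotics (S) to older patients is a leading safety concern, and
physicians are embedded in informal professional networks revealed by the
patients they share. `rxnet` is an R package, plus a numbered analysis
workflow, for asking whether risky prescribing *clusters* on that
network — whether physicians who prescribe alike are more likely to share
patients than chance would predict, at the level of both dyads and closed
triangles. It is aimed at health-services and network researchers working
with claims-shaped data (prescription fills and physician–patient
encounters).

## What the package computes

1. **Shared-patient network.** A patient visiting physician *i* strictly
   before physician *j* is directed evidence *i → j*; an undirected edge
   requires evidence in both directions (mutual ties, threshold 0). The
   network is restricted to O/B/S prescribers and reduced to its largest
   connected component, with region sub-networks by patient plurality.
2. **Prescription-state trajectories.** Fills merge into exposure
   episodes under a 20% refill buffer; each patient's year becomes a
   trajectory over the 8 states formed by subsets of {O, B, S}
   (1 = none, 2–4 = one class, 5–7 = two, 8 = all three). Transitions
   that add classes are attributed to the initiating physicians;
   discontinuations of long, never-refilled episodes are attributed to
   the last qualifying visit before the supply lapses (a claims-only
   deprescribing heuristic with validated sensitivity).
3. **Prescribing indexes.** Each physician's 8×8 transition
   responsibility count matrix C(k) (weighted transitions i → j they are
   responsible for) is summarized into six node attributes: the
   prescribe/deprescribe balance `I_alpha = (P − D)/(P + D)` with
   `P = Σ_{i<j} C_ij |dc(i) − dc(j)|^alpha` (α ∈ {0, 1}, `dc` = drug
   count), the riskiest-state involvement `I_OBS` and its indicator
   `I_everOBS`, and the ≥ 2-class change fractions `I_presc2mr` /
   `I_depresc2mr`.
4. **Dyad-independent ERGMs.** For the homophily model
   `Pr(A = a | x) ∝ exp{Σ_p η_p g_p(a, x)}` with edges, nodefactor,
   nodecov, nodematch and absdiff statistics, the likelihood factorizes
   over dyads and `fit_ergm()` returns the *exact* MLE via per-dyad
   logistic regression, with identifiability diagnostics (for a binary
   attribute, edges + nodefactor + both differential nodematch terms are
   provably collinear) and an enumeration oracle on ≤ 5 nodes.
5. **Triadic homophily.** `tri1` (attribute-weighted share of closed
   triangles whose three members all carry the attribute) and `tri2`
   (attribute-restricted transitivity: the share of attribute-carrying
   2-stars that are closed), with an attribute-redistribution permutation
   test that holds the graph fixed.
6. **Synthetic claims generator.** Deterministic, seedable cohorts with
   refill chains, multi-class escalation tied to a latent
   risky-prescribing propensity, patient-sharing assortative on that
   propensity, and planted deprescribing events with ground truth.

## Worked example

```r
library(rxnet)

co  <- generate_cohort(sim_config(seed = 2014))
res <- run_pipeline(co)

res$funnel
#>                  stage n_nodes n_edges
#> 1:          physicians     150    2980
#> 2:      mutual_network     150    1042
#> 3: prescribing_network     148    1020
#> 4:                 lcc     148    1020
```

150 simulated physicians yield 2,980 directed evidence arcs; mutual
binarization keeps 1,042 undirected ties, 148 physicians prescribe in the
monitored classes, and the LCC retains all of them (density 0.094,
global clustering 0.161, mean path length 2.20).

```r
pr <- res$profiles
mean(pr$I0, na.rm = TRUE)   # 0.358  — prescribing outweighs detected deprescribing
mean(pr$IeverOBS)           # 0.169  — 17% ever moved a patient into state OBS

res$ergm_fits$IeverOBS$coefficients[c(1, 7, 8), 1:3]
#>                    term   estimate        se
#> 1                 edges -2.1388016 0.1492007
#> 7 nodefactor.IeverOBS.1 -0.1410985 0.1126790
#> 8    nodematch.IeverOBS -0.1489268 0.1283684

res$triads
#>           tri1      tri2 n_triangles attr_triangles_weight attr_twostars_weight
#> 1: 0.002444988 0.1333333         818                     2                   45
```

Of 818 closed triangles in the LCC, 2 are entirely composed of ever-OBS
prescribers (`tri1 = 0.0024`); of 45 ever-OBS 2-stars, 13% are closed
(`tri2 = 0.133`). The permutation test (30 attribute redistributions)
gives p = 0.70 for `tri1` here: at this synthetic scale the planted
homophily acts on the latent propensity, and its ever-OBS shadow is too
noisy to reach triadic significance — which is the honest reading, not a
defect. The ERGM parameter-recovery stage (`analysis/04_ergm.R`) shows
the estimator itself recovers a true homophily coefficient of −1.5 with
mean estimate −1.498 (SD 0.076) over 25 simulated 300-node networks.

## The analysis workflow

```sh
Rscript analysis/01_simulate.R        # synthetic cohort + ground truth
Rscript analysis/02_network.R        # funnel, summaries, region sub-networks
Rscript analysis/03_states_indexes.R # trajectories, attribution, indexes
Rscript analysis/04_ergm.R           # homophily models + identifiability + recovery
Rscript analysis/05_triads.R         # tri1/tri2 + permutation tests
```

Each stage prints what it found and writes its tables under `results/`.

## Documentation

The methods vignette
(`vignettes/risky-prescribing-networks.Rmd`) describes the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical conventions,
and known limitations.
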