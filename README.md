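# prognet

Bayesian-network prognosis modelling for advanced non-small-cell lung
cancer (NSCLC), with phantom-validated CT lesion segmentation and
RECIST-based efficacy evaluation.

Deciding which advanced-NSCLC patients will benefit from expensive targeted
maintenance therapy calls for a prognosis model that combines many clinical
factors at once.  prognet implements that analysis end to end for
statisticians and methodologists who want every stage testable: a
survival-status prognosis network learned from clinical variables, tumor
measurement from segmented images, and two-arm treatment-efficacy
evaluation.  Since patient-level data for such a study are not publicly
available, the package ships a synthetic-data generator with a known ground
truth, so structure recovery, segmentation accuracy and survival estimation
can all be verified against the truth that generated the data.

## The model

A discrete Bayesian network is the pair (G, Θ): a directed acyclic graph
G = (V, E) over the variables plus a conditional probability table
Θ_i = P(X_i | Pa(X_i)) per node, so the joint factorizes as

    P(X_1, …, X_n) = ∏ᵢ P(Xᵢ | Pa(Xᵢ)).

Structure is learned by **max-min hill-climbing (MMHC)**:

1. **MMPC** finds each node's candidate parents and children with the
   G²-type conditional-association statistic
   `Assoc(X, T | Z) = 2 Σ N·ln(N·N_c / (N_ac·N_bc))` and its minimum over
   conditioning subsets (MinAssoc), with forward admission, backward
   pruning and a symmetry correction;
2. greedy **hill-climbing** over add/delete/reverse moves, restricted to
   the discovered skeleton, maximizes a decomposable score (BIC by
   default, BDeu optional);
3. CPTs are estimated with a Dirichlet pseudocount, and survival status is
   predicted by exact enumeration of the factorization.

Around the model sit the supporting stages: chi-square screening and
logistic-regression filtering of the 16 candidate variables, equidistant
discretization, Wiener/fuzzy image preprocessing, co-occurrence texture and
differential box-counting fractal features, a from-scratch backpropagation
pixel classifier for lesion segmentation, lesion diameter/volume
measurement, RECIST response classification with ORR/DCR, and Kaplan–Meier
progression-free survival.  See the methods vignette
(`vignettes/prognosis-pipeline.Rmd`) for the full account.

## Worked example

Learn the prognosis network from a synthetic cohort and query a patient:

```r
library(prognet)

truth  <- make_ground_truth()                       # known 7-node truth
cohort <- attr(sample_cohort(truth, 5000, seed = 42), "levels")
fit    <- mmhc(cohort, outcome = "survival_status")
fit
#> Max-min hill-climbing Bayesian network fit
#> Call: mmhc(data = cohort, outcome = "survival_status")
#> Settings: alpha = 0.05, maxk = 3, score = bic
#> Network score: -22701.55 (after 11 accepted moves)
#> Discrete Bayesian network: 7 nodes, 7 edges
#>   histological_grade [2 levels]
#>   tumor_stage [2 levels]
#>   diagnosis_age [2 levels] <- survival_status
#>   tumor_size [2 levels]
#>   examined_lymph_nodes [2 levels]
#>   positive_lymph_nodes [2 levels] <- tumor_stage
#>   survival_status [2 levels] <- tumor_size, tumor_stage,
#>     histological_grade, positive_lymph_nodes, examined_lymph_nodes
#> Outcome node: survival_status
```

All six prognostic variables are recovered as neighbours of survival
status (one edge orientation differs from the generating graph, which is
within the score-equivalence the learner can distinguish).  Posterior
prognosis for a high-risk evidence pattern:

```r
round(predict_outcome(fit, c(histological_grade = "high",
                             tumor_stage = "IV",
                             positive_lymph_nodes = "2")), 3)
#> alive  dead
#> 0.105 0.895
```

A patient with high-grade, stage-IV disease and a high positive-node count
has a predicted 89.5% probability of the unfavourable status.  Efficacy
rates from response counts (CR/PR/SD/PD) work directly:

```r
efficacy_rates(0, 4, 14, 2, group = "research")
#> research: n = 20 | CR 0, PR 4, SD 14, PD 2 | ORR 20.0%, DCR 90.0%
```

i.e. an objective response rate of 20.0% (CR+PR out of 20) and a disease
control rate of 90.0% (CR+PR+SD out of 20).  `run_pipeline()` composes all
stages — cohort simulation, selection, learning, prognosis-guided arm
assignment, phantom segmentation and measurement, RECIST classification,
and Kaplan–Meier PFS — from one seeded `pipeline_config()`.

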