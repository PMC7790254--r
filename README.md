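# persotypes

Person-centered personality research asks whether Big Five trait profiles
aggregate into a small set of recurring *personality prototypes* — the
resilient, overcontroller, undercontroller, reserved and
confident/vulnerable-resilient types — and whether those prototypes predict
life outcomes better than single traits do. The hard part is not clustering
but *selection*: any algorithm returns a partition, so the number of
clusters and the algorithm must be chosen by replicable, bias-aware
criteria.

`persotypes` implements a complete selection pipeline for short Big Five
inventories (15 items, 3 per trait):

* **Scoring and exclusions** — trait scores as means of keyed items;
  persons excluded for more than one missing answer or intradimensional
  answer variance above four times the sample average.
* **Three clustering engines** under one contract — Ward-initialized
  k-means, Gaussian-mixture latent profile analysis (four covariance
  families, BIC-arbitrated), and Ng–Jordan–Weiss spectral clustering.
* **Split-half replication with SVM reclassification** — each half's
  members are re-allocated by one-vs-rest RBF SVMs trained on the opposite
  half's solution; agreement is scored with Cohen's kappa (after optimal
  label alignment), Rand and adjusted Rand. Cluster counts whose
  cross-algorithm mean kappa falls below 0.6 are discarded.
* **A twelve-index validity battery with vote counting** — C-index,
  Baker–Hubert Gamma, G+, generalized Dunn index GDI31, point-biserial,
  silhouette, S_Dbw, classification-likelihood AIC/BIC plus the three
  external criteria; each index votes, most votes wins.
* **Labeling, stability, predictive validity** — winning centers are named
  by Cronbach–Gleser profile distance D against a reference prototype
  table; a second wave is matched by D and compared via SVM allocation;
  person-level inverse distances to each prototype are correlated with
  criterion variables.
* **A synthetic panel generator** — a five-component mixture over trait
  z-space with realistic mixing proportions, Likert discretization,
  careless responders, missingness and criterion variables with planted
  trait correlations, so the entire pipeline is testable without
  restricted-access survey data.

## Worked example

```r
library(persotypes)

# simulate a small panel with planted five-type structure
cfg <- generator_config(n_persons = 2000, within_sd = 0.4,
                        missing_rate = 0.01, careless_rate = 0.03, seed = 42)
pop <- inject_missing_and_careless(generate_population(cfg))

# score, exclude, standardize
pre <- preprocess_items(pop$items)
#> included 1941 of 2000 persons

# replication protocol with vote-count selection (scaled down for a demo)
sel <- select_prototype_solution(
  pre$z, protocol_config(n_resamples = 4, k_range = 3:6, seed = 1))
subset(sel$replication$summary, algorithm == "ward_kmeans")
#>  k kappa rand adjusted_rand
#>  3  0.97 0.97          0.94
#>  4  0.74 0.89          0.73
#>  5  0.96 0.98          0.93
#>  6  0.80 0.94          0.79
sel$winner$k
#> winner: lpa, k = 5

label_prototypes(sel$winner$centers)
#>             prototype    D neuroticism extraversion openness agreeableness conscientiousness
#>  vulnerable-resilient 0.62        0.80         1.02     1.01          0.62              0.64
#>        overcontroller 0.65        0.92        -0.85    -0.88         -0.34             -0.26
#>       undercontroller 0.84        0.02        -0.16    -0.11         -1.18             -1.19
#>             resilient 0.99       -1.35         1.07     1.04          0.62              0.61
#>              reserved 0.52       -0.69        -0.82    -0.85          0.70              0.65
```

Reading the output: the 4- and 6-cluster solutions are unstable across
half-samples (kappa 0.74 / 0.80) because they must make an arbitrary choice
among near-equal merges or splits, while the planted 5-cluster structure
replicates almost perfectly (kappa 0.96); the vote count then picks a
five-cluster solution, and each recovered center is nearest to the planted
prototype it was generated from. `D` is the Euclidean distance between a
recovered center and its reference profile in trait z-space.

A command-line wrapper for item CSV files lives at
`inst/scripts/prototyper.R`:

```sh
Rscript inst/scripts/prototyper.R --input items.csv --out results/
```

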