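# mixbiotic

Dynamic communication-pattern measures for temporal contact and message
networks.

Social isolation and social fragmentation are opposite failures of
communication: the isolated interact too sporadically to bond, while
crowded in-groups interact only with themselves. `mixbiotic` quantifies
where a community sits between those extremes from nothing but its event
stream — who communicated when — by tracking the per-time activation vector
**Q**(t) = (q₁(t), …, qₙ(t)) over the n community members (qᵢ(t) ∈ {0, 1}
by default: did vertex i take part at time t).

Four series summarise each transition **Q**(t) → **Q**(t+1):

* information change  I = (Σᵢ qᵢ(t+1) − Σᵢ qᵢ(t)) / (n·u)
* Euclidean distance  L = ‖Q(t+1) − Q(t)‖₂ / (u·√n)
* relative change     L_R = ‖Q(t+1) − Q(t)‖₂ / ‖Q(t+1)‖₂
* cosine similarity   S = Q(t+1)·Q(t) / (‖Q(t+1)‖·‖Q(t)‖)  ∈ [0, 1]

Their means μ and unbiased variances σ² yield the community-phase measures

| phase | measure | reading |
|---|---|---|
| mobism (fragmentation) | M_mob = μ_L | biased, crowded, large ordered swings |
| atomism (isolation) | M_atom = μ_LR | separate, sporadic, large relative change |
| mixism (the "well-going" middle) | M_mix = μ_S · σ_S² | similarity that also varies |
| nihilism | all ≈ 0 | static and silent |

M_mix is the headline composite: zero both for perfectly repetitive and for
perfectly uncorrelated communication, maximal for communities that cycle
between mixing and mingling. The package also provides the static
social-network-analysis baseline (density, diameter, clustering, …), a polar
communication-trajectory export (r = ‖Q(t)‖, θ = angle to the all-ones
direction), radar-chart normalisation, readers for the SocioPatterns and
network-repository contact-list dialects, a seeded synthetic regime
generator, and a command-line front end.

## Worked example

Generate one synthetic community per phase, compute the measures, and
classify each against the set:

```r
library(mixbiotic)

streams <- lapply(
  c(mobism = "mobism", atomism = "atomism",
    mixism = "mixism", nihilism = "nihilism"),
  function(rg) generate_regime(regime_spec(rg, seed = 1))
)
measures <- lapply(streams, function(s)
  mixbiotic_measures(build_pattern_sequence(s)))
tbl <- dplyr::bind_rows(measures, .id = "community")
tbl[, c("community", "mu_L", "mu_LR", "mu_S", "var_S",
        "M_mob", "M_mix", "M_atom")]
#> # A tibble: 4 × 8
#>   community   mu_L mu_LR   mu_S    var_S  M_mob    M_mix M_atom
#>   <chr>      <dbl> <dbl>  <dbl>    <dbl>  <dbl>    <dbl>  <dbl>
#> 1 mobism    0.224  0.316 0.95   0        0.224  0         0.316
#> 2 atomism   0.140  1.40  0.0113 6.78e- 3 0.140  7.65e- 5  1.40
#> 3 mixism    0.0691 0.138 0.902  8.84e- 2 0.0691 7.98e- 2  0.138
#> 4 nihilism  0      0     1      1.36e-32 0      1.36e-32  0

ref <- dplyr::bind_rows(measures)
sapply(measures, classify_phase, reference = ref)
#>     mobism    atomism     mixism   nihilism
#>   "mobism"  "atomism"   "mixism" "nihilism"
```

Each regime is ranked first on its namesake measure: the drifting clique has
the largest Euclidean stride μ_L (0.224); the fresh-random-pairs stream has
the largest relative change μ_LR (≈1.40, near the √2 of fully disjoint
steps); the block-rotating groups combine high similarity (μ_S ≈ 0.90) with
high similarity variance, so their M_mix (≈0.080) dominates; and the
near-silent stream has all measures ≈ 0.

Real datasets enter through `read_contact_list()`:

```r
stream <- read_contact_list("contacts.txt", dialect = "sociopatterns")
m <- mixbiotic_measures(build_pattern_sequence(stream))
graph_features(stream)      # static baseline
autoplot(polar_trajectory(build_pattern_sequence(stream)))
```

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/scripts/mixbiotic.R`:

```sh
Rscript inst/scripts/mixbiotic.R synth --regime mixism --seed 7 --out s.tsv
Rscript inst/scripts/mixbiotic.R measures --input s.tsv \
    --dialect generic_tsv --out report.json --series series.csv
```

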