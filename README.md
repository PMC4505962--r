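# netmatch

Preferential attachment — newcomers to a social network befriending
already-popular members — treated as softmax *probability matching*
from decision theory. A newcomer with sensitivity `L` chooses to
befriend member `a` with probability

```
P(a) = d_a^L / sum_b d_b^L
```

where `d` is degree. `L = 0` ignores popularity, `L = 1` is linear
matching (the Barabási–Albert rule, producing scale-free networks),
`L -> Inf` produces a star, and `L < 0` is antipreferential
("demophobic"). The package is for behavioral and network scientists
who want to (i) simulate network growth under fixed or
Gaussian-distributed individual differences in `L`, (ii) estimate `L`
from two-choice behavioral data with Bayesian MCMC (per participant,
per choice, shared, and hierarchical individual-differences models,
compared by AICc), (iii) measure small-world connectivity (degree
CCDF, characteristic path length, mean local clustering), and (iv)
correlate fitted sensitivities with personality traits using
percentile-bootstrap CIs. A synthetic-cohort generator emulating the
behavioral dataset (600 participants, `L ~ N(0.68, 3.1^2)`, a 25-node
scale-free stimulus) makes the whole pipeline runnable without any
external data.

## Worked example

```r
library(netmatch)

# a synthetic cohort: 200 participants on the 25-node stimulus
co <- generate_cohort(cohort_config(n_participants = 200, cohort_seed = 42))

# hierarchical individual-differences fit of (mu, sigma)
fit <- fit_hierarchical(co$records, co$stimulus,
                        config = mcmc_config(n_samples = 2000, seed = 42))
fit
#> <population_fit> mu = 1.13 [0.54, 1.65], sigma = 3.32 [2.70, 4.09]  (R-hat 1.068)

# is there evidence for individual differences at all?
compare_models(co$records, co$stimulus)
#> <model_comparison> AICc shared 2485.9 (L = 0.84) vs hierarchical 2334.3
#>   (mu = 1.07, sigma = 3.41); delta = 151.6

# consistency of L between each participant's two selections
maps <- fit_choices_cohort(co$records, co$stimulus)
first_second_consistency(maps, n_boot = 10000)
#> <correlation> r = 0.62, 95% CI [0.54, 0.70] (n = 200, 10000 resamples)

# grow a network and measure its connectivity
g <- grow_network(5000, 3, policy = 1, seed = 42)
network_metrics(g, seed = 42)
#> <network_metrics> 5000 nodes, 14994 edges; path length 3.997 (sampled),
#>   clustering 0.0097, CCDF slope -1.81
```

Reading the numbers: the cohort was generated with `mu = 0.68`,
`sigma = 3.1`; both true values fall inside the reported 95% credible
intervals. The AICc difference of ~152 (positive = individual
differences preferred) correctly detects the heterogeneity, and the
positive first/second correlation is its behavioral signature. The
grown `L = 1` network shows the scale-free CCDF slope near −2
(degree-density exponent −3).

A command-line surface wraps the same stages:

```sh
Rscript -e 'netmatch::cli()' synth-cohort --seed 1 --n 100 --out cohort/
Rscript -e 'netmatch::cli()' fit hierarchical --data cohort/ --out fits/
Rscript -e 'netmatch::cli()' sweep --seed 1 --config sweep.json --out sweep/
```

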