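# prefrl

Do preferences formed by free choice carry over into reward learning?
`prefrl` is an R package for a two-stage behavioural design that asks
exactly that: participants first reveal preferences over novel shapes by
repeated forced choice without feedback (internally guided
decision-making, IDM), then play a two-armed-bandit gambling task with
binary 70%/30% rewards (externally guided decision-making, EDM) in which
the most- and least-preferred shapes reappear next to novel ones. The
package is for computational researchers who want to fit and compare the
candidate learning models on such data — or on fully synthetic studies
with the same statistical structure — without any original raw data.

## The models

Four Q-learning variants share the delta-rule update of the chosen
option,

    Q_i(t+1) = Q_i(t) + alpha * (r(t) - Q_i(t)),

the rejected option unchanged, and the softmax choice rule

    P(chosen) = 1 / (1 + exp(-beta * (Q_chosen - Q_rejected))),

and differ only in the free initial values: RL1 gives every stimulus
class the same eta; RL2 frees the high-preference stimulus (eta1 vs
eta2); RL3 frees the low-preference stimulus; RL4 frees all three
classes. Fitting is Bayesian (uniform priors over the parameter boxes,
random-walk Metropolis with reflection), model comparison uses WBIC —
the posterior mean of the negative log-likelihood sampled at temperature
1/log(n) — which approximates the negative log marginal likelihood, and
Bayes factors are binned by the Kass–Raftery categories. Parameter and
model recovery harnesses, the behavioural test battery (paired
contrasts with Cohen's d, repeated-measures ANOVAs with partial eta
squared, Holm-corrected rating comparisons, first-trial choice
proportions) and a seeded end-to-end pipeline round out the analysis
chain. See `vignettes/preference-seeded-rl.Rmd` for the methods account.

## Worked example

```r
library(prefrl)

study <- generate_study(seed = 42)   # the default 42-participant design
freq  <- pref_frequency_contrast(study)
cmp   <- rl_compare(study, seed = 42)
fit   <- rl_fit(study, "RL2", seed = 42)
```

The synthetic study uses the experimental constants (2 task sets x 105
preference trials and 150 gambling trials, counterbalanced task order)
with gambling choices generated from RL2. The printed results:

```
chosen frequency, high vs low preference: t(41) = 1489.99, d = 229.91

WBIC model comparison (lower is better; BF of best over rival)
 model    wbic delta_wbic  bf_vs_best       label flagged
   RL2 4952.42   0.000000          NA        best   FALSE
   RL1 4952.64   0.216238 1.24140e+00 unimportant   FALSE
   RL4 4990.28  37.860054 2.76957e+16 very strong   FALSE
   RL3 4992.82  40.400948 3.51487e+17 very strong   FALSE

Model RL2 -- 42 fitting unit(s)
  parameter   mean sd_across_units mean_post_sd max_rhat
1     alpha 0.3583          0.1369       0.0622    1.031
2      beta 5.4600          0.8847       0.9021    1.055
3      eta1 0.6466          0.1284       0.1899    1.045
4      eta2 0.3911          0.1100       0.1307    1.052
convergence flagged: p028
```

(The per-participant split R-hat flag at 1.05 is deliberately strict;
one borderline participant out of 42 is reported, never silenced.)

The generating model (RL2, true alpha drawn from U(0.1, 0.6), beta 5.3,
eta1 = 0.7, eta2 = 0.4) attains the lowest summed WBIC and its
parameters are recovered in the posterior means. The margin over the
nested RL1 is small at this scale — the extra initial-value parameter
carries information only in each pair's early trials — while the
misspecified RL3/RL4 schemes are rejected decisively. The fitted value
trajectories show the signature pattern: the preference effect is
present in the initial values and gone from the final ones,

```
                                           effect   statistic df1 df2      p_value
pref_high_prob: stim_type at value_type=initial 147.1910290   1  41 3.769458e-15
pref_high_prob: stim_type at value_type=final     0.7925828   1  41 3.785147e-01
pref_high_prob: prob at value_type=final        241.1907621   1  41 8.937829e-19
```

and on each pair's first presentation 71–83% of simulated participants
choose the preferred stimulus against ~50–62% for the matched novel
stimulus (`first_trial_choice(study)`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch: it simulates
a synthetic study from the given seed, runs the behavioural battery,
fits and compares all four models by WBIC, extracts the value-stage
contrasts under the winning model, and runs a parameter-recovery study,
then writes the result JSON to `--out`.

## Layout

* `R/`, `src/` — implementation (S3 modelling interface around
  `rl_fit()`; compiled session likelihood).
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles.
* `scripts/acceptance.R` — the end-to-end run described above.
* `vignettes/preference-seeded-rl.Rmd` — model, estimation and
  synthetic-world documentation.
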