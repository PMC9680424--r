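# redeye

Dynamic Bayesian differential diagnosis and urgency triage for the acute
red eye.

Static red-eye flowcharts ask every patient the same questions in the same
order. A specialist works differently: they hold a ranked differential in
mind, update it with every finding, and choose the next question by how
much its answer could move the differential. `redeye` implements that
behaviour as an open, knowledge-base-driven engine for front-line
(non-ophthalmologist) triage, plus the statistics used to evaluate such
tools and a synthetic-patient generator that makes the whole pipeline
testable.

## The model

Diagnoses $d_1,\dots,d_m$ carry prior weights $\pi_j$; each question $k$
stores $\theta_{kj} = P(\mathrm{YES} \mid d_j)$. After answers $a_{1:t}$
the differential is the naive-Bayes posterior

$$P(d_j \mid a_{1:t}) \propto \pi_j \prod_{k\le t} L_k(a_k \mid d_j),$$

with $L_k(\mathrm{YES}\mid d_j)=\theta_{kj}$,
$L_k(\mathrm{NO}\mid d_j)=1-\theta_{kj}$, and "I don't know" contributing
likelihood 1 (no evidence). The next question maximizes a value-of-
information score: the total-variation distance between the current and
the answer-updated belief, taken as the max over answers (default) or the
answer-probability-weighted expectation, subject to prerequisite and
redundancy constraints declared in the knowledge base. The interview
stops when the top posterior is at least $\theta$ (default 5) times the
runner-up and above a floor (default 0.5), when the bank is exhausted, or
when the user quits; stopping with a belief still within total variation
0.05 of the prior raises a `low_confidence` flag.

Evaluation reproduces the standard outcome measures: top-1/2/3 accuracy
against a gold-standard diagnosis, and urgency sensitivity/specificity
(urgent iff the *top* diagnosis is flagged urgent) with exact
Clopper–Pearson 95% confidence intervals from beta quantiles.

The default knowledge base covers 15 red-eye diagnoses (4 urgent) with 24
bedside questions; its conditional probabilities are authored clinical
content, editable YAML validated against a shipped JSON schema. See the
vignette (`vignettes/red-eye-triage.Rmd`) for the full methods account.

## A worked example

A contact-lens wearer with a painful eye; fluorescein shows uptake and
there is a whitish opacity:

```r
library(redeye)
kb <- default_kb()
session <- run_interview(kb, answers = c(
  pain = "yes", stain = "yes", opacity = "yes", lens = "yes"
))
```

The engine asks its opening questions, confirms staining (which unlocks
the opacity and contact-lens questions and eliminates chronic tearing as
redundant), and after the opacity answer prints:

```
 1. Corneal Ulcer                             94.7 [######### ] (!)
 2. Keratitis/Corneal Abrasion                 4.2 [          ]
 3. Endophthalmitis/Severe Inflammation        1.0 [          ] (!)
 4. Acute Angle-Closure Glaucoma               0.1 [          ] (!)
 5. Iritis                                     0.0 [          ] (!)
>> ADVICE: Refer to Ophthalmology to rule out a corneal ulcer.
Stopped (dominance)
```

Numbers are posterior percentages (one decimal), the bar is a 0–10 visual
score, `(!)` marks urgent diagnoses (always displayed while they retain
any probability), and the advice rule fired the moment its condition held.
`glance(session)` summarizes: top diagnosis `corneal_ulcer` at posterior
0.947, stopped on dominance after 5 questions, not low-confidence.

Re-analyzing a published 57-patient concordance table shipped with the
package:

```r
counts <- readr::read_csv(system.file("extdata", "concordance-counts.csv",
                                      package = "redeye"))
glance(concordance_eval(counts, kb))
#>    n n_urgent acc_referrer acc_top1 acc_top2 acc_top3 urgent_acc_referrer
#> 1 57       26         70.2     68.4     75.4     80.7                76.9
#>   urgent_acc_top1 urgent_acc_top2 urgent_acc_top3
#> 1            73.1            84.6            88.5
```

i.e. referrers were 70.2% accurate overall while the algorithm reached
68.4% with its top diagnosis, 75.4% within the top two and 80.7% within
the top three; on the 26 urgent cases the corresponding figures are 76.9%
and 73.1/84.6/88.5%. Exact binomial CIs:

```r
clopper_pearson(20, 26)   # urgency sensitivity 20/26
#>     lower     upper
#> 0.5635249 0.9102599     # prints as 76.9% (95% CI: 56–91%)
```

Other entry points: `batch_diagnose()` (case tables), `evaluate_cases()`
(full study-style evaluation), `simulate_cases()` / `perturb_answers()`
(synthetic questionnaires and re-run analyses), `evidence_for()`
(supporting/refuting findings per diagnosis), `autoplot()` methods for
beliefs, sessions and evaluations, and a command-line front-end at
`inst/cli/redeye.R` with `interview`, `diagnose`, `evaluate`, `simulate`
and `validate-kb` subcommands.

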