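---
title: "Dynamic Bayesian workups for the red eye: model, policy, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Bayesian workups for the red eye: model, policy, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redeye)
library(dplyr)
```

## The problem

A red eye is one of the most common ocular presentations in front-line
care, and the conditions behind it range from the trivial (subconjunctival
blood) to the sight-threatening (corneal ulcer, acute angle-closure
glaucoma, iritis, endophthalmitis). Static flowcharts walk every patient
through the same fixed question sequence; a specialist instead keeps a
ranked differential in mind and picks the next question by how much its
answer could move that differential. `redeye` implements that behaviour as
an open, editable knowledge-base-driven engine, together with the
evaluation statistics used to assess such triage tools and a synthetic
patient generator so the whole pipeline is testable end to end.

## The probabilistic model

The knowledge base (KB) defines diagnoses $d_1,\dots,d_m$ with prior
weights $\pi_j$ (renormalized to sum to 1) and questions $q_1,\dots,q_K$.
Each question stores a table $\theta_{kj} = P(\text{YES} \mid d_j)$ — its
ability to stratify the diseases. Given answers $a_1,\dots,a_t$ the
posterior over diagnoses is the naive-Bayes product

$$P(d_j \mid a_{1:t}) \;\propto\; \pi_j \prod_{k \le t} L_k(a_k \mid d_j),
\qquad
L_k(a \mid d_j) = \begin{cases}
\theta_{kj} & a = \text{YES}\\
1-\theta_{kj} & a = \text{NO}\\
1 & a = \text{I don't know},
\end{cases}$$

updated sequentially by `update_posterior()` with renormalization after
every answer. The assumptions this buys and their costs:

* **Conditional independence of answers given the diagnosis.** Real
  symptoms are correlated (pain and photophobia travel together), so the
  posterior is overconfident in exactly the way all naive-Bayes systems
  are. The ranking behaviour — which is what the differential displays —
  is robust to this in practice.
* **"I don't know" is evidence-free.** An undocumented finding multiplies
  every diagnosis by 1. This mirrors how incomplete referral
  questionnaires must be scored (an unanswered checklist item should not
  move the differential) and makes the belief invariant to padding with
  unknowns, a tested property.
* **Hard rule-outs as 0/1 probabilities.** A conditional probability of 0
  (or 1) sends the posterior to exactly zero on the corresponding answer.
  One mechanism covers "rules out", "significantly reduces" and
  "significantly increases" (0 / low / high values). If an answer would
  zero out *every* diagnosis the library raises a contradiction error; the
  interactive and batch front-ends downgrade it to a logged skip so a
  single inconsistent answer cannot destroy a session.

Updates run in linear space with renormalization each step: sessions are at
most a few dozen questions, so underflow is not a practical concern, and
linear space keeps hard zeros exact. Comparisons use a $10^{-9}$ tolerance.

Because the posterior is a normalized product, the answer *order* is
irrelevant to the final belief (commutativity) — batch diagnosis can feed
recorded answers in any order and must agree with an interactive session,
both tested invariants.

## Question selection: value of information

After a fixed opening set (3–4 screening questions, asked in KB order),
the engine picks the eligible question with the greatest potential to move
the differential. For candidate question $k$ and answer
$a \in \{\text{YES}, \text{NO}\}$, let $b^a$ be the belief updated by that
answer and

$$d_a = \tfrac{1}{2}\sum_j \lvert b^a_j - b_j \rvert$$

the total-variation distance from the current belief $b$. Two aggregation
modes are provided (`settings.voi_mode`):

* `max` (default): $\max(d_\text{YES}, d_\text{NO})$ — the best-case
  pre-test to post-test change, reading "potential difference" literally;
* `expected`: $P(\text{YES})\,d_\text{YES} + P(\text{NO})\,d_\text{NO}$
  with $P(\text{YES}) = \sum_j b_j \theta_{kj}$ — the predicted change.

Both are defensible operationalizations of best-case versus average-case
discrimination; neither is claimed to replicate any particular proprietary
implementation, and the choice is a logged KB setting. "I don't know"
never changes the belief, so it is excluded from the score. A
contradictory branch (an answer that would zero out everything)
contributes $d_a = 0$. Ties break by KB declaration order, making
selection fully deterministic.

Eligibility imposes the two clinical constraints a specialist applies:
**prerequisites** (the whitish-opacity and contact-lens questions only
become askable once fluorescein staining is confirmed — the finding that
makes them informative) and **redundancy elimination** (a positive stain
permanently removes the chronic-tearing question, whose answer would add
no diagnostic value once the tear film's disruption is already explained).
Both are declarative KB content, not engine special cases.

## Stopping and the low-confidence flag

The interview stops when the user quits, the bank is exhausted, or the top
diagnosis *heavily outweighs* the runner-up. "Heavily" is quantified as
top $\ge \theta \times$ second **and** top $\ge$ a posterior floor;
defaults $\theta = 5$ and floor $0.5$, both editable KB settings. The
conjunction prevents an early stop when everything is merely flat (0.05 vs
0.01 satisfies the ratio but decides nothing).

If the session stops with the belief still within total variation 0.05 of
the prior, it is flagged `low_confidence`: the questioning achieved no
discrimination and the "top" diagnosis is essentially the prior mode. This
guards the known failure mode of likelihood-ranked differentials on
finding-free presentations — a case with no positive findings otherwise
yields an arbitrary, confidently-displayed diagnosis. The flag surfaces
the situation rather than silently resolving it.

Urgent diagnoses (corneal ulcer, acute angle-closure glaucoma, iritis,
endophthalmitis/severe inflammation in the default KB) are never dropped
from a rendered differential while they retain any posterior mass,
regardless of rank cutoff — critical conditions stay in view.

## The default knowledge base

The default KB (`default_kb()`, shipped as
`inst/extdata/redeye-kb.yaml` with a JSON-schema description alongside)
covers 15 red-eye diagnoses and 24 bedside questions requiring no slit
lamp beyond noting fluorescein uptake and gross corneal opacity. **All
conditional probabilities are authored clinical content, not fitted
estimates.** They were written to encode each condition's textbook
signature — near-pathognomonic markers such as a subconjunctival blood
patch (0.98), corkscrew vessels for AVM (0.97), lid crusting for
blepharitis (0.97), raised pressure for angle closure (0.97) — with
mutually distinct answer profiles across diagnoses, and calibrated once so
that classic presentations rank as a clinician would expect (a stained eye
with a whitish opacity in a lens wearer tops out at corneal ulcer; firm
eye plus fixed pupil at angle closure; withdrawing a staining finding
lets scleritis re-enter behind keratitis). Priors reflect relative
presentation frequency in front-line care (conjunctivitis and
keratitis/abrasion common; AVM and endophthalmitis rare). External
pathologies that are usually clinically apparent (cellulitis, hordeolum,
chalazion, pingueculitis, trauma, penetrating injury) are deliberately
outside the ontology; the evaluation layer maps such gold labels to an
`other` bucket that always scores as an algorithm miss.

Anyone can replace the KB: the engine is KB-agnostic, every structural
invariant is machine-checked by `validate_kb()` (unique ids, resolvable
references, probabilities in $[0,1]$, complete answer models, acyclic
prerequisites), and serialization round-trips losslessly.

## Evaluation statistics

`evaluate_cases()` reproduces the outcome measures used in clinical
evaluations of diagnostic aids:

* **Top-k accuracy** (k = 1, 2, 3): the gold-standard diagnosis appears
  among the k highest-ranked diagnoses. A referrer who attempted no
  diagnosis scores incorrect; an `other` gold label can never match.
* **Urgency triage**: a case is classified urgent iff its *top* diagnosis
  carries the urgent flag; sensitivity and specificity follow, each with
  an exact two-sided **Clopper–Pearson** interval from beta quantiles:
  lower $= B^{-1}(\alpha/2;\, x,\, n-x+1)$, upper
  $= B^{-1}(1-\alpha/2;\, x+1,\, n-x)$. The exact method is used because
  triage evaluations on dozens of cases sit exactly where approximate
  intervals misbehave; the implementation is verified against
  `stats::binom.test` over the whole small-$n$ grid.
* **Concordance-count re-analysis**: `concordance_eval()` accepts a
  per-cluster count table directly (one row per gold diagnosis: n,
  referrer correct, top-1/2/3 correct), so published accuracy tables can
  be re-analyzed without raw cases. The shipped fixture
  `concordance-counts.csv` carries the per-cluster counts from a published
  57-patient emergency-department evaluation of this approach; running it
  through `concordance_eval()` reproduces every printed percentage.

Percentages are rounded half-up to one decimal and CI bounds half-up to
whole percents, the rounding conventions of clinical reports (`round()`'s
round-half-to-even would print 84.65 as 84.6). One consequence is
documented rather than hidden: a specificity of 29/31 computes to 93.5%
at one decimal, while the evaluation this package models printed 93.6%;
the package reports the arithmetically correct 93.5%, and the CI bounds
(which match exactly) are the quantities used for cross-checking.

## The synthetic-patient generator

`simulate_cases()` draws a gold diagnosis from a prevalence vector, then
each answer as Bernoulli($\theta_{kj}$) under the gold diagnosis — exactly
the engine's generative model — then flips it with probability
`noise_rate` and blanks it to unknown with probability `unknown_rate`.
Defaults are chosen to emulate referral questionnaires: `unknown_rate =
0.3` (a large share of checklist findings go undocumented in practice,
which is why evaluation pipelines score blanks as "I don't know") and
`noise_rate = 0.05` (the order of referrer-versus-specialist disagreement
observed on individual findings such as corneal staining). Two prevalence
presets exist: the KB priors, and `"ed-mix"`, the gold-standard case mix
of the published emergency-department evaluation (keratitis/abrasion-,
iritis- and ulcer-heavy, several benign conditions absent).

Because generator and engine share the conditional-independence
assumption, recovery experiments validate the *software* — that the
update, ranking and batch machinery are correct — and say nothing about
clinical validity on real, correlated symptoms. With noise and
missingness at zero the engine is the Bayes classifier for the generating
model, and on the default KB it recovers the simulated diagnosis in
$\ge 95\%$ of 1,000 cases, degrading monotonically as answer noise rises —
both asserted in the test suite. Real questionnaires, with correlated
findings and systematic (not random) referrer error, will do worse; the
published evaluation's 68–81% top-1/2/3 range is the realistic benchmark.

## Problem sizes and numerical choices

The test suite exercises random KBs up to 15 diagnoses by 30 questions,
200-state property checks for the Bayes oracle and the greedy-equals-
exhaustive-argmax policy check, and 1,000-case recovery batches with
500-case noise curves at three replicate seeds — sizes at which every
property is informative while the whole suite runs in a few minutes.
Normalization and commutativity are asserted to $10^{-9}$; the VOI and
ranking tie-breaks are deterministic by construction, so identical inputs
give byte-identical outputs (the simulator's CSV determinism is asserted
byte-for-byte).

## Known limitations

* Conditional independence given diagnosis: no modelling of symptom
  co-occurrence beyond what the diagnosis explains.
* Binary questions only; "moderate/severe pain" style gradations are
  encoded as separate thresholds in question wording, not ordinal scales.
* One-step-lookahead (greedy) question selection; no question costs.
* The default KB's probabilities are expert-authored, not estimated from
  data, and the sharp marker probabilities that make synthetic recovery
  clean will be optimistic for real presentations.
* Posteriors are reported as normalized probabilities; if the underlying
  clinical truth is better described by unnormalized suspicion scores,
  the displayed numbers remain interpretable as relative suspicion.
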