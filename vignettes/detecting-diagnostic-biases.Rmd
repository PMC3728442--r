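---
title: "Detecting cognitive heuristics and biases in diagnostic reasoning logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cognitive heuristics and biases in diagnostic reasoning logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxbias)
```

## The problem

When clinicians reason over a case they take cognitive shortcuts
(heuristics). A shortcut that lands on a correct diagnosis is appropriate
use; the same shortcut landing on an incorrect diagnosis is a bias, and
biases are a recognised contributor to diagnostic error. `dxbias`
operationalises seven such phenomena — anchoring, availability,
confirmation, gambler's fallacy, representativeness, search satisficing,
and over/underconfidence — as deterministic rules over event logs of
diagnostic work: ordered streams of *identify finding*, *add hypothesis*,
*add diagnosis*, *link*, *delete*, *mark confidence*, and *close case*
actions, recorded per participant and case. The setting the package
models is a virtual-slide dermatopathology exercise in which participants
work two 20-case sub-domain sequences (subepidermal vesicular and
nodular/diffuse dermatitides), but nothing in the rules is specific to
that domain: any controlled-vocabulary action log with case ground truth
can be analysed.

The unit of analysis is the case. A case may carry several labels, and a
label is attached at most once per case no matter how many episodes
within the case satisfy its rule.

## Ground truth and correctness

A `knowledge_base()` holds the finding and diagnosis vocabularies, the
support/refute relations between them, and the *taught pairs* — the
finding–diagnosis associations explicitly presented in the study material,
which the representativeness rule treats as the learned model. Case truth
(`load_cases()`) gives each case an *acceptable diagnosis set*: any member
counts as a correct answer. A final differential with no acceptable member
is `incorrect`; one containing some but not all members is
`correct_incomplete`; a superset of the acceptable set is
`correct_complete`. Superset containment is the operational reading of a
"complete" differential, so extra wrong diagnoses alongside the full
acceptable set do not demote the verdict — correctness is
membership-based throughout.

Replay semantics (`evaluate_session()`): actions are ordered by their
sequence number; timestamps are informational only. `DELETE_ITEM` removes
an entity from the live state that defines the final differential and the
scoreable confidence items, but the original add event stays visible to
the pattern rules — a pattern is something the participant *did*, and
deleting an entity later does not undo having done it. A case without
`CLOSE_CASE` is not completed and contributes to no rule and no
denominator. Confidence marks are only legal after `CLOSE_CASE`, matching
a flow in which self-assessment happens once the case is concluded.

## The eight rules

* **Anchoring** (heuristic and bias, single case). An episode starts at a
  hypothesis entered before (some of) the findings; the episode's
  findings are every finding added after it in the case. A diagnosis
  entered after at least one such finding closes an episode: if all
  episode findings support it (whether or not it equals the hypothesis),
  the episode is the heuristic; if not, and no later hypothesis or
  diagnosis in the case is supported by all episode findings, the
  participant failed to adjust and the episode is the bias. Every episode
  is evaluated and the case carries the union, so one case can be both
  `ANCHOR_HEURISTIC` and `ANCHOR_BIAS` through distinct episodes.
* **Confirmation bias** (single case). An incorrect diagnosis is entered
  and the participant then identifies a finding that supports it. The
  default reading requires the supporting finding to be the *next*
  diagnostic action (`confirmation_window = "next"`); the laxer
  `"any_later"` window exists for sensitivity analysis because the two
  plausible readings of "then adds findings" genuinely differ.
* **Search satisficing** (single case). Any findings identified precede
  the hypotheses; a hypothesis is followed by a diagnosis with no
  intervening finding; the verdict is `incorrect` or
  `correct_incomplete`; and nothing else is added before the case is
  closed — premature closure on the first plausible answer.
* **Representativeness** (heuristic and bias, whole session). A finding
  immediately followed by a diagnosis, where the pair is a taught pair,
  is one occurrence of replaying the learned prototype. Only pairs
  occurring more than once in the session qualify — a single use is not
  evidence of a rigid mapping. Each qualifying occurrence labels its own
  case by the correctness of the diagnosis *there*, so the same pair can
  yield `REPR_HEURISTIC` in one case and `REPR_BIAS` in another.
  Occurrences are pooled across both sub-domain sequences.
* **Availability bias** (case sequence). On a designed opportunity — two
  consecutive cases sharing an acceptable set followed by a case whose
  set is disjoint from it — the participant answers incorrectly with a
  member of the predecessors' set. Because a case summary revealing the
  correct diagnosis follows every completed case, exposure depends on the
  predecessors having been *completed*, not answered correctly, so only
  case truth matters on the predecessors.
* **Gambler's fallacy bias** (case sequence). On an opportunity where all
  three consecutive cases share the acceptable set, the participant gives
  the same final differential on the first two cases (correct or not)
  and then a different, incorrect one on the third — the diagnosis is
  rejected for having come up too often. Here the participant's own
  predecessor answers are what matters.
* **Over/underconfidence**. See the bias score below.

`DELETE_ITEM` and `MARK_CONFIDENCE` are transparent to all sequence
rules: "immediately followed" always means the next diagnostic add
action (`ADD_FINDING`/`ADD_HYPOTHESIS`/`ADD_DIAGNOSIS`/`ADD_LINK`).
Refuting relations are stored for log fidelity but no rule consumes
them; none of the rule texts references them.

## The confidence bias score

After closing a case the participant marks each identified item `sure` or
`unsure`. The scoreable items are the findings and diagnoses live at
close, weighted equally; hypotheses and links, though markable in the
original interface, are excluded because the metric is defined over
findings and diagnoses. With `s` items marked sure, `c` items correct,
and `n` items in total, the case score is

\[ \mathrm{bias} = (s - c) / n \in [-1, +1], \]

+1 being complete overconfidence (sure of everything, right about
nothing), −1 complete underconfidence, and 0 the optimum. The score is
totals-based: a sure-wrong item can offset an unsure-right item, so 0
does not imply per-item matching. An unmarked scoreable item is treated
as `unsure` with a warning; a case with no scoreable items has no score.
A participant's score is the unweighted mean over scoreable completed
cases (`weight = "item"` pools the totals instead, weighting large cases
more).

## Sequence design

`build_default_plan()` lays out, per sub-domain, a 20-case sequence
containing exactly 5 gambler's-fallacy and 3 availability opportunity
cases — 10 and 6 over the two sequences. Non-overlapping opportunity
*triples* cannot fit: five gambler triples and three availability triples
would need 24 cases. The builder therefore embeds gambler opportunities
as *runs* of identical-diagnosis cases (a run of length `r` contributes
`r − 2` sliding-window opportunities; the default uses runs of 4, 4, and
3) and realises each availability opportunity by appending a
disjoint-diagnosis case directly after a run's tail. Remaining positions
are padded with cases whose acceptable sets are pairwise distinct, so no
further window qualifies. The opportunity *case* sets remain disjoint —
an availability opportunity requires the third set disjoint from the
predecessors', a gambler opportunity requires it equal. "Same diagnosis"
between cases means equal acceptable sets and "different" means disjoint
sets; partial overlap deliberately makes a triple neither kind of
opportunity, because designed sequences are clean and a partially
overlapping triple has no unambiguous reading. Enumeration
(`enumerate_opportunities()`) always recomputes opportunities from case
truth and slides windows by one, so hand-written plans with overlapping
triples are analysed correctly. The seed only shuffles which diagnosis
groups fill which blocks; the counts are structural.

## The simulator

`simulate_cohort()` exists so every detector can be validated against
known ground truth. Agents are pattern emitters, not cognitive models:
per case, at most one bias pattern is injected, each constructed to
satisfy its rule exactly and to trigger no other rule, and recorded in
the cohort's `truth`. Injections are mutually exclusive within a case
(priority: satisficing, availability, gambler's, confirmation, anchoring,
representativeness) and sequence biases are injected only on their own
opportunity cases while case-level biases are injected only off them;
this keeps every truth label unambiguous at the cost of not modelling
co-occurring biases, which real logs can contain. A representativeness
injection is only recorded as truth when its taught pair fired at least
twice in the session, since a single occurrence is undetectable by the
rule's own definition.

When no bias fires the agent emits a default stream: each true finding
identified with probability `p_find` in canonical order, a hypothesis,
then with probability `p_dx` the full acceptable set as the final
differential, otherwise a wrong diagnosis. An erring default agent
articulates a competing hypothesis between its wrong diagnosis and
closing; without that, every ordinary wrong answer would structurally
coincide with the satisficing pattern and "no bias injected" would be
unrepresentable. Note what this does *not* remove: an unbiased wrong
answer on a gambler opportunity whose predecessors were answered
consistently still *is* gambler's fallacy by the rule — the rule cannot
distinguish random error from fallacy there, which is why the
false-positive guarantee is stated at the null configuration
(`p_dx = 1`, all propensities zero) and why rate-recovery checks hold
`p_dx = 1`.

Default profile parameters (all probabilities, all overridable) emulate
the cohort the package targets: `p_dx = 0.32` (roughly two thirds of
cases misdiagnosed — these are typical presentations of rare entities
worked by non-specialists), `p_find = 0.7`, satisficing propensity rising
with training level (0.14/0.27/0.30) and gambler's propensity 0.04/0.10/
0.10, availability 0.20, confirmation 0.01, anchoring bias 0.06,
representativeness bias 0.02, and `p(sure | correct) = 0.75`,
`p(sure | incorrect) = 0.45`, which centres participants mildly on the
overconfident side. Each participant gets an independent RNG stream
seeded `seed + index`, so a cohort is byte-identical under re-simulation
and stable under profile reordering.

## Reporting conventions

`frequency_table()` reports, per participant and label, flagged cases
over the number of completed cases in which the label could occur: all
completed cases for the four case-level rules, and completed opportunity
cases *whose two predecessors were also completed* for availability and
gambler's fallacy (no completed predecessors, no exposure, no
opportunity). Percentages print to one decimal; a zero denominator is
missing, not zero. Distributions of such counts are not normal, so
summaries are medians with an RMS deviation about the median, and group
comparisons (`compare_groups()`) use Kruskal–Wallis plus pairwise
Mann–Whitney with tie-corrected normal z and effect size
r = |z|/√n; no multiple-testing adjustment is applied, which the output
records. `error_bias_association()` classifies completed cases by error
(incorrect final diagnosis) and reports the share of error cases with at
least one bias label and of correct cases with at least one heuristic
label; per-label breakdowns are normalized for opportunity, with the
denominator defaulting to error cases that were opportunities (the
alternative — all completed opportunities — is a flag, because both
readings are defensible).

## Numerical and degenerate-input choices

Labels are case-sensitive exact strings after whitespace trimming — the
original interfaces forced menu selection, so fuzzy matching would only
mask data errors. Sequences shorter than three cases simply yield empty
opportunity sets. A closed case with an empty final differential has no
diagnosis verdict and is excluded from verdict-dependent rules. Duplicate
`(participant, case, seq)` keys, double closes, confidence marks before
close, and relations over undeclared vocabulary are hard errors naming
the offending record: silent repair of a corrupt log would bias
downstream frequencies.

## Validation strategy and its limits

The test suite validates the detectors three ways: worked single-case
streams with hand-derived labels; brute-force oracle equivalence, where
each rule is re-implemented as an independent exhaustive sub-sequence
scan and compared with the detectors on 1,000 random sessions of up to
12 events per case over a 4-diagnosis domain; and simulator-based checks
— recall 1 on injected patterns, zero detections on the null
configuration, and injected propensities of 0.1/0.3/0.5 recovered within
the exact two-sided 95% binomial acceptance region over at least 150
eligible cases per configuration. Rate recovery runs on cohorts of 7–26
agents over the default 40-case plan, sizes chosen to clear the
150-eligible-case floor per bias.

What passing these tests does and does not show: the rules are faithful
to their stated definitions and internally consistent, and the pipeline's
denominators and scores are arithmetically right. The simulator's agents
emit clean patterns; real participants interleave actions, change their
minds, and commit overlapping biases, so agreement on synthetic cohorts
bounds implementation error, not construct validity. Cohort-level
frequencies from real logs depend on the participants and the case mix
and are not reproducible from this package alone.

## Known limitations

Only the seven measured phenomena are detected — no base-rate neglect,
no premature-closure variants beyond the satisficing rule. Whether the
original anchoring rule evaluated only a case's first episode is unknown;
evaluating every episode is the more informative choice. Whether
availability required the echoed diagnosis to be the *sole* member of the
final differential is likewise unknown; membership is used. Deletion
handling (live-state final differential, rules see all adds) is a
convention worth sensitivity analysis on real logs. The `ADD_LINK` event
is carried and counts as a diagnostic action for immediacy, but no rule
consumes link polarity.
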