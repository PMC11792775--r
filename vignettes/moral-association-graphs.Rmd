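---
title: "Moral association graphs: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moral association graphs: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralassoc)
```

## The model

Word-association norms record, for each cue word $c$, how many participants
produced each response word $t$: an asymmetric count matrix $A_{c,t}$. Given
a moral lexicon $M$, the moral association graph score of a cue is

$$\mathrm{MAG}(c) \;=\; \frac{\sum_{t \in T(c) \cap M} A_{c,t}}
                             {\sum_{t \in T(c)} A_{c,t}},$$

the count-weighted proportion of the cue's responses that are moral
vocabulary. The quantity is a proportion, so cues annotated by different
numbers of participants (SWOW-EN's 100 per cue versus SWOW-RP's 70) are
directly comparable without further normalization. There are no fitted
parameters; `mag()` is a "fitting" function only in the sense that it
evaluates this ratio for every cue and returns a model object with the
usual methods (`coef`, `predict`, `summary`, `plot`, `simulate`).

The model's substantive assumption is that moralization is visible in
first-order associations: if a concept has acquired moral relevance, moral
words are produced as immediate responses to it. The score inherits the
norms' population and era, and it is count-limited: with $n$ responses per
cue the score has binomial standard error $\sqrt{\theta(1-\theta)/n}$,
about 0.05 at $n = 100$ — differences smaller than that are noise.

## Lexicons and normalization

Lexicon entries are either literal tokens or prefix wildcards (`kill*`),
mirroring how the Moral Foundations Dictionary distributes stems. Literal
entries pass through the same normalization as data tokens so the two
sides align; wildcard stems are never lemmatized (lemmatizing a stem can
detach it from the surface forms it is meant to cover). Entries may carry a
foundation (care, fairness, loyalty, authority, sanctity, general) and a
polarity (virtue, vice); `foundation_sublexicon()` restricts to one
foundation, and when the labels partition the lexicon the per-foundation
scores of a cue sum exactly to its overall score, a property the test
suite checks.

Token normalization lowercases, trims and collapses whitespace, then
applies a rule-based English noun lemmatizer (`lemmatize_noun()`): an
irregular-plural table followed by ordered suffix rules (`-ies -> -y`,
`-sses/-ches/-shes/-xes/-zes` strip `es`, `-ves -> -f`, final `-s`
stripped, with `-ss/-us/-is` protected). It is deterministic and
dictionary-free, so it handles regular plurals correctly and leaves
everything else alone; it is not a full morphological analyzer, and a flag
disables it for non-English data. Multi-word responses are kept as single
tokens (spaces collapsed) and match lexicons as whole strings — the
conservative choice; `keyword_prf(split_phrases = TRUE)` offers
constituent-token matching where a looser criterion is wanted.

Missing-response sentinels (`NA`, the empty string, `Unknown word`,
`No more responses`, case-insensitive, configurable) are dropped before
counting. Duplicate (participant, cue, response) rows are counted each
time they occur, because $A$ is defined as a participant count and the
data formats carry no session identity that would justify deduplication.

## The interpretability walk

For one cue, the response co-occurrence graph $G_c(V, E)$ has the cue's
responses as nodes and, as edge weights, the number of participants who
gave both endpoint words. The walk iterates

$$p^{(t+1)} = \beta \tilde A\, p^{(t)} + (1-\beta)\, m$$

with $\tilde A = D^{-1/2} W D^{-1/2}$ the symmetrically normalized
adjacency and $m$ the restart distribution: mass proportional to weighted
degree on lexicon-matching nodes, zero elsewhere, normalized to sum to 1.
The top-$K$ nodes of the converged $p$ are reported as the keywords that
explain the cue's moralization. Moral nodes are not excluded from the
ranking — they are typically its most informative members.

Defaults and their rationale:

* **beta = 0.5** — equal weight to diffusion and restart; the walk reaches
  second- and third-order neighbors of the moral words without drifting
  into the global graph structure.
* **K = 25** — a readable keyword list; purely presentational.
* **tol = 1e-8, max_iter = 10000** — `tol` bounds the L-infinity distance
  of the returned vector from the exact fixed point
  $p^* = (1-\beta)(I - \beta\tilde A)^{-1} m$. Because $\tilde A$ is only
  guaranteed non-expansive in the spectral norm (its rows can sum to more
  than 1), stopping on the raw successive change would not certify that
  bound; the iteration therefore stops when the successive change falls
  below $\mathrm{tol}\,(1-\beta)/(\beta\sqrt{|V|})$, which does, via the
  contraction inequality. At $\beta = 0.5$ convergence is geometric and
  typically takes 30–60 iterations; $\beta = 0$ is exact after one update.

Further numerical choices: ties in the keyword ranking are broken
lexicographically so output is reproducible; isolated nodes (responses
given only by single-response participants) stay in $V$ with zero rows in
$\tilde A$ and zero restart mass, so they can never accumulate rank —
effectively excluded while keeping $|V| = |T(c)|$; the cue itself is not a
node, since it is not a response to itself. An edgeless graph or a graph
with no positive-degree moral node makes the walk undefined and raises a
classed error naming the cue.

The initial distribution $p^{(0)} \propto 1/|V| + \mathrm{MAG}(v)$
(each node's own score as a cue, uniformly smoothed) is provided for
completeness, but for $\beta < 1$ the fixed point is independent of the
initialization — the property tests verify two arbitrary starting vectors
agree to within $10\times$ tolerance. The initialization would matter only
under early truncation, which the package does not do: it iterates to
convergence.

## Document scoring

A document's score is the unweighted mean of the MAG scores of its covered
lemma occurrences. Two open choices are resolved as follows, each behind a
flag:

* Lemmas that are not cues in the norms are **skipped**, not scored zero
  (`zero_fill = FALSE`): zero-filling would make document scores a
  function of out-of-vocabulary rate rather than moral association.
* Averaging is **per occurrence**, not per type
  (`type_weighted = FALSE`): a word used three times contributes three
  times.

A document with no covered lemma gets an undefined (`NA`) score — a
flagged value, deliberately distinct from 0.

## Two-wave change analysis

`delta_scores()` scores the same words in two waves of norms and records
`after − before`. Words absent from either wave are reported in an
attribute, never silently dropped. The analysis then focuses on words with
strictly positive deltas — those that acquired new moral associations:

* **Rank-sum contrast** (`wilcoxon_contrast`): one-sided by default
  (target group greater), since the substantive hypothesis is directional;
  two-sided is available. Normal approximation with tie correction.
* **Permutation contrast** (`permutation_contrast`): statistic = mean
  delta of the target group minus mean delta of all other words; p-value
  $(1 + \#\{\text{permuted} \ge \text{observed}\})/(1 + n_{\mathrm{perm}})$
  with seeded, reproducible label shuffles, $n_{\mathrm{perm}} \ge 1000$
  enforced. Run on the positive-delta subset by default
  (`positive_only = FALSE` uses all words).
* **precision@K** (`precision_at_k`): fraction of the top-K words by delta
  (lexicographic tie-break) belonging to the target group, with the
  group's overall share reported as the chance level. Computed over all
  words by default, since restricting to positive deltas would change the
  chance level K-dependently.

Group contrasts are run pairwise (e.g. pandemic versus control, routine,
emotion) rather than omnibus, matching how such two-wave designs are
reported.

## The synthetic generator

`simulate_associations()` plants a per-cue probability $\theta_c$ that a
response slot draws from the moral sub-vocabulary; the returned lexicon is
exactly that sub-vocabulary, so $\theta_c$ is recoverable by the MAG score
up to binomial error — the ground truth for every recovery test. Defaults
are chosen to emulate large association norms: 100 participants per cue,
three response slots each, $\theta \sim U(0, 0.6)$ (moral association
proportions are low for most everyday concepts; 0.6 caps at strongly
moralized ones), a 200-word vocabulary of which 20% is moral.
`simulate_two_wave()` draws two waves over shared vocabulary with
$\theta + \mathrm{shift}$ on a designated subset, labeled `pandemic`
against `control`. Optional co-occurrence blocks make a participant draw
all slots from one token cluster, planting the community structure the
walk needs for non-trivial rankings.

What the generator does **not** emulate: realistic lexical content, Zipfian
response frequencies, the heavy-tailed cue-response overlap of real norms,
spelling variation, or multilingual data. Passing tests therefore
demonstrate correctness of the computations and calibration of the
statistics under known structure — not that real norms satisfy the model's
assumptions.

## Problem sizes and verification

The test suite verifies the score against a record-by-record brute-force
count on 100 random datasets (exact integer agreement), the walk against a
direct linear solve on graphs up to 50 nodes (L-infinity error at most
1e-8), recovery of $\theta$ over 200 cues at 100 responses each (Spearman
at least 0.95, RMSE at most 0.06), null calibration of both contrasts over
500 replicates (rejection at $\alpha = 0.05$ between 3% and 8%), and
detection of a +0.2 shift planted on 50 of 500 cues (rank-sum p < 0.01,
permutation p <= 0.05, precision@25 at least 0.7). These sizes keep the
full suite under a minute while leaving the binomial and Monte-Carlo error
margins comfortably inside the asserted bounds. `scripts/acceptance.R`
recomputes the same quantities from scratch for any seed.

## Limitations

The score is bounded by lexicon coverage: a concept moralized through
vocabulary outside $M$ scores low. Association norms are slow and costly
to collect, so temporal resolution is limited to the waves available.
The lemmatizer is rule-based English; disable it elsewhere. Scores for
cues with few retained responses are noisy, and the package deliberately
does not smooth or shrink them — the integer numerator and denominator are
always reported so users can filter by evidence.
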