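# moralassoc

Moral association graphs from human word-association data.

## What it does

When people moralize a concept — cigarettes, abortion, masks — the change
shows up in what the concept makes them think of. `moralassoc` quantifies
this from word-association norms (SWOW-style data, where participants see a
cue word and produce up to three responses). The core statistic is the
**moral association graph (MAG) score** of a cue *c*:

    MAG(c) = Σ_{t ∈ T(c) ∩ M} A[c,t]  /  Σ_{t ∈ T(c)} A[c,t]

where `A[c,t]` is the number of participants who responded *t* to cue *c*,
`T(c)` is the cue's response set, and `M` is a moral lexicon such as the
Moral Foundations Dictionary (literal words and `stem*` wildcards, with
foundation and virtue/vice labels). The score is the count-weighted
proportion of a concept's associations that are moral vocabulary: a
parameter-free measure of moral relevance in [0, 1]. Swapping in an emotion
lexicon gives the EAG (emotion association) variant; restricting `M` to one
foundation's words gives a five-dimensional foundation profile.

To *explain* a score, the package builds the cue's response co-occurrence
graph (edge weight = number of participants who gave both responses) and
runs a damped random walk with restart toward the lexicon-matching nodes,

    p(t+1) = β Ã p(t) + (1 − β) m,      β = 0.5 by default,

with `Ã` the symmetrically normalized adjacency matrix and `m` the
degree-weighted restart distribution over moral nodes. The top-K nodes of
the fixed point (K = 25 by default) are the associative contexts in which
the cue is moralized.

Around this core the package provides document scoring by lemma averaging,
evaluation harnesses (Spearman rank correlation against external ratings;
precision/recall/F1 of retrieved keywords), a two-wave analysis of
short-term moral change (per-word score deltas, rank-sum and permutation
contrasts, precision@K retrieval of shifted words), and a seeded synthetic
generator with planted moral-association probabilities so the whole
pipeline is testable without any external dataset.

Intended users: computational cognitive scientists and NLP researchers
working with association norms, moral lexicons, or lexicon-induction
evaluation.

## Worked example

```r
library(moralassoc)

# A synthetic association norm: 6 cues x 100 participants x 3 responses,
# each with a known (planted) probability theta of drawing a moral word.
sim <- simulate_associations(n_cues = 6, n_participants = 100, seed = 42)
fit <- mag(sim$data, sim$lexicon)
fit
#> Moral association graph model (lexicon 'synthetic-moral')
#>   6 cues scored; mean score 0.4111, range [0.1567, 0.6000]

cbind(head(fit$scores, 3), theta = head(sim$theta$theta, 3))
#>       cue     score n_matched n_total     theta
#> 1 cue0001 0.6000000       180     300 0.5488836
#> 2 cue0002 0.5666667       170     300 0.5622452
#> 3 cue0003 0.1566667        47     300 0.1716837
```

Each score is the integer ratio `n_matched / n_total` and estimates the
planted theta to binomial accuracy (here within ±0.05 at 300 responses).
The rank agreement between truth and estimate:

```r
rank_correlation(sim$theta$theta, coef(fit))
#> $rho
#> [1] 0.9428571
#> $p
#> [1] 0.004804665
```

Which associations carry the score? The random walk over the cue's
response co-occurrence graph ranks them:

```r
w <- mag_explain(sim$data, sim$lexicon, "cue0002")
w
#> Random-walk interpretation for cue 'cue0002'
#>   converged: TRUE after 24 iterations
#>   top 4 keywords:
#>       keyword       p is_moral
#>  moralterm034 0.03747     TRUE
#>  moralterm017 0.03599     TRUE
#>  moralterm014 0.03478     TRUE
#>  moralterm019 0.03431     TRUE
```

With real SWOW data loaded via `read_associations()` and the MFD via
`read_lexicon()`, the same calls score and explain real concepts;
`delta_scores()` + `wilcoxon_contrast()` / `permutation_contrast()` /
`precision_at_k()` run the two-wave change analysis, and `predict(fit,
texts)` scores documents.

A command-line wrapper (`exec/moralassoc`, or `mag_cli()` in-process)
exposes the pipeline as subcommands: `score`, `foundations`, `score-docs`,
`interpret`, `change`, `eval-corr`, `eval-prf`, `simulate`.

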