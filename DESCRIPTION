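Package: moralassoc
Title: Moral Association Graphs from Word-Association Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the moral relevance of concepts from human word-association
    norms. The moral association graph (MAG) score of a cue word is the
    count-weighted proportion of its association responses that fall inside a
    moral lexicon such as the Moral Foundations Dictionary; an emotion-lexicon
    variant (EAG) and per-foundation profiles are included. A damped random
    walk with restart over each cue's response co-occurrence graph retrieves
    the associated concepts that explain why a cue is moralized. The package
    also provides document-level scoring by lemma averaging, rank-correlation
    and keyword precision/recall evaluation harnesses, a two-wave analysis of
    short-term moral change (rank-sum and permutation contrasts,
    precision-at-K retrieval), and a seeded generator of synthetic
    word-association datasets with planted moral-association probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
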