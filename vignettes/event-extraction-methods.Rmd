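---
title: "Methods: distributed-representation event extraction at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributed-representation event extraction at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bioevent)
```

This vignette documents the models, the numerical and design choices
behind them, what the synthetic corpus does and does not emulate, and
the limits of what the package's tests demonstrate.

## Pipeline and data model

The package operates on BioNLP-style standoff corpora: document text in
`.txt`, given entities in `.a1`, triggers and events in `.a2`, all
referenced by 0-based half-open character offsets. Sentence
segmentation, tokenization, POS tags and dependency trees come from
CoNLL-X files produced externally (or by the corpus generator); the
package aligns token surfaces to the text greedily left-to-right and
validates each sentence's dependency graph as a single-rooted tree.
Discontinuous spans and modification/normalization annotation lines are
out of scope.

Annotations spanning several tokens are reduced to one *anchor* token —
the last overlapping token, on the head-final-noun-phrase rationale; a
"syntactic head within span" alternative is available
(`anchor_annotation(rule = "head")`). Token-level classification of
multi-token triggers is an underdetermined part of the task
formulation, and the anchor heuristic is our resolution of it;
approximate span matching at evaluation time absorbs the off-by-a-token
consequences.

## Trigger identification

Every token is a candidate (an optional content-word POS pre-filter
exists but defaults to off, for fidelity to the all-tokens
formulation). The representation concatenates four blocks:

* **Context** (always on): word-embedding rows for the window
  `i - d_win ... i + d_win`, `d_win = 2` by default. Positions beyond
  the sentence edge use a dedicated learned padding row rather than a
  fresh random draw, so features are deterministic within a run.
  Dictionary and embedding lookup lowercase surfaces and collapse digit
  strings to a `<num>` placeholder; unseen test-time words map to a
  reserved unknown row.
* **Topic**: each word carries p(topic | word) from a collapsed-Gibbs
  LDA fit over the training sentences (the topic model is fit in
  package code — about sixty lines of standard collapsed Gibbs — since
  the R environment offers no topic-model package; it is seeded and
  deterministic). The sentence-topic feature multiplies the window
  words' distributions elementwise. The defining product formula
  indexes the trigger's context window even though a whole-sentence
  reading is also plausible; we follow the formula and expose
  `topic_scope = "sentence"` as an option. The raw product underflows
  for long windows and is scale-free as a feature, so it is computed in
  log space and renormalized to a distribution — this preserves the
  relative topic weights.
* **POS**: a trainable `d_pos`-wide embedding of the token's tag.
* **Distance**: a trainable `d_dis`-wide embedding of the
  dependency-tree distance to the *nearest* entity in the sentence,
  clipped at `max_distance = 10` with a dedicated unreachable bucket
  (used too when the sentence has no entities). The inventory of
  distance buckets must be bounded somewhere; 10 exceeds the tree
  diameter of ordinary sentences.

The classifier is a feed-forward ReLU network with softmax
cross-entropy, trained by minibatch Adadelta (rho 0.95, eps 1e-6) with
inverted dropout. Defaults follow the reference setting: word dimension
100, three hidden layers of 1000 units, batch 512, dropout 0.2. Epoch
count and early stopping are not part of that setting; the default is
30 epochs with patience-5 early stopping on a 10% validation split
(`patience = 0` disables it). The hidden activation (ReLU) is likewise
our choice where the setting is silent. POS and distance tables always
receive gradient updates; the word table is trainable by default
(`train_embeddings`), mirroring common practice. Pretrained word2vec
text-format embeddings can seed the word table; rows not covered by the
file are drawn from uniform(-0.25, 0.25) under the run seed.

## Argument detection

Candidates are all ordered (trigger, entity) and (trigger,
other-trigger) pairs within a sentence — events are taken to be
sentence-internal, so no cross-sentence pairs are generated. The pair's
dependency path (BFS shortest path between the anchors; endpoints
included) is rendered as the matrix psi(S) described in the README.
Design points:

* The two endpoint *type* embeddings are appended as two extra columns
  of the word block only (the type width equals the word width by
  construction); the POS and distance blocks carry padding entries in
  those two columns so the stacked matrix is rectangular. The original
  formulation leaves this rectangularization open; this is our reading,
  and the geometry is asserted in tests.
* The distance blocks encode *positional offsets along the extracted
  path* (0, 1, 2, ... from each endpoint), clipped like tree distances
  — position-embedding practice; tree distance proper already serves
  the trigger stage.
* Paths longer than `max_path_len` (default 20) are truncated
  symmetrically around the midpoint; shorter paths are padded. Tokens
  in distinct parse components (malformed parses) fall back to the
  linear token sequence, flagged on the example.
* The convolution applies filter widths {3, 5, 7} over the column axis
  with `n_maps` feature maps per width and max-pooling over positions,
  so the pooled width `3 · n_maps` is independent of path length. The
  reference table's "1000" is read as the dense-layer width (parallel
  to the trigger table's wording), not a feature-map count; feature
  maps default to 100 per width.

Internally, examples are padded to a fixed `max_path_len + 2` columns
with the type columns at fixed positions, which makes batched im2col
convolution and exact batch-composition invariance straightforward; the
canonical `n + 2`-column psi(S) is what `build_path_matrix()` returns.

## Event assembly and post-processing

Each trigger with at least one positive relation yields one event
carrying all its arguments (no argument-combination enumeration — the
simplest composition reading; binding-style combinatorics are a
non-goal). Post-processing applies schema-driven rules to a fixpoint:
drop roles the event type does not allow; drop event-valued fillers on
roles that may not take events; drop arguments whose filler event
disappeared; drop events lacking a core argument; break reference
cycles by removing the offending argument of the later-id event;
deduplicate. The concrete rule set used by any particular corpus
deployment is unrecoverable from published descriptions, so the rules
are driven by a declarative YAML schema (`inst/extdata/default_schema.yaml`:
regulation-family types take Theme + Cause with event-valued fillers,
everything else an entity-valued Theme) — corpus-specific conventions
are configuration, not code. Post-processing is idempotent and its
output always satisfies the schema and acyclicity; both properties are
tested.

## Evaluation

Triggers: approximate span matching — types equal and the predicted
span within the gold span extended by one *token* on each side (the
extension unit follows the tokenization in use). Events: approximate
recursive matching — types equal, triggers span-match, and a one-to-one
correspondence exists between argument lists with equal roles and
matching fillers; entity fillers match by type and approximate span,
event fillers recursively. Following the shared-task convention, the
recursive comparison of an event-valued *filler* is restricted to its
core (Theme) arguments; `recursive_core_only = FALSE` switches to full
recursive comparison. Matching within a document is greedy over
predictions sorted by offset (ties by id), each gold item consumed at
most once, which makes counts deterministic. Undefined
precision/recall (empty denominator) is reported as 0. The strict and
event-decomposition scoring modes of the shared tasks are not
implemented.

## Synthetic corpus: what it emulates, and what it does not

The generator emulates the *structure* of an MLEE-style corpus:
documents of sentences with typed entity mentions (5 entity types),
19 trigger types including a regulation family, role-labeled events
with nested (trigger-valued) Themes at probability
`nesting_probability`, and dependency trees constructed alongside the
tokens so parses are consistent by construction. The signal is lexical
and type-structural: each trigger type owns three surface inflections,
and roles follow a fixed (trigger type, entity type) → role table
recorded in the answer key, so a rule-based decoder recovers gold
events perfectly at noise 0 — this is the yardstick the learnability
tests measure models against. The `noise_rate` knob replaces trigger
surfaces with ambiguous words shared across types, destroying exactly
that signal.

The generator deliberately does *not* imitate real biomedical language:
no distributional semantics, no subword morphology shared across types,
no annotation noise or parser errors, and templated syntax only.
Passing the learnability tests therefore demonstrates that the feature
construction, the two networks, the gradient flow into the lookup
tables, assembly and scoring are correct and can extract a planted
signal end to end — it does not predict performance on real corpora,
and benchmarking against published corpus scores is out of scope.

## Problem sizes, seeds, determinism

The study configuration used by the acceptance script and the
end-to-end tests is 70 documents (50 train / 20 held-out) of 6
sentences, noise 0. At that scale the desk models — trigger network
with one 256-unit hidden layer on 48-dimensional embeddings, 60 epochs;
argument CNN with 32 maps per width and a 128-unit dense layer, 40
epochs; early stopping off for exact reproducibility — train in about
a minute on one CPU. The reference-scale defaults (`trigger_config()`,
`argument_config()`) remain the package defaults and are asserted
as such; they are simply more capacity than the synthetic task needs.

All randomness fans out from one run seed through stage-specific
derived seeds (generation, table initialization, topic fit, shuffling,
dropout). Training avoids early returns through the RNG, so a fixed
seed and config reproduce checkpoints, predictions and reports
bit-for-bit in a single-threaded BLAS; the test suite asserts this.

## Known limitations

* One event per trigger: argument-combination enumeration (e.g.
  multi-Theme binding decompositions) is not modeled.
* Token-level trigger prediction spans exactly the anchor token;
  multi-token trigger spans are recovered only up to approximate
  matching.
* The negative class is left at its natural frequency (no downsampling
  by default; a ratio knob exists) — heavily imbalanced corpora may
  need it.
* The LDA fit uses a single chain and point estimate; topic features
  are auxiliary and are not meant as a publishable topic model.
* `dependency_distance` treats the parse as an undirected tree;
  non-tree graph formats are rejected at load.
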