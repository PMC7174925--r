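---
title: "Methods: bipartite skip-gram embeddings for adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite skip-gram embeddings for adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

A spontaneous adverse-event report is two unordered sets of concept IDs:
the drugs taken and the reactions observed. `msgddi` treats each report as
a degenerate "sentence" and learns token embeddings with a skip-gram
objective in which the positional window is replaced by a bipartite rule:
within a report, the contexts of a drug are all of its reactions and the
contexts of a reaction are all of its drugs. Both directions are emitted
as training pairs; drug–drug and reaction–reaction pairs are never
emitted. The assumptions this encodes are that token order within a report
is meaningless, that repeated mentions carry no extra information
(within-report duplicates are collapsed, so all counts in the package are
document frequencies), and that the only association worth modelling at
training time is cross-side co-occurrence.

The conditional probability of a target token given an input token is
factorised by hierarchical softmax over a Huffman tree built from token
frequencies. Each of the `V - 1` internal nodes carries a vector; the
probability of a leaf is the product along its root-to-leaf path of
`sigmoid(x)` for a 0-bit step and `sigmoid(-x)` for a 1-bit step, where
`x` is the inner product of the node vector with the input embedding.
Because `sigmoid(x) + sigmoid(-x) = 1`, the probabilities over the
vocabulary telescope to exactly 1 for any parameter values, which the test
suite asserts to 1e-9.

Training is plain sequential SGD: for each directed pair, the node vectors
on the target's path and the input vector receive the analytic gradient of
the log path-probability (verified against central finite differences at
relative tolerance 1e-5). Updates are applied in deterministic corpus
order — report by report, drug-input pairs before reaction-input pairs,
each side in report order — so a corpus, a parameter set and a seed fully
determine the result to the last bit. This sequential-equivalence contract
is deliberate: it trades the throughput of lock-free threading for exact
reproducibility, which the downstream determinism guarantees depend on.

## Tunable parameters

* `dim` (default 100): embedding dimensionality. The default parallels
  common practice for concept-embedding work at corpus scale; the bundled
  experiments use 50 to match their smaller vocabularies.
* `alpha0` (default 0.025) and `min_alpha` (default 1e-4): the learning
  rate decays linearly from `alpha0` to `min_alpha` over all
  `epochs * n_pairs` updates. 0.025 is the standard skip-gram starting
  rate; the floor keeps late updates from vanishing entirely.
* `epochs` (default 5): passes over the corpus. Five passes are a common
  default for this model family on mid-sized corpora; a single pass is
  defensible on very large ones. Exposed because the right value scales
  inversely with corpus size.
* `min_count` (default 10): minimum number of reports a token must occur
  in. Ten reports per concept is the conventional support threshold for
  reliability in spontaneous-report analyses; it applies to drugs and
  reactions alike.
* Initialisation: input vectors uniform in `[-0.5/dim, 0.5/dim]` from the
  seeded generator; internal-node vectors zero. Both are the standard
  choice for this family; zero node vectors make the initial distribution
  exactly uniform over leaves.

## The TF-IDF baseline

The comparison method builds the term-by-report co-occurrence matrix with
weights `(n_ij / report_total) * log(n_reports / doc_freq)` and zero where
a term is absent. Two choices the weighting leaves open are made here
once: the logarithm is natural (any base rescales every weight by the same
constant, so PCA directions and downstream classifier ranks cannot
change), and the general count form is kept even though set semantics make
`n_ij` binary, so corpora with multiplicities would work unchanged. Term
rows are centred (not scaled — the weights share one scale by
construction) and projected onto the top `k` principal axes; `k` defaults
to 100 to parallel the embedding dimension, and the per-component sign is
fixed by making each component's largest-magnitude loading positive so
results are deterministic. PCA output is checked against a brute-force
eigendecomposition of the covariance at 1e-8.

## Labelling, cross-validation, enrichment

A drug pair is a positive example for an adverse-event class if any of
three reference strategies fires: either drug is in the class's drug list;
either drug has a toxicity record whose text contains a class keyword
(case-insensitive substring, so "cardiotox" hits "cardiotoxicity"); or the
pair itself has an interaction record with a keyword-bearing description.
The strategies are reported per pair, and the working label is their
union: the three sources are complementary evidence of the same
association, and keeping per-strategy flags preserves the ability to count
them separately. Negatives are all remaining candidate pairs — pairs
observed in two-drug reports whose drugs are in the reference drug list —
optionally subsampled (seeded) to match the positive count, since the raw
negative class otherwise dominates.

The classifier is ridge logistic regression (`glmnet`, fixed penalty
0.01, recorded in the run configuration) on summed pair embeddings, with
label-stratified seeded folds. AUROC is computed by the Mann–Whitney rank
statistic with average ranks for ties, and is tested for exact agreement
with brute-force concordant-pair counting.

Enrichment ranks every in-vocabulary reaction by cosine between its vector
and the additive pair embedding, keeps the top 20, and calls the pair
valid for a class if any kept reaction maps to the class's System Organ
Class. Exact cosine ties (measure zero, but reproducibility matters) break
by token order. Reactions missing from the SOC map are silently
non-matching, because user-supplied maps are routinely partial. Pooled
accuracy is the ratio of summed counts, not the mean of per-class
accuracies — the two differ whenever class sizes do.

## The synthetic generator

`synth_bundle()` emulates the statistical structure the pipeline assumes:
a handful of adverse-event classes, each with a drug pool and a reaction
pool that co-occur within reports, against a background of unrelated
tokens. Each report carries exactly two drugs (matching the two-drug
filter applied to regulatory corpora before pair analysis; a class report
draws each drug slot from its class pool with probability `signal`) and
2–4 reactions, each independently replaced by a background reaction with
probability `noise_rate`. Defaults — 5 classes, 40 drugs per class, 15
reactions per class, 60 background reactions, 2000 reports, signal 0.8,
noise 0.1 — were chosen once as a desk-scale caricature of a filtered
reporting corpus: enough reports that class drugs comfortably clear the
support threshold, pools small enough that the full pipeline runs in
seconds. Class keywords are synthetic (`class3tox`), to avoid baking
clinical vocabulary into test fixtures. Every side resource (drug lists,
toxicity texts, DDI descriptions, SOC map) is derived from the same ground
truth, and the bundle writes byte-identically from a seed.

What the generator does **not** emulate: reporting biases, duplicated
cases, demographic structure, polypharmacy beyond two drugs, reactions
shared between classes, and realistically heavy-tailed token frequencies.
Passing the planted-recovery tests therefore shows that the implementation
recovers structure that is genuinely present at the stated signal level;
it does not certify performance on real reporting data.

## Numerical choices and degenerate inputs

Huffman ties (equal counts) prefer the lower creation index, leaves before
internal nodes, so the tree is unique; code optimality is tested against
exhaustive search over all leaf-depth profiles for up to 8 tokens.
Vocabulary order is order of first appearance, which makes consistent
token relabelling a pure permutation of the result. Reports with an empty
side contribute no pairs and are legal; a corpus yielding zero pairs is an
error naming `min_count` as the likely cause; a vocabulary of fewer than
two tokens cannot support hierarchical softmax and is rejected. Embedding
files round-trip at 6 decimals (so re-read vectors differ by at most
5e-7 per coordinate); all pipeline artifacts print numbers at fixed
6-decimal width so identical runs are byte-identical.

## Known limitations

The enrichment step inherits a structural weakness of input-input cosine
under the strict bipartite context rule. A drug's input vector is trained
to *predict* reactions, and a reaction's input vector to predict drugs;
the two sides never share context tokens, so nothing in the objective
directly pulls a drug vector toward the vectors of its own reactions. At
high co-occurrence density (one drug–reaction pair repeated hundreds of
times) the relative ranking still recovers the association, and the test
suite demonstrates this on a planted exclusive pair. But when a class's
association mass is spread over a 40-drug by 15-reaction block, the
*aggregate* geometry between the drug cluster and the reaction cluster —
which can land with either sign — dominates the per-pair first-order
signal, and whole classes pass or fail the top-20 rule together. The
acceptance script reports this honestly: at the bundled study conditions
the cross-validated AUROC of the summed-embedding classifier is essentially
perfect while the pooled enrichment accuracy sits far below it, and the
per-class validity pattern is all-or-nothing. Conclusions about the
enrichment procedure on real data should rest on corpora whose per-pair
co-occurrence counts are orders of magnitude larger, where the first-order
effect has room to dominate.

Other limitations: no negative sampling or frequent-word subsampling (the
bipartite rule replaces windowing entirely, and hierarchical softmax is
the fixed gradient scheme); no handling of tokens appearing as both drug
and reaction (rejected as ambiguous rather than disambiguated); the
logistic-regression penalty is fixed rather than tuned, because the
evaluation compares feature sources, not classifier configurations.
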