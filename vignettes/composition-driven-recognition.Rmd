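---
title: "Composition-driven symptom phrase recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-driven symptom phrase recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsym)
```

## The problem

Patients describing symptoms in online consultations rarely use the
standardized phrases of the medical literature. Annotated training corpora
for symptom mention extraction are scarce, but curated *symptom
dictionaries* — lists of standard phrases such as "persistent low back
pain" — are comparatively easy to obtain. `compsym` implements a
recognizer that learns *how symptom phrases are composed* from such a
dictionary alone and uses that knowledge to extract phrases never seen
verbatim, from free text, with no annotated sentences at all.

The unit of composition is the **component**: a tokenizer-produced word,
or a single character in character mode. The tokenizer is a plugged-in
function; nothing in the method depends on the language or segmenter.

## The models

### Automatic BIES annotation and the position model

Every dictionary phrase is annotated mechanically: one component is `S`
(Single); otherwise first is `B` (Begin), last is `E` (End), interior
components are `I` (Intermediate). Counting each component's occurrences
over positions gives a multinomial \((n, \pi_B, \pi_I, \pi_E, \pi_S)\)
per component, estimated by maximum likelihood \(\pi_X = n_X / n\):

```{r position}
phrases <- list(
  symptom_phrase("persistent lowback pain",
                 c("persistent", "lowback", "pain")),
  symptom_phrase("persistent fever", c("persistent", "fever")),
  symptom_phrase("fever", "fever"))
stats <- position_stats(annotate_dictionary(phrases))
position_probabilities(stats)
```

Counts are stored as exact integers and probabilities are derived on
demand. There is **no smoothing**: a position never observed has
probability exactly 0 and is not a permissible label for that component
during recognition. This follows from the role the model plays — it
defines which position *arrangements* are admissible — and it makes the
worked estimates exact. The cost is that a component's positional
repertoire is bounded by what the dictionary shows; we accept that, since
the dictionary is the only supervision available.

### Neighbourhood distributions and the interaction score

Position statistics say nothing about whether two components *belong
together*. For that, skip-gram embeddings (with negative sampling,
trained on the dictionary's component sequences, optionally supplemented
by unlabeled corpus sentences) place components in a vector space; then,
rather than thresholding a raw distance — which in high dimension
conflates unrelated regions of the semantic space — each component is
represented by the *distribution of its neighbourhood*: k-means
partitions all vectors into \(C\) clusters, and the component's k nearest
neighbours (cosine, self excluded) vote a cluster-occupancy histogram
\(P_\alpha\). Two components interact strongly when their neighbourhoods
look alike, measured by the Jensen–Shannon divergence and mapped to
\([0,1]\):

\[
I(w_\alpha, w_\beta) = \exp(-\nu \, JSD(P_\alpha \| P_\beta) + \gamma).
\]

The logarithm is natural throughout; the base is absorbable into \(\nu\),
but a fixed convention is needed for reproducibility. JSD is always
finite (the mixture dominates both arguments), so the infinite KL case
can never leak into a score.

### Recognition

A sentence is preprocessed (sentence split, tokenized, non-informative
tokens masked: extremely common, rare, or unknown to both models), and
every kept token receives its permissible labels — each BIES label with
\(\pi > 0\), plus `O` (outside). A token unknown to the position model
but present in the embedding vocabulary may still serve as a *filler
intermediate* (`{I, O}`): colloquial sentences interleave such words with
symptom components. Valid labelings follow the grammar

\[(O \mid S \mid B^{+}(I|O)^{*}E^{+})^{*},\]

runs of `B`/`E` collapsing to the leftmost `B` and rightmost `E`. Each
labeling is scored by the boundary function
\(\sum_i \boldsymbol{\pi}^{l_i}\), where a single-`S` subsequence scores
\(\pi_S\) and a span scores \(\pi_B(\text{first}) \cdot
\pi_E(\text{last})\). The argmax labeling wins; ties prefer larger token
coverage, then leftmost subsequence starts, then the lexicographically
smallest label string (the coverage preference matches the
leftmost-B/rightmost-E spirit; the final key only serves determinism).
Finally, each interior `I` component of a span is kept only if its
utility — the mean interaction with the two boundary components —
reaches the threshold \(\delta\); interior `O` tokens are skipped
(disjoint colloquial material), and `B–E` spans keep both components
unconditionally.

Two ablations share this scaffolding: *no-interaction* keeps every
interior component (equivalently \(\delta = 0\); the package treats an
out-of-vocabulary intermediate as utility 0, so this equivalence holds on
every input), and *no-position* drops the boundary model entirely,
emitting connected groups (size \(\ge 2\)) of pairwise-interacting
components. The grouping rule of the no-position variant is an
interpretation — the underlying idea is stated only loosely in the
literature — and is flagged as such.

### Evaluation

Extractions are matched to gold phrases greedily in descending
character-multiset IoU, one-to-one, counting a pair correct when IoU
\(\ge \varepsilon\) (the `>=` reading keeps \(\varepsilon = 1\)
meaningful as exact-match evaluation). Micro metrics pool TP/FP/FN over
records; macro metrics average per-record precision and recall and
combine them harmonically. IoU on character multisets is itself a design
choice: it behaves sensibly for partially overlapping phrases and needs
no alignment, but it can over-credit anagram-like near-misses; the
synthetic token inventory uses short random letter strings to keep
accidental character overlap low.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dim` | 500 full scale; 32–48 in tests | embedding dimension |
| `window` | 5 | skip-gram context window |
| `clusters` (C) | `min(500, ceil(V/4))` | k-means clusters |
| `knn` (k) | `min(2000, ceil(V/2))` | neighbourhood size |
| `nu` | 7.5 | JSD scaling |
| `gamma` | 0 | score offset (clipped at 1 if positive) |
| `delta` | 0.2 | utility / interaction threshold |
| `epsilon` | 0.6–1.0 | IoU threshold at evaluation |
| `common_top` / `rare_min` | 0.001 / 2 | frequency filters |

The full-scale operating point (\(d = 500\), \(C = 500\), \(k = 2000\),
\(\nu = 7.5\), \(\gamma = 0\), \(\delta = 0.2\)) presumes a dictionary of
several hundred thousand phrases. At desk scale both \(C\) and \(k\) must
shrink with the vocabulary \(V\); crucially \(k\) must stay well below
\(V\), since as \(k \to V\) every neighbourhood histogram converges to
the global cluster distribution and all interaction scores collapse
towards 1, erasing the signal. We use \(k = \min(2000, \lceil V/2
\rceil)\): at two-topic desk scale this keeps a component's neighbourhood
roughly within its own semantic region, and at full scale it reproduces
\(k = 2000\).

## The synthetic benchmark

Real consultation corpora (and the curated dictionaries behind them) are
not redistributable, so the package ships a generator that emulates the
statistical structure the method relies on, with known ground truth:

* components are opaque ASCII symbols in `n_topics` disjoint topics, each
  with a positional **role** (begin / end / interior / single) and a
  known BIES multinomial; the `mixing` parameter scales the off-role
  intermediate mass (default 0.25, e.g. \(\pi_B \in [0.65, 0.9]\) for
  begin components — boundary words also occur mid-phrase);
* dictionary phrases are assembled from per-component multinomial
  position draws (B/E tokens paired, I tokens distributed), so empirical
  position frequencies are unbiased estimates of the generating
  multinomials — this is what makes parameter-recovery testing exact in
  expectation; phrase lengths are emergent from the role mix;
* corpus sentences embed phrases re-composed in position-legal order
  (mostly unseen as wholes), interrupted by out-of-vocabulary *filler*
  tokens (rate 0.3 per interior gap) and by cross-topic *distractor*
  components (rate 0.15 per span) that are position-legal interiors but
  semantically incompatible; background noise pads the spans. Gold
  records the intended symptom components only.

Embeddings for the benchmark are trained on the dictionary plus the
unlabeled corpus (so fillers acquire their own embedding context and are
rejected by interaction scoring rather than by accident of vocabulary).

What passing benchmark tests shows — and what it does not: the generator
reproduces compositional recombination, colloquial interruption and
position ambiguity, but not real tokenizer errors, unsegmentable idioms,
polysemous characters, or the heavy-tailed frequency profile of real
consultation text. Absolute scores on the benchmark say nothing about
absolute performance on clinical corpora; the *contrasts* (full vs.
ablations, clean vs. noisy) are the meaningful quantities.

### Why the exactness check uses pure roles

With mixed roles (`mixing > 0`) an interior component that is also
begin-capable can legitimately out-score the true span start under the
boundary function, and a single-capable interior invites splitting a span
into singletons (the additive score rewards more subsequences). These are
genuine, documented failure modes of the method on clean text, not
implementation defects — empirically they cap noise-free micro-F1 around
80 on this benchmark. The end-to-end *exactness* check therefore runs at
`mixing = 0` (every component positionally unambiguous), where a correct
implementation must recover every phrase: micro-F1 = 100 at
\(\varepsilon = 1\). The ablation and recovery analyses keep the
realistic mixed default.

## Numerical and degenerate-input choices

* Exhaustive enumeration of valid labelings is used up to 25 tokens;
  longer sentences fall back to a beam (default width 64) whose partial
  score adds closed-subsequence scores plus the pending span's
  \(\pi_B\) as an optimistic bound; survivors are rescored exactly. A
  beam at least as wide as the number of valid labelings is provably
  identical to exhaustive enumeration (and is tested to be).
* Duplicate labelings that normalize to the same labeling are merged
  before scoring; per-subsequence scores are summed in start order so
  that floating-point ties are stable.
* An emitted subsequence must exceed a configurable score floor
  (default 0 — a no-op, since candidate labels already require positive
  probabilities; raising it guards against degenerate many-`S`
  segmentations if a deployment needs that).
* Zero denominators in precision/recall are defined as 0 with a
  consolidated warning. Empty-vs-empty string IoU is 1.
* Spans are reported as 0-based, half-open token indices throughout the
  extraction tables.
* Desk-scale problem sizes used by the test-suite study: dictionaries of
  ~400 phrases over ~230 components (10,000 for parameter recovery, over
  40 components so that per-component counts concentrate), corpora of
  200 sentences, embeddings of dimension 32–48 with 10 epochs when the
  corpus supplement is present and 25 without it (the dictionary alone
  provides far fewer co-occurrence pairs per epoch), 12–20 paired seeds
  for the ablation contrast.

## Known limitations

* The additive boundary score can prefer splitting genuinely long
  phrases when interior components are themselves boundary- or
  single-capable; see above.
* Components absent from the dictionary and the embedding vocabulary are
  invisible — sentences whose symptom words are all out-of-vocabulary
  yield nothing, and a phrase whose only begin-capable word is missing
  cannot be anchored.
* One-to-one greedy IoU matching is a convention; other matchers
  (optimal assignment) could shift absolute scores slightly.
* The no-position grouping rule is an interpretation (see above), so its
  ablation score should be read qualitatively.
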