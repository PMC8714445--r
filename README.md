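# compsym

Composition-driven symptom phrase recognition for free-text medical
consultation records — **without any annotated corpus**.

Clinical question-answering pipelines need to find symptom mentions in
what patients actually write, but spoken-language expressions rarely match
a curated vocabulary verbatim, and labeled clinical text is scarce.
`compsym` targets the setting where the *only* supervision is a **symptom
dictionary** (one standard phrase per line, e.g. "persistent low back
pain"). It learns how phrases are *composed* from that dictionary and uses
the learned composition to extract symptom phrases never seen as a whole.
It is aimed at clinical NLP practitioners and methods researchers studying
dictionary-only (distantly supervised) entity recognition.

## The method

Each dictionary phrase is split into components (words, or characters in
character mode) and annotated automatically with BIES position labels
(`S` for a one-component phrase, otherwise `B` first / `I` interior / `E`
last). Two models are estimated:

1. **Position model.** Per component `w`, the BIES occurrence counts form
   a multinomial `(n, π_B, π_I, π_E, π_S)` with MLE `π_X = n_X / n`. A
   component seen 60 times at the beginning and 12 times in the middle of
   phrases has `π = (0.83, 0.17, 0, 0)` over `n = 72` trials. Unseen
   positions have probability exactly 0 (no smoothing) and are
   inadmissible at recognition time.
2. **Interaction model.** Skip-gram embeddings (negative sampling) are
   trained on the dictionary's component sequences; k-means partitions the
   vectors into `C` clusters and each component is represented by the
   cluster-occupancy distribution `P_α` of its `k` nearest neighbours.
   Semantic compatibility is scored as

       I(w_α, w_β) = exp(−ν · JSD(P_α ‖ P_β) + γ) ∈ [0, 1]

   with Jensen–Shannon divergence under the natural log (defaults
   `ν = 7.5`, `γ = 0`).

To recognize phrases in a sentence, every kept token receives its
admissible labels (`π_X > 0`, plus `O`; embedding-only tokens may act as
filler intermediates). Over all valid labelings — non-overlapping
subsequences, each a single `S` or a `B…E` span — the boundary score

    𝛑(l_1, …, l_q) = Σ_i 𝛑^{l_i},   𝛑^{l_i} = π_S  or  π_B(first)·π_E(last)

is maximized; consecutive `B`/`E` runs collapse to the leftmost/rightmost.
Within the winning spans, an interior component `w_i` survives only if its
utility `θ(w_i) = (I(w_1, w_i) + I(w_i, w_k)) / 2` reaches the threshold
`δ` (default 0.2); surviving components are concatenated into the
extracted phrase. Evaluation matches extractions to gold phrases by
character-multiset IoU at a threshold `ε`, reporting micro/macro
precision, recall and F1 (percent). Ablations (`no-interaction`,
`no-position`), a dictionary-lookup baseline and bidirectional maximal
matching (BDMM) are included, plus a synthetic benchmark generator with
known positional multinomials and topic structure.

## Worked example

The synthetic benchmark exercises the whole pipeline with known ground
truth (opaque ASCII tokens stand in for segmented words):

```r
library(compsym)
cfg    <- generator_config(seed = 42)
dict   <- generate_dictionary(cfg)              # 376 phrases, 2 topics
corpus <- generate_corpus(dict)                 # 200 noisy sentences + gold

stats <- position_stats(annotate_dictionary(dict$phrases))
stats
#> <position_stats> 199 components, 1172 position observations
#>      B I E S
#> ytin 7 2 0 0
#> smjw 1 5 0 0
#> xnux 0 5 0 0
#> ...

space <- train_embeddings(dict$phrases, dim = 48, epochs = 10,
                          corpus = strsplit(unname(corpus$texts), " "),
                          seed = 42)
model <- fit_interaction(space, interaction_params(seed = 42))
model
#> <interaction_model> 270 components, 68 clusters, k = 135, nu = 7.5, gamma = 0

sents <- preprocess(corpus$texts,
                    filters = filter_config(
                      vocab = union(rownames(stats), space$vocabulary),
                      rare_min = 0))
ext <- extract_corpus(sents, stats, model,
                      extract_config(mode = "full", delta = 0.2))
head(ext, 4)
#>   record_id               phrase start end components
#> 1     r0002 jrmuFXSRbcbnFACNiqmq     3   8  3,4,5,6,7
#> 2     r0002     zljnsaqdakftzauf     8  12  8,9,10,11
#> 3     r0003             enjokkme     1   3        1,2
#> 4     r0003         xugcjlczzauf     3   7      3,4,6

evaluate_extractions(ext, corpus$gold, epsilon = 0.6)
#> <eval_report> epsilon = 0.60, 185 records (TP 207 / FP 35 / FN 37)
#>   micro  P  85.54  R  84.84  F1  85.19
#>   macro  P  85.59  R  85.68  F1  85.63
```

Reading the output: spans are 0-based half-open token indices and
`components` lists the tokens that were concatenated — in record `r0003`
the span covered tokens 3–6 but the interaction filter discarded the
incompatible interior at position 5, recovering the intended phrase. The
report says 207 of 244 gold phrases were matched at IoU ≥ 0.6 with 35
spurious extractions; micro pools counts over records while macro averages
per-record rates.

A thin CLI wraps the same functions
(`inst/cli/compsym <annotate|train-pos|train-int|extract|eval|simulate>`).

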