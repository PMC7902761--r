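# cidre — chemical-induced disease relation extraction

`cidre` extracts **chemical-induced disease (CID)** relations from
annotated biomedical abstracts at the *document* level: given a PubTator
file with gold chemical/disease mentions normalized to MeSH concept
identifiers, it scores every chemical × disease concept pair, including
the roughly 30% of true relations that are never expressed inside a
single sentence.  It is aimed at biomedical text-mining practitioners who
need a trainable, inspectable document-level relation extractor and a
fully synthetic benchmark to validate it without corpus downloads.

## The model

For a document with `N` mentions, `R` entity concepts and `T` sentences:

1. Each sentence is encoded by a **bidirectional LSTM**; forward and
   backward states are averaged, giving contextual token vectors of
   dimension `d_h`.
2. **Mention** nodes average the token vectors in the mention span,
   **entity** nodes average their mentions, **sentence** nodes average all
   tokens; each node appends its learned type embedding (`d_t`), so all
   `N + R + T` nodes share dimension `d = d_h + d_t`.
3. A **heterogeneous document graph** connects: mentions co-occurring in
   a sentence; every pair of sentences; mentions to their sentence;
   mentions to their entity; entities to every sentence containing one of
   their mentions; plus self-loops.
4. Stacked **graph convolutions** `V⁽ˡ⁺¹⁾ = LeakyReLU(A V⁽ˡ⁾ W⁽ˡ⁾)`
   aggregate evidence over the graph.  Between layers, a **gating
   mechanism**

       g = σ(V_raw W_g + V⁽ˡ⁾ U_g + b_g),   V⁽ˡ⁺¹⁾ = V_raw ⊙ g + V⁽ˡ⁾ ⊙ (1 − g)

   interpolates coordinatewise between the convolution output and the
   previous representation, counteracting the over-smoothing that
   otherwise makes deep stacks collapse node representations (residual
   and dense-concatenation connections are also available).
5. For each pair, a **bilinear softmax**
   `P(r | e_chem, e_dis) = softmax(e_chemᵀ W_cls e_dis)` with
   `W_cls ∈ ℝ^{d×2×d}` scores the relation; training minimizes the summed
   negative log-likelihood of the gold labels over all candidate pairs
   with SGD (momentum, gradient clipping), all gradients derived
   analytically and verified against finite differences.

The package also ships a **synthetic corpus generator** that emits valid
PubTator files with planted, cue-determined relations reproducing the
structural statistics of the CDR benchmark (multi-mention entities,
~30% inter-sentence positives), an intra-/inter-sentence **evaluation
harness**, **ablation utilities** (fully connected graph, no gating, no
aggregation; depth × connection-mechanism sweeps), an **over-smoothing
diagnostic**, and a small **CLI** (`inst/cli/cidre`).

## Worked example

```r
library(cidre)

corpus <- generate_corpus(synth_config(n_docs = 120, seed = 7))
train  <- new_corpus(corpus$documents[1:100], "train")
test   <- new_corpus(corpus$documents[101:120], "test")
corpus_stats(train)[c("documents", "positives", "inter_positives")]
#> $documents      [1] 100
#> $positives      [1] 145
#> $inter_positives[1] 45

vocab <- sort(unique(unlist(lapply(train$documents,
                                   function(d) tolower(unlist(d$sentences))))))
model <- cid_model(vocab, d_w = 24, d_h = 24, d_t = 8, n_layers = 4,
                   mode = "gated", adjacency = "sym", seed = 1)
model <- train_model(model, train,
                     config = train_config(lr = 0.1, epochs = 30, seed = 1))

pred <- predict_relations(model, test)
head(pred, 3)
#>    doc_id chemical_id disease_id score label
#> 1 9000104     D100012    D200035     1     1
#> 2 9000108     D100022    D200036     1     1
#> 3 9000116     D100006    D200013     1     1

evaluate_predictions(test, pred)
#> overall  P 0.7381  R 0.9688  F1 0.8378  (tp 31 fp 11 fn 1)
#> intra    P 0.8846  R 0.9583  F1 0.9200  (tp 23 fp 3 fn 1)
#> inter    P 0.5000  R 1.0000  F1 0.6667  (tp 8 fp 8 fn 0)
```

Each row of `pred` is one chemical–disease concept pair with
`score = p(r = 1)`; `evaluate_predictions()` reports micro-averaged
precision/recall/F1 overall and split into intra-sentence pairs (some
sentence contains mentions of both concepts) and inter-sentence pairs
(cross-sentence inference required — the hard part, visibly lower here at
this small training size; the acceptance run below trains on 200
documents at `d_h = 32`).

Real corpora in PubTator format load with
`read_pubtator("CDR_TrainingSet.PubTator.txt")`; pretrained word vectors
(word2vec text dialect) load with `load_word_embeddings()` and are passed
to `cid_model()` in place of the vocabulary.

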