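# msgddi

Joint drug/reaction concept embeddings from spontaneous adverse-event
reports, for drug–drug interaction (DDI) signal work in pharmacovigilance.

Spontaneous reporting systems collect millions of reports, each listing the
drugs a patient took and the adverse reactions observed. `msgddi` learns a
low-dimensional vector for every drug and reaction concept with a **modified
skip-gram** model: instead of a positional text window, the context of a
drug within a report is *every reaction in that report*, and the context of
a reaction is *every drug* — a bipartite context rule matched to the
structure of a report, which is two unordered token sets rather than a
sentence. The package is aimed at methodologists who want to experiment
with embedding-based DDI screening pipelines end to end without access to
regulatory data: a synthetic report generator with planted adverse-event
classes stands in for the real corpora.

## The model

For a report corpus *D*, training maximises

> &Sigma;<sub>(w,c)&isin;D</sub> &Sigma;<sub>w<sub>j</sub>&isin;c</sub> log P(w | w<sub>j</sub>)

where *c* is the report's cross-side token set for w<sub>j</sub>. The
conditional is factorised by **hierarchical softmax** over a Huffman tree
built from token document frequencies: P(w | w<sub>j</sub>) is a product of
per-node sigmoids &sigma;(&plusmn;&langle;v<sub>n</sub>,
e(w<sub>j</sub>)&rangle;) along w's root-to-leaf path, trained by
sequential SGD with a linearly decaying learning rate (defaults: dimension
100, starting alpha 0.025, minimum document frequency 10).

Around the model the package provides, behind one tabular interface:

* **CM-TF-IDF baseline** — a term-by-report co-occurrence matrix weighted
  by tf-idf = (n<sub>ij</sub>/&Sigma;<sub>k</sub>n<sub>kj</sub>) ·
  ln(|D|/df<sub>i</sub>), reduced to fixed-length term vectors by PCA.
* **Pair classification** — drug-pair features are the elementwise sum of
  the two drug vectors; pairs are labelled positive for an adverse-event
  class by three reference strategies (class drug lists, keyword hits in
  toxicity texts, keyword hits in DDI descriptions); AUROC is estimated by
  stratified 10-fold cross-validated ridge logistic regression.
* **Description enrichment** — candidate reactions are ranked by cosine
  between their vector and the additive pair embedding; an enrichment is
  *valid* if any top-20 reaction maps to the class's System Organ Class
  (SOC), and per-class accuracy tables pool counts across classes.

## Worked example

```r
library(msgddi)

b <- synth_bundle(n_reports = 1000, signal = 0.9, seed = 42)  # planted classes
m <- msg_train(b$corpus, dim = 50, epochs = 5, min_count = 10, seed = 42)
m
#> Modified skip-gram model
#>   tokens: 205 (81 drugs, 124 reactions)
#>   dim: 50  epochs: 5  training pairs/epoch: 5766
#>   mean log-likelihood (final epoch): -5.2834

pairs <- observed_pairs(b$corpus, reference_drugs = m$vocab$token)
lab   <- label_pairs(pairs, b$resources, b$event_classes[1, ])
cv    <- crossval_auroc(pair_features(m, lab), lab, n_folds = 10, seed = 42)
glance(cv)
#> # A tibble: 1 × 4
#>   mean_auroc n_folds sd_auroc  seed
#>        <dbl>   <int>    <dbl> <int>
#> 1      0.979      10   0.0339    42

rank_reactions(m, lab$drug_a[1], lab$drug_b[1],
               m$vocab$token[m$vocab$kind == "reaction"], k = 5)
#> # A tibble: 5 × 3
#>    rank reaction cosine
#>   <int> <chr>     <dbl>
#> 1     1 35000098  0.499
#> 2     2 35000109  0.464
#> 3     3 35000122  0.463
#> 4     4 35000095  0.380
#> 5     5 35000112  0.367
```

The mean AUROC of 0.979 says the summed embeddings of a drug pair separate
pairs associated with the planted class from the rest almost perfectly at
this signal strength; the ranking shows the five reactions whose vectors
lie closest in cosine to that pair's embedding, the raw material of the
enrichment step. `run_pipeline(pipeline_config(...))` chains all stages —
generation, training, baseline, labelling, cross-validation, enrichment —
and writes embeddings, per-fold AUROCs, ROC points, enrichment rows and the
accuracy table to an output directory; `inst/scripts/run_pipeline.R` is a
command-line wrapper over it.

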