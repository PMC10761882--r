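# metapara

Meta-weighted, domain-adaptive paraphrase augmentation for low-resource
text classification.

## The problem

Training a text classifier on a few hundred labeled documents — the
motivating case is recognising long-COVID-related articles from titles and
abstracts — usually calls for data augmentation. Paraphrase augmentation
rewrites each training text with a sequence-to-sequence model and lets the
rewrite inherit the label. But paraphrasers are trained on *generic*
sentence-pair corpora: pairs far from the target domain teach the
paraphraser rewrites that can hurt the downstream classifier.

`metapara` implements a data-reweighting multi-level optimization (MLO)
framework that closes the loop. A **meta-weight network** (MWN) `W` — a
1→25→25→1 MLP with a terminal sigmoid — maps each paraphrase pair's
teacher-forcing loss `l_i` to a data weight `a_i ∈ (0,1)`:

```
outer    min_W   L(C*(S*(W)), D_MLO-val)
middle   C*(·) = argmin_C  L(C, D_MLO-tr) + γ · L(C, G(D_MLO-tr, S*(W)))
inner    S*(W) = argmin_S  Σ_i  W(l(S, t_i, s_i)) · l(S, t_i, s_i)
```

`S` is the paraphraser, `C` the classifier, `G(·, S)` the label-preserving
paraphrases of the MLO-train texts, and `γ` (default 0.85) the trade-off on
the generated-data loss. Each inner problem is approximated by a one-step
gradient unroll, and `W` descends the hypergradient of the MLO-validation
loss, computed with nested symmetric finite differences whose steps are
adaptively scaled (`0.01 / ‖·‖₂`). Weights are *learned*, not set: pairs
whose gradient helps the downstream domain get upweighted.

The package ships:

* tiny reference models with fully hand-derived gradients (seq2seq
  paraphraser with monotonic source feed; embedding → bi-LSTM(64) →
  bi-LSTM(32) → ReLU dense(20) → softmax classifier; the MWN),
* the three-stage alternating engine (`train_mlo()`), the Para-Sep and
  Only-Aug ablations, and final fine-tuning,
* an **exact hypergradient oracle** (analytic chain rule + complex-step
  directional derivatives) and a brute-force numerical route, so the
  finite-difference scheme is verifiable three ways,
* a synthetic two-domain corpus generator making every claim testable
  offline in minutes,
* the evaluation protocol (positive-class or macro metrics, midrank /
  one-vs-one AUC), seed and γ sweeps, and a CLI.

## Worked example

Build the synthetic two-domain task (60 paraphrase pairs, half from the
task's token domain; 120/40/80 train/val/test; two classes decided by
signal tokens), run the full MLO loop plus fine-tuning with the desk-scale
profile, and inspect what the meta-weight network learned:

```r
library(metapara)

task   <- make_synthetic_task(synthetic_spec(seed = 1))
cfg    <- mlo_config_synthetic(seed = 1)
halves <- split_mlo(task$train, seed = 1)       # deterministic 80/20
fit    <- train_mlo(cfg, task$paraphrase, halves$mlo_train,
                    halves$mlo_val, task$train, vocab = task$vocab)

weights <- mwn_pair_weights(fit$mwn, fit$paraphraser, task$paraphrase,
                            standardize = TRUE)
aggregate(weight ~ domain_tag, weights, mean)
#>   domain_tag    weight
#> 1  in_domain 0.5011886
#> 2 off_domain 0.5017594

evaluate_classifier(fit$classifier, task$test)
#> <metapara_metrics> n=80 (binary averaging, binary AUC)
#>   accuracy 97.50  precision 95.24  recall 100.00  F1 97.56  AUC 99.69 (%)

generate(fit$paraphraser, task$train$text[1])
#> [1] "a03 a22 a22 a22 a17 a27 a03 a22"

bayes_reference_accuracy(task, task$test)   # noise-limited ceiling
#> [1] 0.9875
```

The classifier reaches 97.5% accuracy against a 98.75% noise ceiling. The
per-seed weight gap between in-domain and off-domain pairs is small (the
two domains are symmetric by construction, so their loss distributions
overlap); across five seeds it is positive in four — the directional
signature of domain-adaptive reweighting — and the full feedback loop
matches or beats the no-feedback Para-Sep ablation on mean accuracy, while
the Only-Aug ablation (classifier trained on generations only) is far less
stable across seeds. The methods vignette
(`vignettes/metapara-methods.Rmd`) explains the algorithm, the
differentiable decoding coupling, and every tunable.

Command-line interface over the same functions:

```sh
inst/cli/metapara synth --out-dir data --seed 1
inst/cli/metapara train --pairs data/pairs.tsv --train data/train.csv --out-dir run --seed 1
inst/cli/metapara evaluate --model run/classifier.json --corpus data/test.csv
```

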