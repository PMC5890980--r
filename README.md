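# topicgru

Per-visit 30-day hospital readmission prediction from longitudinal EHR code
sequences, with a hybrid model that captures both time scales of readmission
risk:

* **local context** — a gated recurrent unit (GRU) over the visit sequence,
  whose input at step *t* is the embedded previous visit
  (x_t = W_v' V_{t−1});
* **global context** — a per-patient latent vector θ ~ N(0, I_N), inferred
  by a variational recognition network from the patient's bag-of-events
  counts, entering each visit's score through a topic bias.

The per-visit risk is

    P(y_t = 1) = sigmoid( Q' h_t + q_0 + B_t' θ ),

where h_t is the GRU state, B_t the mean of the learned topic vectors of
the codes in visit t, and θ is trained by maximizing the single-sample
reparameterized evidence lower bound (Bernoulli log-likelihood of the
supervised visit labels minus the closed-form KL to the prior) with Adam,
batch size 1, all gradients derived analytically (backpropagation through
time; verified against finite differences in the test suite). Dropping the
B_t'θ term gives the GRU-only ablation used as a baseline.

The package is aimed at researchers studying readmission models or
sequence models of coded clinical events: it includes corpus I/O for
visit-sequence data, 30-day label construction from admission timestamps,
patient-level splitting, repeated-run evaluation (ROC-AUC, PR-AUC,
accuracy), patient embedding with k-means phenotype clustering, and two
synthetic-EHR generators (a subsample-and-combine procedure for
de-identifying a source corpus, and a de novo simulator with known
ground-truth risk for recovery testing).

## Worked example

Simulate a cohort with known risk structure, fit both variants, and
compare them against the Bayes bound given by the true generating
probabilities:

```r
library(topicgru)

sim <- simulate_ehr(n_patients = 600, vocab_size = 100, n_topics = 8,
                    mean_visits = 20, mean_codes_per_visit = 2.86,
                    global_weight = 2, local_weight = 1, seed = 1)
corpus <- split_corpus(sim$corpus, c(400, 100, 100), seed = 1)

fit <- topicgru(corpus, variant = "content",
                embed_dim = 32, hidden_dim = 32, n_topics = 8,
                rec_dims = c(32, 32), learning_rate = 5e-4,
                max_epochs = 40, patience = 12, seed = 1)
fit
#> Topic-biased GRU readmission model (variant: content )
#>   vocabulary: 100 codes; H=32, D_h=32, N=8
#>   trained 17 epochs, best validation roc_auc 0.6736 at epoch 5

test <- corpus_subset(corpus, "test")
scores <- unlist(predict(fit, test))
labels <- unlist(lapply(test$records, function(r)
  vapply(r$visits, `[[`, integer(1), "label")))
roc_auc(scores, labels)
#> [1] 0.7247187
roc_auc(sim$truth$df$p_star, sim$truth$df$label)  # Bayes upper bound
#> [1] 0.8762687
```

The fitted model reaches ROC-AUC ≈ 0.72 against a Bayes bound of ≈ 0.88 on
this configuration; the residual gap is the part of the local risk state
that is unobservable from the code sequence plus label noise. Patient
phenotyping from the same fit:

```r
emb <- embed_patients(corpus, fit)      # theta ++ final hidden state
cl  <- cluster_patients(emb, k = 20, seed = 1)
summarize_clusters(corpus, cl, exclude_top = 3)
```

Real corpora are read with `read_ehr_corpus()` (JSON-Lines or a flat
tab-separated dialect), labeled with `build_labels()` (readmission window
`(discharge, discharge + 30 d]`), and evaluated with
`evaluate_repeated()`, which refits over seeds and reports each metric as
mean ± sd. A command-line wrapper (`inst/cli/topicgru.R`) exposes
`simulate`, `stats`, `train`, `predict`, `evaluate`, `embed`, `cluster`,
each writing a JSON run manifest alongside its outputs.

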