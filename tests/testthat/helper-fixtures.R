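# Shared fixtures, all built in code.

# One patient, visits {A}, {A,B}; labels 1, 0.
tiny_corpus <- function() {
  ehr_corpus(c("A", "B"), list(
    ehr_record("p1", list(ehr_visit(1L, label = 1L),
                          ehr_visit(c(1L, 2L), label = 0L)))
  ))
}

# Three patients, 7 visits, 15 events, hand-countable.
three_patient_corpus <- function() {
  ehr_corpus(c("A", "B", "C", "D"), list(
    ehr_record("p1", list(ehr_visit(c(1L, 2L), label = 1L),
                          ehr_visit(c(1L, 3L), label = 0L),
                          ehr_visit(2L, label = 0L))),
    ehr_record("p2", list(ehr_visit(c(1L, 2L, 3L, 4L), label = 1L),
                          ehr_visit(c(2L, 4L), label = 1L))),
    ehr_record("p3", list(ehr_visit(3L, label = 0L),
                          ehr_visit(c(1L, 2L, 4L), label = 0L)))
  ))
}

# Random corpus over C codes with labels everywhere.
random_corpus <- function(n = 20, C = 12, max_visits = 6, seed = 1) {
  set.seed(seed)
  records <- lapply(seq_len(n), function(i) {
    T_p <- sample(max_visits, 1)
    t0 <- 0L
    visits <- lapply(seq_len(T_p), function(t) {
      t0 <<- t0 + sample(1:20, 1)
      ehr_visit(sample(C, sample(3, 1)), time = t0,
                label = sample(0:1, 1))
    })
    ehr_record(sprintf("r%03d", i), visits)
  })
  ehr_corpus(sprintf("code%02d", seq_len(C)), records)
}

# Small random parameter set for network tests.
small_params <- function(C = 6, H = 3, D = 4, N = 2, rec = c(5, 5), seed = 2) {
  init_params(C, embed_dim = H, hidden_dim = D, n_topics = N,
              rec_dims = rec, seed = seed)
}

zero_params <- function(...) {
  par <- small_params(...)
  at <- attributes(par)
  par <- lapply(par, function(x) { x[] <- 0; x })
  attributes(par) <- at
  par
}

# Independent scalar GRU step: plain loops over the four printed equations,
# no matrix code shared with the implementation.
oracle_gru_step <- function(x, h_prev, par) {
  D <- length(h_prev)
  h_new <- numeric(D)
  for (i in seq_len(D)) {
    az <- sum(par$uz[i, ] * x) + sum(par$wz[i, ] * h_prev) + par$bz[i]
    ar <- sum(par$ur[i, ] * x) + sum(par$wr[i, ] * h_prev) + par$br[i]
    z <- 1 / (1 + exp(-az))
    r <- 1 / (1 + exp(-ar))
    ah <- sum(par$uh[i, ] * x) + r * sum(par$wh[i, ] * h_prev) + par$bh[i]
    cand <- tanh(ah)
    h_new[i] <- z * h_prev[i] + (1 - z) * cand
  }
  h_new
}

# Independent scalar forward pass for a whole record (content scoring).
oracle_forward <- function(record, par, theta) {
  H <- ncol(par$wv)
  h <- numeric(length(par$q))
  logits <- numeric(length(record$visits))
  for (t in seq_along(record$visits)) {
    x <- numeric(H)
    if (t > 1) for (m in record$visits[[t - 1]]$codes) x <- x + par$wv[m, ]
    h <- oracle_gru_step(x, h, par)
    bt <- numeric(length(theta))
    cs <- record$visits[[t]]$codes
    if (length(cs)) {
      for (m in cs) bt <- bt + par$btop[m, ]
      bt <- bt / length(cs)
    }
    logits[t] <- sum(par$q * h) + par$q0 + sum(bt * theta)
  }
  logits
}

# Independent scalar recognition network.
oracle_posterior <- function(counts, par) {
  relu <- function(v) ifelse(v > 0, v, 0)
  r1 <- relu(as.numeric(par$w1 %*% counts) + par$b1)
  r2 <- relu(as.numeric(par$w2 %*% r1) + par$b2)
  list(mu = as.numeric(par$wmu %*% r2) + par$bmu,
       log_sigma = as.numeric(par$wsig %*% r2) + par$bsig)
}

pooled_test_scores <- function(corpus, fit) {
  test <- corpus_subset(corpus, "test")
  probs <- predict(fit, test)
  list(scores = unlist(lapply(seq_along(test$records),
                              function(i) probs[[i]][test$records[[i]]$mask])),
       labels = unlist(lapply(test$records, function(r) {
         vapply(r$visits, function(v) if (is.null(v$label)) NA_integer_ else v$label,
                integer(1))[r$mask]
       })))
}
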