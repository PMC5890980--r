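#' Subsample-and-combine synthetic corpus from a source corpus
#'
#' Emulates a de-identification procedure for visit-sequence data: for each
#' source record a fraction u ~ Uniform(0.3, 0.5) of its visits is kept
#' (ceiling(u * T) visits sampled without replacement, source order
#' preserved), record order is permuted, and consecutive record pairs are
#' merged into one synthetic patient. The second record's event times are
#' shifted so its first kept visit aligns with the first record's first kept
#' visit; the merged visit stream is sorted by time (stable; at equal times
#' the first record's visit comes first, and same-time visits are not
#' fused). Labels travel with their source visits unchanged. An odd record
#' out is dropped, so n records yield floor(n / 2) synthetic patients.
#'
#' @param source an \code{\link{ehr_corpus}} whose visits all carry times.
#' @param seed RNG seed; output is fully reproducible given the seed.
#' @return an \code{\link{ehr_corpus}} over the source vocabulary.
#' @export
subsample_combine <- function(source, seed = 1L) {
  n <- length(source$records)
  if (n < 2) stop("need at least 2 source records to combine")
  for (r in source$records) for (v in r$visits) {
    if (is.null(v$time)) stop("subsample_combine needs a time on every visit")
  }
  with_seed(seed, {
    kept <- lapply(source$records, function(r) {
      T_p <- length(r$visits)
      u <- stats::runif(1, 0.3, 0.5)
      m <- ceiling(u * T_p)
      idx <- sort(sample.int(T_p, m))
      r$visits[idx]
    })
    perm <- sample.int(n)
    kept <- kept[perm]
    n_out <- n %/% 2L
    records <- vector("list", n_out)
    for (i in seq_len(n_out)) {
      a <- kept[[2L * i - 1L]]
      b <- kept[[2L * i]]
      offset <- a[[1]]$time - b[[1]]$time
      b <- lapply(b, function(v) { v$time <- v$time + offset; v })
      visits <- c(a, b)
      src <- c(rep(0L, length(a)), rep(1L, length(b)))
      tms <- vapply(visits, `[[`, integer(1), "time")
      visits <- visits[order(tms, src, method = "radix")]
      records[[i]] <- ehr_record(sprintf("synth%05d", i), visits)
    }
    ehr_corpus(source$vocab, records)
  })
}

#' De novo synthetic EHR generator with known ground truth
#'
#' Simulates longitudinal visit-sequence data whose readmission risk has
#' both a patient-level (global) and a recent-visit (local) component, so
#' that model recovery can be judged against the true generating
#' probabilities. Per patient a context vector theta* ~ N(0, I_K) is drawn;
#' visit codes are sampled from a mixture of K sparse positive topic-code
#' rows weighted by softmax(theta*). A damped scalar state
#' \code{s_t = 0.7 s_(t-1) + (acute_t - E[acute])}, driven by a designated
#' acute code subset (10 percent of the vocabulary), carries local risk. The
#' true per-visit risk is
#' \code{p*_t = sigmoid(label_bias + global_weight * <w_g, theta*> +
#' local_weight * s_t)} with w_g the first standard basis vector, and labels
#' are Bernoulli(p*_t). Every visit is supervised. (w_g must not be constant
#' across topics: the code distribution depends on theta* only through
#' softmax(theta*), which is invariant to adding a constant to theta*, so a
#' uniform w_g would make the global risk component unrecoverable from the
#' codes by construction.)
#'
#' Defaults mirror a large chronic-disease cohort: a 618-code vocabulary,
#' about 80 visits per patient and about 2.86 codes per visit (about 228
#' events per patient).
#'
#' @param n_patients number of patients (default 3000).
#' @param vocab_size vocabulary size C (default 618).
#' @param n_topics latent topic count K (default 10).
#' @param mean_visits Poisson mean of visits per patient (default 80,
#'   minimum 1).
#' @param mean_codes_per_visit Poisson mean of codes per visit (default
#'   2.86, minimum 1; within-visit duplicates collapse, set semantics).
#' @param global_weight,local_weight coefficients of the two risk
#'   components (defaults 1 and 1).
#' @param label_bias intercept of the risk logit (default 0).
#' @param seed RNG seed; output is bitwise reproducible.
#' @return a list with \code{corpus} (an \code{\link{ehr_corpus}}) and
#'   \code{truth}: \code{theta} (n x K matrix of true context vectors),
#'   \code{df} (one row per visit: pid, visit, p_star, label),
#'   \code{acute_codes}, and the generator's own bookkeeping counters
#'   \code{n_visits} and \code{n_events}.
#' @export
simulate_ehr <- function(n_patients = 3000L, vocab_size = 618L, n_topics = 10L,
                         mean_visits = 80, mean_codes_per_visit = 2.86,
                         global_weight = 1, local_weight = 1,
                         label_bias = 0, seed = 1L) {
  stopifnot(n_patients >= 1, vocab_size >= 2, n_topics >= 1,
            mean_visits > 0, mean_codes_per_visit > 0,
            is.finite(global_weight), is.finite(local_weight))
  C <- as.integer(vocab_size); K <- as.integer(n_topics)
  vocab <- sprintf("C%04d", seq_len(C))
  with_seed(seed, {
    # sparse positive topic-code rows with a small floor so every code is
    # reachable; row-normalized
    active <- matrix(stats::rbinom(K * C, 1L, min(1, 3 / K)), K, C)
    G <- active * matrix(stats::rexp(K * C), K, C) + 0.02
    G <- G / rowSums(G)
    acute <- sample.int(C, max(1L, round(0.1 * C)))
    is_acute <- logical(C); is_acute[acute] <- TRUE
    w_g <- c(1, numeric(K - 1))
    # centering constant for the local state: expected acute codes per visit
    # under the topic-average code distribution
    acute_rate <- mean_codes_per_visit * sum(colMeans(G)[acute])

    theta <- matrix(stats::rnorm(n_patients * K), n_patients, K)
    records <- vector("list", n_patients)
    rows_pid <- character(0); rows_visit <- integer(0)
    rows_p <- numeric(0); rows_y <- integer(0)
    n_visits_tot <- 0L; n_events_tot <- 0L
    for (i in seq_len(n_patients)) {
      th <- theta[i, ]
      w <- exp(th - max(th)); w <- w / sum(w)
      mix <- drop(w %*% G)
      T_p <- max(1L, stats::rpois(1, mean_visits))
      M <- pmax(1L, stats::rpois(T_p, mean_codes_per_visit))
      draws <- sample.int(C, sum(M), replace = TRUE, prob = mix)
      ends <- cumsum(M)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      gaps <- stats::rpois(T_p, 13) + 1L
      times <- cumsum(gaps) - gaps[1]
      s <- 0
      glob <- global_weight * sum(w_g * th)
      visits <- vector("list", T_p)
      p_star <- numeric(T_p)
      for (t in seq_len(T_p)) {
        cs <- unique(draws[starts[t]:ends[t]])
        s <- 0.7 * s + (sum(is_acute[cs]) - acute_rate)
        p <- stats::plogis(label_bias + glob + local_weight * s)
        lab <- stats::rbinom(1, 1L, p)
        visits[[t]] <- ehr_visit(cs, time = times[t], label = lab)
        p_star[t] <- p
        n_events_tot <- n_events_tot + length(cs)
      }
      n_visits_tot <- n_visits_tot + T_p
      pid <- sprintf("P%05d", i)
      records[[i]] <- ehr_record(pid, visits)
      rows_pid <- c(rows_pid, rep(pid, T_p))
      rows_visit <- c(rows_visit, seq_len(T_p))
      rows_p <- c(rows_p, p_star)
      rows_y <- c(rows_y, vapply(visits, `[[`, integer(1), "label"))
    }
    rownames(theta) <- vapply(records, `[[`, character(1), "pid")
    list(corpus = ehr_corpus(vocab, records),
         truth = list(theta = theta,
                      df = data.frame(pid = rows_pid, visit = rows_visit,
                                      p_star = rows_p, label = rows_y),
                      acute_codes = vocab[acute],
                      n_visits = n_visits_tot, n_events = n_events_tot))
  })
}

#' Write the ground-truth sidecar of a de novo simulation
#'
#' @param sim result of \code{\link{simulate_ehr}}.
#' @param path output path (tab-separated: pid, visit, p_star, label).
#' @export
write_ground_truth <- function(sim, path) {
  utils::write.table(sim$truth$df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
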