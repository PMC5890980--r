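#' Fit the topic-biased GRU readmission model
#'
#' Maximizes the single-sample reparameterized ELBO over the training split
#' with Adam, visiting patients in shuffled order (batch size 1 by default,
#' i.e. one update per patient). After every epoch the selection metric is
#' computed on the validation split from posterior-mean predictions; the
#' returned parameters are those of the best validation epoch (early stopping
#' with patience). The \code{"gru"} variant drops the context vector and the
#' KL term, reducing the objective to the Bernoulli log-likelihood: plain
#' logistic regression on the GRU hidden state.
#'
#' @param corpus an \code{\link{ehr_corpus}} with train and validation split
#'   tags (see \code{\link{split_corpus}}).
#' @param variant "content" (GRU + patient context vector) or "gru"
#'   (ablation).
#' @param embed_dim,hidden_dim,n_topics,rec_dims network dimensions, see
#'   \code{\link{init_params}}.
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size patients per gradient update (default 1).
#' @param max_epochs upper bound on training epochs (default 100).
#' @param patience epochs without validation improvement before stopping
#'   (default 10).
#' @param selection_metric validation metric for early stopping, "roc_auc" or
#'   "pr_auc". Falls back to mean validation log-likelihood when the metric
#'   is undefined (single-class validation labels).
#' @param clip_norm global gradient-norm clip (default 5); NULL disables
#'   clipping (strict mode).
#' @param scale_counts divide the recognition input by the patient's number
#'   of visits (default FALSE: raw counts).
#' @param theta_context "full" (default: the posterior conditions on the
#'   whole record) or "causal" (prediction-time posterior per visit uses
#'   previous visits only). Training always uses the full-record posterior.
#' @param seed seed controlling initialization, shuffling and
#'   reparameterization noise.
#' @param verbose print one line per epoch.
#' @return an object of class \code{topicgru}: parameters, config, per-epoch
#'   \code{history} (mean training ELBO, validation metric), \code{best_epoch}
#'   and the vocabulary hash of the training corpus.
#' @export
topicgru <- function(corpus, variant = c("content", "gru"),
                     embed_dim = 100L, hidden_dim = 200L, n_topics = 50L,
                     rec_dims = c(200L, 200L),
                     learning_rate = 0.001, batch_size = 1L,
                     max_epochs = 100L, patience = 10L,
                     selection_metric = c("roc_auc", "pr_auc"),
                     clip_norm = 5, theta_context = c("full", "causal"),
                     scale_counts = FALSE, seed = 1L, verbose = FALSE) {
  variant <- match.arg(variant)
  selection_metric <- match.arg(selection_metric)
  theta_context <- match.arg(theta_context)
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 0)
  train <- corpus_subset(corpus, "train")
  val <- corpus_subset(corpus, "validation")
  if (!length(train$records) || !length(val$records)) {
    stop("train and validation splits must both be nonempty")
  }
  C <- length(corpus$vocab)
  par <- init_params(C, embed_dim, hidden_dim, n_topics, rec_dims,
                     seed = derive_seed(seed, 1L))
  opt <- adam_init(par, learning_rate)
  metric_fun <- if (selection_metric == "roc_auc") roc_auc else pr_auc

  n_train <- length(train$records)
  dims <- param_dims(par)
  history <- data.frame(epoch = integer(), elbo = numeric(), val = numeric())
  best <- list(par = par, val = -Inf, epoch = 0L)
  wait <- 0L
  set.seed(derive_seed(seed, 2L))
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n_train)
    tot <- 0
    acc <- NULL
    in_batch <- 0L
    for (k in seq_along(ord)) {
      i <- ord[k]
      eps <- if (variant == "content") stats::rnorm(dims$N) else NULL
      res <- elbo_grad(train$records[[i]], par, eps = eps, variant = variant,
                       scale_counts = scale_counts)
      if (!is.finite(res$elbo)) {
        stop("non-finite objective at record ", i, " (patient ",
             train$records[[i]]$pid, "), epoch ", epoch)
      }
      tot <- tot + res$elbo
      acc <- if (is.null(acc)) res$grad else add_params(acc, res$grad)
      in_batch <- in_batch + 1L
      if (in_batch == batch_size || k == length(ord)) {
        if (!is.null(clip_norm)) acc <- clip_global_norm(acc, clip_norm)
        upd <- adam_step(opt, par, acc)
        par <- upd$par; opt <- upd$opt
        acc <- NULL; in_batch <- 0L
      }
    }
    val_metric <- validation_metric(val, par, variant, metric_fun, scale_counts)
    history <- rbind(history, data.frame(epoch = epoch, elbo = tot / n_train,
                                         val = val_metric))
    if (verbose) {
      message(sprintf("epoch %3d  elbo %10.4f  val %.4f",
                      epoch, tot / n_train, val_metric))
    }
    if (val_metric > best$val + 1e-12) {
      best <- list(par = par, val = val_metric, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience && patience > 0L) break
    }
  }
  structure(list(
    par = best$par,
    variant = variant,
    history = history,
    best_epoch = best$epoch,
    vocab = corpus$vocab,
    vocab_hash = vocab_hash(corpus$vocab),
    config = list(embed_dim = dims$H, hidden_dim = dims$D,
                  n_topics = dims$N, rec_dims = c(dims$D1, dims$D2),
                  learning_rate = learning_rate, batch_size = batch_size,
                  max_epochs = max_epochs, patience = patience,
                  selection_metric = selection_metric, clip_norm = clip_norm,
                  theta_context = theta_context, scale_counts = scale_counts,
                  seed = seed)
  ), class = "topicgru")
}

validation_metric <- function(val, par, variant, metric_fun,
                              scale_counts = FALSE) {
  scores <- numeric(); labels <- integer(); ll <- 0
  for (r in val$records) {
    p <- record_probs(r, par, variant, scale_counts = scale_counts)
    y <- visit_labels(r)
    scores <- c(scores, p[r$mask])
    labels <- c(labels, y[r$mask])
    lg <- qlogis(pmin(pmax(p[r$mask], 1e-12), 1 - 1e-12))
    ll <- ll + bernoulli_loglik(y[r$mask], lg)
  }
  out <- tryCatch(metric_fun(scores, labels), error = function(e) NA_real_)
  # undefined metric (single-class validation): fall back to log-likelihood
  if (is.na(out)) out <- ll / length(labels)
  out
}

# Posterior-mean per-visit probabilities for one record.
record_probs <- function(record, par, variant, theta_context = "full",
                         scale_counts = FALSE) {
  if (variant == "gru") return(forward_record(record, par)$prob)
  dims <- param_dims(par)
  if (theta_context == "full") {
    post <- infer_posterior(rec_input(record, dims$C, scale_counts), par)
    forward_record(record, par, theta = post$mu)$prob
  } else {
    base <- forward_record(record, par, keep = TRUE)
    logit <- base$logit
    for (t in seq_along(record$visits)) {
      counts <- patient_counts(record, dims$C, upto_visit = t)
      if (scale_counts && t > 1) counts <- counts / (t - 1)
      post <- infer_posterior(counts, par)
      logit[t] <- logit[t] + sum(base$Bt[t, ] * post$mu)
    }
    plogis(logit)
  }
}

add_params <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

clip_global_norm <- function(grad, max_norm) {
  nrm <- sqrt(sum(vapply(grad, function(x) sum(x * x), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm) {
    scl <- max_norm / nrm
    for (nm in names(grad)) grad[[nm]] <- grad[[nm]] * scl
  }
  grad
}

adam_init <- function(par, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = zero_like(par), v = zero_like(par), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

# One Adam update; grad is the gradient of the loss (-ELBO) being minimized.
adam_step <- function(opt, par, grad) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    par[[nm]] <- par[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(par = par, opt = opt)
}

#' @export
print.topicgru <- function(x, ...) {
  cat("Topic-biased GRU readmission model (variant:", x$variant, ")\n")
  cat(sprintf("  vocabulary: %d codes; H=%d, D_h=%d, N=%d\n",
              length(x$vocab), x$config$embed_dim, x$config$hidden_dim,
              x$config$n_topics))
  cat(sprintf("  trained %d epochs, best validation %s %.4f at epoch %d\n",
              nrow(x$history), x$config$selection_metric,
              max(x$history$val), x$best_epoch))
  invisible(x)
}

#' @export
summary.topicgru <- function(object, ...) {
  n_par <- sum(vapply(object$par, length, numeric(1)))
  out <- list(variant = object$variant, n_parameters = n_par,
              config = object$config, history = object$history,
              best_epoch = object$best_epoch)
  class(out) <- "summary.topicgru"
  out
}

#' @export
print.summary.topicgru <- function(x, ...) {
  cat("Variant:", x$variant, " (", x$n_parameters, "parameters )\n")
  cat("Best epoch:", x$best_epoch, "\n")
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.topicgru <- function(object, ...) object$par

#' Per-visit readmission probabilities for new data
#'
#' Scores every visit of every record with the fitted model, using the
#' posterior-mean context vector (deterministic). With
#' \code{theta_context = "causal"} the context at visit t is inferred from
#' visits before t only.
#'
#' @param object a fitted \code{\link{topicgru}} model.
#' @param corpus an \code{\link{ehr_corpus}} over the same vocabulary the
#'   model was fitted on (checked by hash).
#' @param type "prob" for per-visit probabilities, "logit" for logits,
#'   "embedding" for the patient embedding matrix
#'   (see \code{\link{embed_patients}}).
#' @param theta_context NULL to use the fitted config, else "full"/"causal".
#' @param ... unused.
#' @return for "prob"/"logit", a named list (one numeric vector per patient,
#'   all visits); for "embedding", a matrix.
#' @export
predict.topicgru <- function(object, corpus, type = c("prob", "logit", "embedding"),
                             theta_context = NULL, ...) {
  type <- match.arg(type)
  check_vocab(object, corpus)
  if (is.null(theta_context)) theta_context <- object$config$theta_context
  if (type == "embedding") return(embed_patients(corpus, object))
  out <- lapply(corpus$records, function(r) {
    p <- record_probs(r, object$par, object$variant, theta_context,
                      scale_counts = isTRUE(object$config$scale_counts))
    if (type == "logit") qlogis(p) else p
  })
  names(out) <- vapply(corpus$records, `[[`, character(1), "pid")
  out
}

check_vocab <- function(object, corpus) {
  if (!identical(object$vocab_hash, vocab_hash(corpus$vocab))) {
    stop("corpus vocabulary does not match the fitted model's vocabulary")
  }
}

#' @export
residuals.topicgru <- function(object, corpus, ...) {
  probs <- predict(object, corpus)
  rows <- lapply(seq_along(corpus$records), function(i) {
    r <- corpus$records[[i]]
    y <- visit_labels(r)
    keep <- which(r$mask)
    if (!length(keep)) return(NULL)
    data.frame(pid = r$pid, visit = keep, label = y[keep],
               prob = probs[[i]][keep])
  })
  out <- do.call(rbind, rows)
  out$residual <- out$label - out$prob
  out
}

#' Simulate readmission labels from a fitted model
#'
#' Draws per-visit Bernoulli labels at the fitted posterior-mean
#' probabilities, one replicate per column.
#'
#' @param object a fitted \code{\link{topicgru}} model.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param corpus corpus to score and simulate over.
#' @param ... unused.
#' @return a list of length nsim; each element is a list of 0/1 vectors
#'   (one per patient, one entry per visit).
#' @export
simulate.topicgru <- function(object, nsim = 1, seed = NULL, corpus, ...) {
  probs <- predict(object, corpus)
  draw <- function() lapply(probs, function(p) stats::rbinom(length(p), 1L, p))
  if (!is.null(seed)) with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

#' @export
plot.topicgru <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$elbo, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean training ELBO",
                 main = "Training objective", ...)
  graphics::plot(x$history$epoch, x$history$val, type = "b", pch = 16,
                 xlab = "epoch", ylab = x$config$selection_metric,
                 main = "Validation metric", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' @param object a fitted \code{\link{topicgru}} model.
#' @param path file path for the checkpoint archive.
#' @return \code{load_checkpoint} returns the fitted model.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "topicgru"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "topicgru")) stop("not a model checkpoint: ", path)
  obj
}
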