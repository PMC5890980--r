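#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counted one half; computed from midranks.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), same length.
#' @return scalar in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes present")
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: thresholds are swept over the distinct score
#' values in decreasing order and precision is accumulated over recall
#' increments; tied scores enter as one group.
#'
#' @inheritParams roc_auc
#' @return scalar in (0, 1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("pr_auc needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification accuracy at a threshold
#'
#' Fraction of points with \code{(score >= threshold) == label}.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold (default 0.5; scores at the threshold
#'   are called positive).
#' @return scalar in [0, 1].
#' @export
accuracy_score <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) stop("empty input")
  mean((scores >= threshold) == (as.integer(labels) == 1L))
}

#' Repeated-run evaluation of a model variant
#'
#' Fits the model \code{n_runs} times with seeds \code{base_seed + 0 ..
#' n_runs - 1} on the corpus's train/validation splits, scores the test
#' split with posterior-mean predictions, pools all supervised visit
#' predictions across test patients (micro-pooling), and reports each
#' metric's mean and sample standard deviation over runs. The split is held
#' fixed across runs (only initialization, shuffling and reparameterization
#' noise are re-seeded) unless \code{resplit} is TRUE, in which case the
#' split is re-drawn per run with the run's seed.
#'
#' @param corpus a split-tagged \code{\link{ehr_corpus}}.
#' @param n_runs number of repetitions (default 10).
#' @param base_seed seed of the first run.
#' @param resplit re-draw the split each run.
#' @param split_sizes sizes passed to \code{\link{split_corpus}} when
#'   resplitting.
#' @param ... arguments passed to \code{\link{topicgru}} (variant,
#'   dimensions, learning rate, epochs, ...).
#' @return an object of class \code{eval_report}: a per-run data frame plus
#'   mean/sd per metric (\code{pr_auc}, \code{roc_auc}, \code{acc}).
#' @export
evaluate_repeated <- function(corpus, n_runs = 10L, base_seed = 1L,
                              resplit = FALSE, split_sizes = NULL, ...) {
  if (is.null(corpus$split) && !resplit) {
    stop("corpus has no splits; run split_corpus or set resplit = TRUE")
  }
  runs <- data.frame(run = seq_len(n_runs), seed = base_seed + seq_len(n_runs) - 1L,
                     pr_auc = NA_real_, roc_auc = NA_real_, acc = NA_real_)
  for (i in seq_len(n_runs)) {
    sd_i <- runs$seed[i]
    cp <- if (resplit) split_corpus(corpus, split_sizes, seed = sd_i) else corpus
    fit <- topicgru(cp, seed = sd_i, ...)
    test <- corpus_subset(cp, "test")
    probs <- predict(fit, test)
    scores <- numeric(); labels <- integer()
    for (j in seq_along(test$records)) {
      r <- test$records[[j]]
      scores <- c(scores, probs[[j]][r$mask])
      labels <- c(labels, visit_labels(r)[r$mask])
    }
    runs$pr_auc[i] <- pr_auc(scores, labels)
    runs$roc_auc[i] <- roc_auc(scores, labels)
    runs$acc[i] <- accuracy_score(scores, labels)
  }
  summarise <- function(x) c(mean = mean(x),
                             sd = if (n_runs > 1) stats::sd(x) else 0)
  structure(list(runs = runs, n_runs = n_runs,
                 pr_auc = summarise(runs$pr_auc),
                 roc_auc = summarise(runs$roc_auc),
                 acc = summarise(runs$acc)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation over", x$n_runs, "runs (mean ± sd):\n")
  for (m in c("pr_auc", "roc_auc", "acc")) {
    cat(sprintf("  %-8s %.4f ± %.4f\n", m, x[[m]]["mean"], x[[m]]["sd"]))
  }
  invisible(x)
}

#' Export an evaluation report as a data frame
#'
#' @param x an \code{eval_report}.
#' @param ... unused.
#' @return data frame with one row per metric: mean, sd and per-run values.
#' @export
as.data.frame.eval_report <- function(x, ...) {
  mets <- c("pr_auc", "roc_auc", "acc")
  out <- data.frame(metric = mets,
                    mean = vapply(mets, function(m) x[[m]]["mean"], numeric(1)),
                    sd = vapply(mets, function(m) x[[m]]["sd"], numeric(1)))
  per_run <- t(as.matrix(x$runs[, mets]))
  colnames(per_run) <- paste0("run", seq_len(x$n_runs))
  cbind(out, per_run, row.names = NULL)
}
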