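#' Patient embeddings from a fitted model
#'
#' Represents each patient as the concatenation of the posterior-mean
#' context vector (length N, from the full record) and the final GRU hidden
#' state (length D_h). Under the GRU-only variant the context block is zero.
#'
#' @param corpus an \code{\link{ehr_corpus}} over the fitted vocabulary.
#' @param fit a fitted \code{\link{topicgru}} model.
#' @return numeric matrix, one row per patient (rownames = patient ids),
#'   N + D_h columns named theta1..thetaN, h1..hD.
#' @export
embed_patients <- function(corpus, fit) {
  check_vocab(fit, corpus)
  par <- fit$par
  dims <- param_dims(par)
  n <- length(corpus$records)
  out <- matrix(0, n, dims$N + dims$D,
                dimnames = list(vapply(corpus$records, `[[`, character(1), "pid"),
                                c(paste0("theta", seq_len(dims$N)),
                                  paste0("h", seq_len(dims$D)))))
  for (i in seq_len(n)) {
    r <- corpus$records[[i]]
    theta <- if (fit$variant == "content") {
      counts <- patient_counts(r, dims$C)
      if (isTRUE(fit$config$scale_counts)) counts <- counts / length(r$visits)
      infer_posterior(counts, par)$mu
    } else numeric(dims$N)
    h_final <- forward_record(r, par)$hidden[length(r$visits), ]
    out[i, ] <- c(theta, h_final)
  }
  out
}

#' Cluster patient embeddings with k-means
#'
#' Seeded squared-Euclidean k-means (multiple random restarts keeping the
#' best within-cluster sum of squares).
#'
#' @param embeddings matrix from \code{\link{embed_patients}}.
#' @param k number of clusters (default 20).
#' @param seed RNG seed for initialization.
#' @param nstart random restarts (default 10).
#' @return integer cluster assignment in 1..k, named by patient id, with the
#'   fitted \code{kmeans} object in attribute "kmeans".
#' @export
cluster_patients <- function(embeddings, k = 20L, seed = 1L, nstart = 10L) {
  if (nrow(embeddings) < k) {
    stop("need at least k = ", k, " patients, got ", nrow(embeddings))
  }
  km <- with_seed(seed, stats::kmeans(embeddings, centers = k, nstart = nstart,
                                      iter.max = 100))
  out <- km$cluster
  names(out) <- rownames(embeddings)
  attr(out, "kmeans") <- km
  out
}

#' Per-cluster readmission burden and top clinical events
#'
#' For each cluster: the number of patients, the mean per-patient count of
#' positive (readmission) labels, and the event codes ranked by their
#' within-cluster occurrence count after excluding the globally most common
#' codes (which describe the whole cohort rather than the cluster).
#'
#' @param corpus the corpus the assignments refer to (same order of records).
#' @param assignments integer cluster ids from \code{\link{cluster_patients}}.
#' @param exclude_top number of globally most frequent codes to drop from the
#'   rankings (default 3); ignored when \code{exclude_codes} is given.
#' @param exclude_codes optional explicit character vector of codes to drop.
#' @param top_n how many top events to keep per cluster (default 10).
#' @return a list of class \code{cluster_summaries}; each element has
#'   \code{cluster_id}, \code{n_patients}, \code{avg_readmissions} and a
#'   \code{top_events} data frame (code, count).
#' @export
summarize_clusters <- function(corpus, assignments, exclude_top = 3L,
                               exclude_codes = NULL, top_n = 10L) {
  n <- length(corpus$records)
  if (length(assignments) != n) stop("assignments must cover every record")
  C <- length(corpus$vocab)
  global_counts <- numeric(C)
  for (r in corpus$records) for (v in r$visits) {
    global_counts[v$codes] <- global_counts[v$codes] + 1
  }
  excl <- if (!is.null(exclude_codes)) {
    match(exclude_codes, corpus$vocab)
  } else if (exclude_top > 0) {
    order(global_counts, decreasing = TRUE)[seq_len(min(exclude_top, C))]
  } else integer()
  out <- lapply(sort(unique(assignments)), function(k) {
    idx <- which(assignments == k)
    counts <- numeric(C)
    readmits <- vapply(idx, function(i) {
      r <- corpus$records[[i]]
      for (v in r$visits) counts[v$codes] <<- counts[v$codes] + 1
      y <- visit_labels(r)
      sum(y[r$mask] == 1L)
    }, numeric(1))
    ranked <- setdiff(order(counts, decreasing = TRUE), excl)
    ranked <- ranked[counts[ranked] > 0]
    ranked <- utils::head(ranked, top_n)
    list(cluster_id = k, n_patients = length(idx),
         avg_readmissions = mean(readmits),
         total_event_counts = counts,
         top_events = data.frame(code = corpus$vocab[ranked],
                                 count = counts[ranked]))
  })
  structure(out, class = "cluster_summaries")
}

#' @export
print.cluster_summaries <- function(x, ...) {
  for (s in x) {
    cat(sprintf("cluster %d: %d patients, %.2f readmissions/patient; top: %s\n",
                s$cluster_id, s$n_patients, s$avg_readmissions,
                paste(utils::head(s$top_events$code, 5), collapse = ", ")))
  }
  invisible(x)
}
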