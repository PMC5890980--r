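#' Initialize model parameters
#'
#' All weights for the generative network (code embeddings, GRU gates, output
#' vector, topic matrix) and the variational recognition network, drawn from
#' zero-mean uniform distributions scaled by fan-in (He-style bound
#' \code{sqrt(1/fan_in)}); biases start at zero.
#'
#' @param n_codes vocabulary size C.
#' @param embed_dim code-embedding dimension H (default 100).
#' @param hidden_dim GRU hidden dimension D_h (default 200).
#' @param n_topics context-vector dimension N (default 50).
#' @param rec_dims hidden widths of the two recognition layers
#'   (default \code{c(200, 200)}).
#' @param seed RNG seed for the draw.
#' @return a named list of numeric arrays (class \code{topicgru_params}):
#'   \code{wv} (C x H embeddings), GRU gate matrices \code{uz, wz, ur, wr,
#'   uh, wh} and biases \code{bz, br, bh}, output weights \code{q, q0}, topic
#'   matrix \code{btop} (C x N), and recognition weights \code{w1, b1, w2,
#'   b2, wmu, bmu, wsig, bsig}.
#' @export
init_params <- function(n_codes, embed_dim = 100L, hidden_dim = 200L,
                        n_topics = 50L, rec_dims = c(200L, 200L), seed = 1L) {
  H <- as.integer(embed_dim); D <- as.integer(hidden_dim)
  N <- as.integer(n_topics); C <- as.integer(n_codes)
  D1 <- as.integer(rec_dims[1]); D2 <- as.integer(rec_dims[2])
  u <- function(nr, nc, fan) matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
  par <- with_seed(seed, list(
    wv = u(C, H, C),
    uz = u(D, H, H), wz = u(D, D, D), bz = numeric(D),
    ur = u(D, H, H), wr = u(D, D, D), br = numeric(D),
    uh = u(D, H, H), wh = u(D, D, D), bh = numeric(D),
    q = u(D, 1, D)[, 1], q0 = 0,
    # fan-in of the topic-bias score B_t' theta is N (not C)
    btop = u(C, N, N),
    w1 = u(D1, C, C), b1 = numeric(D1),
    w2 = u(D2, D1, D1), b2 = numeric(D2),
    wmu = u(N, D2, D2), bmu = numeric(N),
    wsig = u(N, D2, D2), bsig = numeric(N)
  ))
  structure(par, dims = list(C = C, H = H, D = D, N = N, D1 = D1, D2 = D2),
            class = "topicgru_params")
}

param_dims <- function(par) attr(par, "dims")

# Zero-filled copy of a parameter list, for gradient accumulators.
zero_like <- function(par) {
  out <- lapply(par, function(x) { x[] <- 0; x })
  attributes(out) <- attributes(par)
  out
}

#' Embed a visit as the sum of its code embeddings
#'
#' A visit is a binary indicator vector over the vocabulary; its embedding is
#' the matrix product of the embedding matrix transpose with that indicator,
#' i.e. the sum of the embedding rows of the codes present. An empty visit
#' embeds to the zero vector.
#'
#' @param codes integer vector of code indices (a visit's code set).
#' @param wv C x H embedding matrix.
#' @return numeric vector of length H.
#' @export
embed_visit <- function(codes, wv) {
  if (length(codes) == 0) return(numeric(ncol(wv)))
  if (length(codes) == 1) return(wv[codes, ])
  colSums(wv[codes, , drop = FALSE])
}

#' One GRU step
#'
#' Computes the update gate z, reset gate r, candidate state (tanh of the
#' input term plus the reset-gated recurrent term) and the convex combination
#' \code{h = z * h_prev + (1 - z) * candidate}.
#'
#' @param x input vector (length H).
#' @param h_prev previous hidden state (length D_h).
#' @param par parameter list holding \code{uz, wz, bz, ur, wr, br, uh, wh, bh}.
#' @return the new hidden state (length D_h).
#' @export
gru_step <- function(x, h_prev, par) {
  if (!all(is.finite(x)) || !all(is.finite(h_prev))) {
    stop("non-finite input to gru_step")
  }
  z <- plogis(par$uz %*% x + par$wz %*% h_prev + par$bz)
  r <- plogis(par$ur %*% x + par$wr %*% h_prev + par$br)
  cand <- tanh(par$uh %*% x + r * (par$wh %*% h_prev) + par$bh)
  drop(z * h_prev + (1 - z) * cand)
}

#' Topic bias of a visit
#'
#' The mean of the topic vectors of the codes in the visit; the zero vector
#' for an empty visit.
#'
#' @param codes integer vector of code indices.
#' @param btop C x N topic matrix.
#' @return numeric vector of length N.
#' @export
topic_bias <- function(codes, btop) {
  if (length(codes) == 0) return(numeric(ncol(btop)))
  if (length(codes) == 1) return(btop[codes, ])
  colMeans(btop[codes, , drop = FALSE])
}

# Full forward pass over one record. Input at step t is the embedding of the
# previous visit (the first step sees an empty visit), so the score for visit
# t conditions on history strictly before t plus the context vector. Returns
# all intermediates needed for backprop when keep = TRUE.
forward_record <- function(record, par, theta = NULL, keep = FALSE) {
  dims <- param_dims(par)
  T_p <- length(record$visits)
  H <- dims$H; D <- dims$D; N <- dims$N
  use_theta <- !is.null(theta)
  if (use_theta && length(theta) != N) stop("theta must have length ", N)
  X <- matrix(0, T_p, H)       # row t: embedding of visit t-1
  Bt <- matrix(0, T_p, N)      # row t: topic bias of visit t
  for (t in seq_len(T_p)) {
    if (t > 1) X[t, ] <- embed_visit(record$visits[[t - 1]]$codes, par$wv)
    if (use_theta || keep) Bt[t, ] <- topic_bias(record$visits[[t]]$codes, par$btop)
  }
  Hmat <- matrix(0, T_p, D)
  Zs <- matrix(0, T_p, D); Rs <- matrix(0, T_p, D)
  Cs <- matrix(0, T_p, D); Whh <- matrix(0, T_p, D)
  h <- numeric(D)
  for (t in seq_len(T_p)) {
    x <- X[t, ]
    z <- drop(plogis(par$uz %*% x + par$wz %*% h + par$bz))
    r <- drop(plogis(par$ur %*% x + par$wr %*% h + par$br))
    wh_h <- drop(par$wh %*% h)
    cand <- tanh(drop(par$uh %*% x) + r * wh_h + par$bh)
    h <- z * h + (1 - z) * cand
    Hmat[t, ] <- h
    if (keep) { Zs[t, ] <- z; Rs[t, ] <- r; Cs[t, ] <- cand; Whh[t, ] <- wh_h }
  }
  logit <- drop(Hmat %*% par$q) + par$q0
  if (use_theta) logit <- logit + drop(Bt %*% theta)
  out <- list(logit = logit, prob = plogis(logit), hidden = Hmat)
  if (keep) out <- c(out, list(X = X, Bt = Bt, Z = Zs, R = Rs, cand = Cs,
                               whh = Whh))
  out
}

#' Per-visit scores for one patient under the full model
#'
#' Runs the GRU over the visit sequence (the input at each step is the
#' previous visit's embedding; the first step sees an empty visit) and scores
#' each visit as \code{sigmoid(q' h_t + q0 + B_t' theta)} where \code{B_t} is
#' the visit's topic bias and \code{theta} the patient context vector.
#'
#' @param record an \code{\link{ehr_record}}.
#' @param par a \code{\link{init_params}} parameter list.
#' @param theta context vector of length N.
#' @return a list with per-visit \code{logit}, \code{prob} and the T x D_h
#'   matrix of hidden states.
#' @export
forward_scores <- function(record, par, theta) {
  forward_record(record, par, theta = theta)
}

#' Per-visit scores under the GRU-only ablation
#'
#' Identical to \code{\link{forward_scores}} with the topic-bias term removed
#' (equivalently, theta = 0): plain logistic regression on the GRU hidden
#' state.
#'
#' @inheritParams forward_scores
#' @return as \code{\link{forward_scores}}.
#' @export
gru_scores <- function(record, par) {
  forward_record(record, par, theta = NULL)
}

#' Bag-of-events count vector for a patient
#'
#' Entry c counts the visits (among the included prefix) containing code c.
#' With \code{upto_visit = NULL} all visits are included; with an integer t,
#' only visits strictly before t (the causal prefix used when conditioning a
#' prediction at visit t on the past only).
#'
#' @param record an \code{\link{ehr_record}}.
#' @param n_codes vocabulary size C.
#' @param upto_visit NULL for the whole record, or an integer in 1..T_p.
#' @return numeric count vector of length C.
#' @export
patient_counts <- function(record, n_codes, upto_visit = NULL) {
  T_p <- length(record$visits)
  if (is.null(upto_visit)) {
    idx <- seq_len(T_p)
  } else {
    if (upto_visit < 1 || upto_visit > T_p) {
      stop("upto_visit must lie in 1..", T_p)
    }
    idx <- seq_len(upto_visit - 1L)
  }
  counts <- numeric(n_codes)
  for (t in idx) {
    cs <- record$visits[[t]]$codes
    counts[cs] <- counts[cs] + 1
  }
  counts
}

# Recognition forward pass with intermediates for backprop.
recognition_forward <- function(counts, par) {
  a1 <- drop(par$w1 %*% counts) + par$b1
  r1 <- pmax(a1, 0)
  a2 <- drop(par$w2 %*% r1) + par$b2
  r2 <- pmax(a2, 0)
  list(r1 = r1, r2 = r2,
       mu = drop(par$wmu %*% r2) + par$bmu,
       log_sigma = drop(par$wsig %*% r2) + par$bsig)
}

#' Variational posterior over the patient context vector
#'
#' Two rectified layers over the patient's bag-of-events counts, followed by
#' affine heads for the posterior mean and log standard deviation of the
#' diagonal Gaussian q(theta | patient).
#'
#' @param counts non-negative count vector of length C
#'   (see \code{\link{patient_counts}}).
#' @param par parameter list holding \code{w1, b1, w2, b2, wmu, bmu, wsig,
#'   bsig}.
#' @return a list of class \code{posterior_gaussian} with \code{mu} and
#'   \code{log_sigma}, each of length N.
#' @export
infer_posterior <- function(counts, par) {
  if (!all(is.finite(counts))) stop("non-finite counts")
  f <- recognition_forward(counts, par)
  structure(list(mu = f$mu, log_sigma = f$log_sigma),
            class = "posterior_gaussian")
}

#' Draw a context vector by reparameterization
#'
#' Returns \code{mu + exp(log_sigma) * eps} with eps standard normal. Supply
#' \code{eps} explicitly (eps = 0 gives the posterior mean), or a seed from
#' which it is drawn.
#'
#' @param post a \code{posterior_gaussian}.
#' @param eps noise vector of length N, or NULL to draw one.
#' @param seed RNG seed used when eps is NULL.
#' @return numeric vector of length N.
#' @export
sample_theta <- function(post, eps = NULL, seed = NULL) {
  n <- length(post$mu)
  if (is.null(eps)) {
    eps <- if (is.null(seed)) stats::rnorm(n) else with_seed(seed, stats::rnorm(n))
  }
  post$mu + exp(post$log_sigma) * eps
}

#' KL divergence from the posterior to the standard normal prior
#'
#' Closed form for a diagonal Gaussian against N(0, I):
#' \code{0.5 * sum(mu^2 + sigma^2 - 1 - 2 log sigma)}. Non-negative, zero
#' exactly when the posterior equals the prior.
#'
#' @param post a \code{posterior_gaussian}.
#' @return a non-negative scalar.
#' @export
kl_to_prior <- function(post) {
  s2 <- exp(2 * post$log_sigma)
  0.5 * sum(post$mu^2 + s2 - 1 - 2 * post$log_sigma)
}
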