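# Numerically stable log(sigmoid(x)).
log_sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- -log1p(exp(-x[pos]))
  out[!pos] <- x[!pos] - log1p(exp(x[!pos]))
  out
}

# Bernoulli log-likelihood of labels y at logits l, summed.
bernoulli_loglik <- function(y, logit) {
  sum(log_sigmoid(ifelse(y == 1, logit, -logit)))
}

#' Single-sample ELBO for one patient record
#'
#' The evidence lower bound estimated with one reparameterized draw of the
#' context vector: the Bernoulli log-likelihood of the supervised visit
#' labels under the model probabilities, minus the closed-form KL divergence
#' from the variational posterior to the N(0, I) prior. Under the GRU-only
#' variant there is no context vector and the value reduces to the plain
#' Bernoulli log-likelihood. Always non-positive.
#'
#' @param record an \code{\link{ehr_record}} with at least one supervised
#'   (masked-in) visit.
#' @param par a \code{\link{init_params}} parameter list.
#' @param eps reparameterization noise (length N); \code{eps = 0} evaluates
#'   at the posterior mean. Drawn from \code{seed} when NULL.
#' @param seed RNG seed used when \code{eps} is NULL.
#' @param variant "content" (full model) or "gru" (ablation).
#' @param scale_counts divide the recognition input by the number of visits.
#' @return scalar ELBO estimate.
#' @export
elbo_loss <- function(record, par, eps = NULL, seed = NULL,
                      variant = c("content", "gru"), scale_counts = FALSE) {
  variant <- match.arg(variant)
  if (!any(record$mask)) stop("record ", record$pid, " has no supervised visits")
  y <- visit_labels(record)
  if (variant == "gru") {
    fw <- forward_record(record, par)
    return(bernoulli_loglik(y[record$mask], fw$logit[record$mask]))
  }
  dims <- param_dims(par)
  counts <- rec_input(record, dims$C, scale_counts)
  post <- infer_posterior(counts, par)
  theta <- sample_theta(post, eps = eps, seed = seed)
  fw <- forward_record(record, par, theta = theta)
  bernoulli_loglik(y[record$mask], fw$logit[record$mask]) - kl_to_prior(post)
}

visit_labels <- function(record) {
  vapply(record$visits, function(v) {
    if (is.null(v$label)) NA_integer_ else v$label
  }, integer(1))
}

# ELBO and the gradient of -ELBO w.r.t. every parameter, by backpropagation
# through time. eps is the (fixed) reparameterization noise; under the gru
# variant the recognition network and topic matrix receive no gradient and
# the objective is the Bernoulli log-likelihood alone.
rec_input <- function(record, C, scale_counts) {
  counts <- patient_counts(record, C)
  if (scale_counts) counts <- counts / length(record$visits)
  counts
}

elbo_grad <- function(record, par, eps = NULL, variant = "content",
                      scale_counts = FALSE) {
  dims <- param_dims(par)
  use_theta <- variant == "content"
  T_p <- length(record$visits)
  y <- visit_labels(record)
  mask <- record$mask
  if (!any(mask)) stop("record ", record$pid, " has no supervised visits")

  counts <- NULL; post <- NULL; theta <- NULL; rec <- NULL; sigma <- NULL
  if (use_theta) {
    counts <- rec_input(record, dims$C, scale_counts)
    rec <- recognition_forward(counts, par)
    post <- structure(list(mu = rec$mu, log_sigma = rec$log_sigma),
                      class = "posterior_gaussian")
    if (is.null(eps)) eps <- stats::rnorm(dims$N)
    sigma <- exp(rec$log_sigma)
    theta <- rec$mu + sigma * eps
  }
  fw <- forward_record(record, par, theta = theta, keep = TRUE)
  ll <- bernoulli_loglik(y[mask], fw$logit[mask])
  elbo <- if (use_theta) ll - kl_to_prior(post) else ll

  grad <- zero_like(par)
  # d(-loglik)/dlogit, zero on unsupervised visits
  g <- numeric(T_p)
  g[mask] <- fw$prob[mask] - y[mask]

  Hmat <- fw$hidden
  Hprev <- rbind(numeric(dims$D), Hmat[-T_p, , drop = FALSE])
  grad$q <- drop(crossprod(Hmat, g))
  grad$q0 <- sum(g)

  # backward through time: collect pre-activation gradients per step
  DAz <- matrix(0, T_p, dims$D)
  DAr <- matrix(0, T_p, dims$D)
  DAc <- matrix(0, T_p, dims$D)
  carry <- numeric(dims$D)
  for (t in rev(seq_len(T_p))) {
    dh <- g[t] * par$q + carry
    z <- fw$Z[t, ]; r <- fw$R[t, ]; cand <- fw$cand[t, ]; whh <- fw$whh[t, ]
    h_prev <- Hprev[t, ]
    dz <- dh * (h_prev - cand)
    dc <- dh * (1 - z)
    dhp <- dh * z
    dac <- dc * (1 - cand^2)
    dr <- dac * whh
    dhp <- dhp + drop(crossprod(par$wh, dac * r))
    daz <- dz * z * (1 - z)
    dar <- dr * r * (1 - r)
    dhp <- dhp + drop(crossprod(par$wz, daz)) + drop(crossprod(par$wr, dar))
    DAz[t, ] <- daz; DAr[t, ] <- dar; DAc[t, ] <- dac
    carry <- dhp
  }
  X <- fw$X
  grad$uz <- crossprod(DAz, X); grad$wz <- crossprod(DAz, Hprev)
  grad$bz <- colSums(DAz)
  grad$ur <- crossprod(DAr, X); grad$wr <- crossprod(DAr, Hprev)
  grad$br <- colSums(DAr)
  grad$uh <- crossprod(DAc, X)
  grad$wh <- crossprod(DAc * fw$R, Hprev)
  grad$bh <- colSums(DAc)

  # embeddings: input at step t is visit t-1
  DX <- DAz %*% par$uz + DAr %*% par$ur + DAc %*% par$uh
  for (t in seq_len(T_p)) {
    if (t == 1) next
    cs <- record$visits[[t - 1]]$codes
    if (length(cs)) grad$wv[cs, ] <- grad$wv[cs, , drop = FALSE] +
        rep(DX[t, ], each = length(cs))
  }

  if (use_theta) {
    # topic matrix: dlogit_t/dbtop[m, ] = theta / M_t for codes m in visit t
    for (t in seq_len(T_p)) {
      if (g[t] == 0) next
      cs <- record$visits[[t]]$codes
      if (length(cs)) grad$btop[cs, ] <- grad$btop[cs, , drop = FALSE] +
          rep((g[t] / length(cs)) * theta, each = length(cs))
    }
    dtheta <- drop(crossprod(fw$Bt, g))
    dmu <- dtheta + rec$mu                       # + dKL/dmu
    dlsig <- dtheta * sigma * eps + (sigma^2 - 1) # + dKL/dlog_sigma
    grad$wmu <- tcrossprod(dmu, rec$r2); grad$bmu <- dmu
    grad$wsig <- tcrossprod(dlsig, rec$r2); grad$bsig <- dlsig
    dr2 <- drop(crossprod(par$wmu, dmu)) + drop(crossprod(par$wsig, dlsig))
    da2 <- dr2 * (rec$r2 > 0)
    grad$w2 <- tcrossprod(da2, rec$r1); grad$b2 <- da2
    dr1 <- drop(crossprod(par$w2, da2))
    da1 <- dr1 * (rec$r1 > 0)
    grad$w1 <- tcrossprod(da1, counts); grad$b1 <- da1
  }
  list(elbo = elbo, grad = grad)
}

# Flatten a parameter list to one numeric vector and back; used by the
# finite-difference gradient checks and for norm computations.
flatten_params <- function(par) unlist(par, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    n <- length(skeleton[[nm]])
    out[[nm]][] <- vec[pos + seq_len(n)]
    pos <- pos + n
  }
  out
}
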