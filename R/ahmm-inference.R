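# Exact chain inference. On this model structure -- a first-order hidden
# chain whose continuous emission depends on the *observed* previous weight
# -- clique-tree (junction tree) inference reduces exactly to the classical
# forward-backward recursions with modified emission densities: conditioning
# on the observed AR parent only changes the per-visit emission term, never
# the clique structure of the chain. The recursions below therefore compute
# the exact smoothed posteriors.

# Core scaled forward-backward on an emission log-density matrix.
# want_xi: TRUE returns the full (k-1) x N x N pairwise posterior array;
# "sum" returns only its sum over t (the EM sufficient statistic).
fb_core <- function(E_log, pi, A, want_xi = TRUE) {
  k <- nrow(E_log)
  n <- ncol(E_log)
  cmax <- apply(E_log, 1, max)
  bad <- which(!is.finite(cmax) | cmax <= LOG_ZERO)
  if (length(bad)) {
    stopf("zero total emission likelihood at visit %d: no state can explain the observation",
          bad[1])
  }
  E <- exp(E_log - cmax)
  alpha <- matrix(0, k, n)
  norms <- numeric(k)
  a <- pi * E[1, ]
  norms[1] <- sum(a)
  if (norms[1] <= 0) stopf("zero forward probability at visit 1")
  alpha[1, ] <- a / norms[1]
  if (k > 1) {
    for (t in 2:k) {
      a <- as.numeric(crossprod(A, alpha[t - 1, ])) * E[t, ]
      norms[t] <- sum(a)
      if (norms[t] <= 0) stopf("zero forward probability at visit %d", t)
      alpha[t, ] <- a / norms[t]
    }
  }
  beta <- matrix(1, k, n)
  if (k > 1) {
    for (t in (k - 1):1) {
      beta[t, ] <- as.numeric(A %*% (E[t + 1, ] * beta[t + 1, ])) / norms[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  loglik <- sum(log(norms)) + sum(cmax)
  xi <- NULL
  if (identical(want_xi, "sum") && k > 1) {
    xi <- matrix(0, n, n)
    for (t in 2:k) {
      m <- (alpha[t - 1, ] %o% (E[t, ] * beta[t, ])) * A
      xi <- xi + m / sum(m)
    }
  } else if (isTRUE(want_xi) && k > 1) {
    xi <- array(0, dim = c(k - 1, n, n))
    for (t in 2:k) {
      m <- (alpha[t - 1, ] %o% (E[t, ] * beta[t, ])) * A
      xi[t - 1, , ] <- m / sum(m)
    }
  }
  list(gamma = gamma, xi = xi, loglik = loglik, alpha = alpha, norms = norms)
}

#' Smoothed state posteriors and sequence log-likelihood
#'
#' Runs exact forward-backward inference for one observation sequence under
#' the given parameters, in scaled arithmetic so sequences of length up to
#' thousands of visits remain numerically stable.
#'
#' @param seq An `observation_sequence` (or anything accepted by
#'   [as_observation_sequences()] that yields exactly one sequence).
#' @param params An `ahmm_params` object.
#' @return A list with `gamma` (k x N matrix of per-visit smoothed state
#'   posteriors, rows sum to 1), `xi` (array of dimension (k-1) x N x N of
#'   pairwise transition posteriors, each slice sums to 1; `NULL` for k = 1),
#'   and `loglik` (the sequence log-likelihood).
#' @export
forward_backward <- function(seq, params) {
  validate_ahmm_params(params)
  stack <- build_stack(list(seq))
  E_log <- emission_matrix(stack, params)
  out <- fb_core(E_log, params$pi, params$A, want_xi = TRUE)
  out[c("gamma", "xi", "loglik")]
}

#' Most probable state path (Viterbi decoding)
#'
#' @param seq An `observation_sequence`.
#' @param params An `ahmm_params` object.
#' @return Integer vector of state indices, length k. Ties are broken toward
#'   the lower state index.
#' @export
viterbi <- function(seq, params) {
  validate_ahmm_params(params)
  stack <- build_stack(list(seq))
  E_log <- emission_matrix(stack, params)
  k <- nrow(E_log)
  n <- ncol(E_log)
  logA <- log(pmax(params$A, 1e-300))
  delta <- log(pmax(params$pi, 1e-300)) + E_log[1, ]
  psi <- matrix(0L, k, n)
  if (k > 1) {
    for (t in 2:k) {
      cand <- delta + logA  # cand[i, j]: best ending in i then moving to j
      best <- apply(cand, 2, which.max)  # which.max takes the lowest index on ties
      delta <- cand[cbind(best, seq_len(n))] + E_log[t, ]
      psi[t, ] <- best
    }
  }
  path <- integer(k)
  path[k] <- which.max(delta)
  if (k > 1) for (t in (k - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Total log-likelihood of a cohort under given parameters
#'
#' Sequences contribute independently; the total is the sum of per-sequence
#' forward log-likelihoods.
#'
#' @param seqs List of `observation_sequence` objects.
#' @param params An `ahmm_params` object.
#' @return Scalar log-likelihood.
#' @export
cohort_loglik <- function(seqs, params) {
  validate_ahmm_params(params)
  stack <- build_stack(seqs)
  E_log <- emission_matrix(stack, params)
  total <- 0
  for (s in seq_len(stack$n_seq)) {
    rows <- stack$idx_start[s]:stack$idx_end[s]
    total <- total + fb_core(E_log[rows, , drop = FALSE], params$pi, params$A,
                             want_xi = FALSE)$loglik
  }
  total
}
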