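# Independent oracles and small generators shared across tests.

# Exhaustive path enumeration: joint log-probability of every state path,
# giving the exact sequence log-likelihood, smoothed marginals, and the
# most probable path. Independent of the forward-backward implementation.
enum_inference <- function(seq, params) {
  n <- params$n_states
  k <- length(seq$age)
  E <- matrix(0, k, n)
  for (t in seq_len(k)) {
    for (i in seq_len(n)) {
      E[t, i] <- emission_logdensity(
        params, i, seq$age[t], seq$weight[t], seq$sex, seq$genotype,
        prev_weight = if (t == 1) NULL else seq$weight[t - 1]
      )
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  logp <- apply(paths, 1, function(path) {
    lp <- log(params$pi[path[1]]) + E[1, path[1]]
    if (k > 1) {
      for (t in 2:k) {
        lp <- lp + log(params$A[path[t - 1], path[t]]) + E[t, path[t]]
      }
    }
    lp
  })
  total <- max(logp) + log(sum(exp(logp - max(logp))))
  w <- exp(logp - total)
  gamma <- matrix(0, k, n)
  for (t in seq_len(k)) {
    for (i in seq_len(n)) gamma[t, i] <- sum(w[paths[, t] == i])
  }
  best <- which.max(logp)  # first max: lowest-index path under expand.grid order
  list(loglik = total, gamma = gamma, map_path = unname(paths[best, ]),
       map_logp = logp[best])
}

# Random valid parameter set for small-N inference tests.
random_params <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rdir <- function(k) {
    g <- rgamma(k, 1)
    g / sum(g)
  }
  A <- t(vapply(seq_len(n), function(i) rdir(n), numeric(n)))
  A <- matrix(A, n, n)
  ahmm_params(
    pi = rdir(n), A = A,
    age_mean = runif(n, 5, 25), age_var = runif(n, 1, 16),
    sex_probs = t(vapply(seq_len(n), function(i) rdir(2), numeric(2))),
    geno_probs = t(vapply(seq_len(n), function(i) rdir(3), numeric(3))),
    ar_intercept = runif(n, 1, 8), ar_male = runif(n, -1, 2),
    ar_slope = runif(n, 0.1, 0.95), ar_var = runif(n, 0.5, 3),
    init_intercept = runif(n, 18, 32), init_male = runif(n, 0, 5),
    init_var = runif(n, 0.5, 4)
  )
}

# Random observation sequence of length k.
random_seq <- function(k, id = "m1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  observation_sequence(
    mouse_id = id,
    sex = sample(c("female", "male"), 1),
    genotype = sample(c("E3/3", "E3/4", "E4/4"), 1),
    age = sort(runif(k, 5, 28)),
    weight = runif(k, 15, 45)
  )
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

# Best elementwise transition-matrix error over state relabelings.
best_perm_error <- function(A_fit, A_true) {
  best <- Inf
  best_p <- NULL
  for (p in all_perms(nrow(A_true))) {
    err <- max(abs(A_fit[p, p, drop = FALSE] - A_true))
    if (err < best) {
      best <- err
      best_p <- p
    }
  }
  list(error = best, perm = best_p)
}

# Simulate, preprocess, and return model-ready sequences plus truth.
simulate_cohort <- function(config) {
  tp <- generate_true_params(config)
  sim <- simulate_colony(tp, config)
  pre <- apply_exclusions(colony_from_table(sim$colony)$mice)
  seqs <- suppressWarnings(as_observation_sequences(pre$retained))
  list(config = config, true_params = tp, sim = sim, pre = pre, seqs = seqs)
}
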