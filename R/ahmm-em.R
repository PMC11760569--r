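# EM (Baum-Welch) fitting of the autoregressive HMM.

# Weighted least squares for one state's weight regression; tiny ridge keeps
# the solve well-posed when a design column is constant (e.g. single-sex data).
wls_fit <- function(X, y, w, var_floor) {
  sw <- sum(w)
  XtW <- t(X * w)
  coefs <- solve(XtW %*% X + diag(1e-8, ncol(X)), XtW %*% y)
  res <- y - as.numeric(X %*% coefs)
  list(coefs = as.numeric(coefs), var = max(sum(w * res^2) / sw, var_floor))
}

# Precomputed design matrices shared across EM iterations.
em_design <- function(stack) {
  first_rows <- which(stack$is_first)
  ar_rows <- which(!stack$is_first)
  list(first_rows = first_rows, ar_rows = ar_rows,
       X_ar = cbind(1, stack$male[ar_rows], stack$prev_weight[ar_rows]),
       y_ar = stack$weight[ar_rows],
       X0 = cbind(1, stack$male[first_rows]),
       y0 = stack$weight[first_rows])
}

# Closed-form M-step from responsibilities G (n_obs x N), accumulated
# pairwise counts xi_sum (N x N), and first-visit posteriors pi_acc.
m_step_closed <- function(stack, design, G, xi_sum, pi_acc,
                          var_floor = 1e-3, prob_floor = 1e-12) {
  n <- ncol(G)
  resp <- colSums(G)
  pi_new <- floor_normalize(pi_acc, prob_floor)
  A_new <- if (n == 1) matrix(1, 1, 1) else
    t(apply(xi_sum, 1, floor_normalize, floor = prob_floor))
  sex_new <- matrix(0, n, 2)
  geno_new <- matrix(0, n, 3)
  for (s in 1:2) sex_new[, s] <- colSums(G[stack$sex_idx == s, , drop = FALSE])
  for (g in 1:3) geno_new[, g] <- colSums(G[stack$geno_idx == g, , drop = FALSE])
  sex_new <- t(apply(sex_new, 1, floor_normalize, floor = prob_floor))
  geno_new <- t(apply(geno_new, 1, floor_normalize, floor = prob_floor))
  age_mean <- colSums(G * stack$age) / resp
  age_var <- pmax(colSums(G * (stack$age - rep(age_mean, each = stack$n_obs))^2) / resp,
                  var_floor)
  ar_int <- ar_male <- ar_slope <- ar_var <- numeric(n)
  init_int <- init_male_ <- init_var <- numeric(n)
  G_ar <- G[design$ar_rows, , drop = FALSE]
  G0 <- G[design$first_rows, , drop = FALSE]
  for (i in seq_len(n)) {
    f <- wls_fit(design$X_ar, design$y_ar, pmax(G_ar[, i], 1e-300), var_floor)
    ar_int[i] <- f$coefs[1]; ar_male[i] <- f$coefs[2]; ar_slope[i] <- f$coefs[3]
    ar_var[i] <- f$var
    f0 <- wls_fit(design$X0, design$y0, pmax(G0[, i], 1e-300), var_floor)
    init_int[i] <- f0$coefs[1]; init_male_[i] <- f0$coefs[2]
    init_var[i] <- f0$var
  }
  ahmm_params(
    pi = pi_new, A = A_new, age_mean = age_mean, age_var = age_var,
    sex_probs = sex_new, geno_probs = geno_new,
    ar_intercept = ar_int, ar_male = ar_male, ar_slope = ar_slope,
    ar_var = ar_var, init_intercept = init_int, init_male = init_male_,
    init_var = init_var, var_floor = var_floor
  )
}

# Randomized initialization (draws come from the caller's RNG state, which
# em_fit seeds per restart). Observations are clustered by k-means on
# standardized (age, sex-adjusted weight), so initial states are localized
# in the age-weight plane - the structure this model family is built to
# find. Cluster labels are then treated as a hard state assignment and
# pushed through the closed-form M-step (transition counts, first-visit
# frequencies, per-cluster weight regressions), with mild smoothing so no
# probability starts at zero. k-means' own random starts provide the
# restart-to-restart diversity.
init_params <- function(stack, n_states, var_floor = 1e-3) {
  n <- n_states
  w_f <- stack$weight[stack$male == 0]
  w_m <- stack$weight[stack$male == 1]
  sex_gap <- if (length(w_f) && length(w_m)) mean(w_m) - mean(w_f) else 0
  w_adj <- stack$weight - sex_gap * stack$male
  # alternate clustering views across restarts: weight-only targets
  # level-separated states, joint (age, weight) targets age-structured ones
  feats <- if (stats::runif(1) < 0.5) cbind(w_adj) else
    cbind(as.numeric(scale(stack$age)), 2 * as.numeric(scale(w_adj)))
  z <- tryCatch(
    stats::kmeans(feats, centers = n, nstart = 5, iter.max = 30)$cluster,
    error = function(e) sample.int(n, stack$n_obs, replace = TRUE)
  )
  # jitter a small random fraction of labels for extra restart diversity
  flip <- stats::runif(stack$n_obs) < 0.02
  if (n > 1 && any(flip)) {
    z[flip] <- sample.int(n, sum(flip), replace = TRUE)
  }
  G <- matrix(0.05 / max(n - 1, 1), stack$n_obs, n)
  G[cbind(seq_len(stack$n_obs), z)] <- if (n == 1) 1 else 0.95
  xi_sum <- matrix(0.5, n, n)
  for (s in seq_len(stack$n_seq)) {
    rows <- stack$idx_start[s]:stack$idx_end[s]
    if (length(rows) > 1) {
      zt <- z[rows]
      for (t in 2:length(zt)) {
        xi_sum[zt[t - 1], zt[t]] <- xi_sum[zt[t - 1], zt[t]] + 1
      }
    }
  }
  pi_acc <- tabulate(z[stack$is_first], n) + 0.5
  design <- em_design(stack)
  p <- m_step_closed(stack, design, G, xi_sum, pi_acc, var_floor = var_floor)
  # The within-cluster AR regression is unreliable at this stage (residual
  # age-weight heterogeneity inside a cluster inflates the slope), so seed
  # the weight autoregression around the cluster weight levels with a
  # randomized moderate slope instead; EM refines it from there.
  resp <- colSums(G)
  level <- colSums(G * w_adj) / resp
  phi0 <- stats::runif(n, 0.05, 0.5)
  p$ar_slope <- phi0
  p$ar_intercept <- level * (1 - phi0)
  p$ar_male <- rep(sex_gap, n) * (1 - phi0)
  wvar <- pmax(colSums(G * (w_adj - rep(level, each = stack$n_obs))^2) / resp,
               var_floor)
  p$ar_var <- wvar
  p$init_intercept <- level
  p$init_male <- rep(sex_gap, n)
  p$init_var <- wvar
  validate_ahmm_params(p)
  p
}

#' Fit the autoregressive HMM by EM from one random start
#'
#' Alternates exact forward-backward E-steps with closed-form M-steps:
#' initial distribution and transition matrix from normalized expected
#' counts, categorical emissions from responsibility-weighted frequencies,
#' age Gaussians from weighted moments, and the per-state weight
#' autoregression (intercept, male offset, AR slope) from
#' responsibility-weighted least squares. The total log-likelihood is
#' non-decreasing across iterations (up to the configured variance and
#' probability floors). A state whose total responsibility collapses to
#' numerical zero is re-seeded from a random observation with a warning.
#'
#' @param data List of `observation_sequence` objects (see
#'   [as_observation_sequences()]).
#' @param n_states Number of hidden states.
#' @param n_iters Maximum EM iterations (default 1500).
#' @param seed RNG seed for the randomized initialization.
#' @param tol Relative early-stopping tolerance: iteration stops when
#'   `|LL_t - LL_(t-1)| < tol * |LL_t|`. Set to 0 to always run `n_iters`.
#' @param var_floor Variance floor (g^2) enforced in every M-step.
#' @param prob_floor Probability floor applied before normalization.
#' @param init Optional `ahmm_params` to start from (warm start) instead of
#'   the randomized initialization.
#' @return A list of class `ahmm_em` with `params`, `loglik`, `trace`
#'   (per-iteration log-likelihood), `n_iter`, and `seed`.
#' @export
em_fit <- function(data, n_states, n_iters = 1500, seed = 1, tol = 1e-8,
                   var_floor = 1e-3, prob_floor = 1e-12, init = NULL) {
  if (!length(data)) stopf("need at least one observation sequence")
  if (n_states < 1) stopf("n_states must be >= 1")
  stack <- build_stack(data)
  params <- if (is.null(init)) {
    with_seed(seed, init_params(stack, n_states, var_floor))
  } else {
    validate_ahmm_params(init)
    if (init$n_states != n_states) stopf("init has %d states, expected %d",
                                         init$n_states, n_states)
    init
  }
  n <- n_states
  design <- em_design(stack)
  reseed_pool <- derive_seeds(seed, 1)
  trace <- numeric(0)

  for (iter in seq_len(n_iters)) {
    E_log <- emission_matrix(stack, params)
    G <- matrix(0, stack$n_obs, n)
    xi_sum <- matrix(0, n, n)
    pi_acc <- numeric(n)
    ll <- 0
    for (s in seq_len(stack$n_seq)) {
      rows <- stack$idx_start[s]:stack$idx_end[s]
      fb <- fb_core(E_log[rows, , drop = FALSE], params$pi, params$A,
                    want_xi = "sum")
      G[rows, ] <- fb$gamma
      if (!is.null(fb$xi)) {
        xi_sum <- xi_sum + fb$xi
      }
      pi_acc <- pi_acc + fb$gamma[1, ]
      ll <- ll + fb$loglik
    }
    trace <- c(trace, ll)

    # Guard against collapsed states before taking weighted moments.
    resp <- colSums(G)
    dead <- which(resp < 1e-8)
    if (length(dead)) {
      params <- with_seed(reseed_pool + iter, {
        p <- params
        for (i in dead) {
          j <- sample.int(stack$n_obs, 1)
          p$age_mean[i] <- stack$age[j]
          p$age_var[i] <- max(stats::var(stack$age), var_floor)
          p$ar_slope[i] <- 0.8
          p$ar_intercept[i] <- stack$weight[j] * 0.2
          p$ar_male[i] <- 0
          p$ar_var[i] <- max(stats::var(stack$weight), var_floor)
          p$init_intercept[i] <- stack$weight[j]
          p$init_male[i] <- 0
          p$init_var[i] <- max(stats::var(design$y0), var_floor)
          p$sex_probs[i, ] <- 0.5
          p$geno_probs[i, ] <- 1 / 3
        }
        p
      })
      warnf("iteration %d: re-seeded %d collapsed state(s)", iter, length(dead))
      next
    }

    params <- m_step_closed(stack, design, G, xi_sum, pi_acc,
                            var_floor = var_floor, prob_floor = prob_floor)

    if (tol > 0 && iter >= 2) {
      d <- abs(trace[iter] - trace[iter - 1])
      if (d < tol * abs(trace[iter])) break
    }
  }

  structure(
    list(params = params, loglik = trace[length(trace)], trace = trace,
         n_iter = length(trace), seed = seed),
    class = "ahmm_em"
  )
}

#' Fit the model with multiple random EM restarts
#'
#' Runs `n_restarts` independent EM fits from seeds derived from
#' `master_seed` and keeps the fit with the largest final log-likelihood.
#' The selected model's states are then canonically relabeled (sorted by
#' stationary weight level, see [canonical_relabel()]) so labels are stable
#' across restarts and platforms.
#'
#' @param data List of `observation_sequence` objects.
#' @param n_states Number of hidden states (default 10).
#' @param n_iters Maximum EM iterations per restart (default 1500).
#' @param n_restarts Number of independent restarts (default 10).
#' @param master_seed Master seed governing every restart.
#' @param ... Passed to [em_fit()] (`tol`, `var_floor`, `prob_floor`).
#' @return An object of class `ahmm_fit`: `params` (relabeled best
#'   parameters), `restarts` (data frame of per-restart seed, final
#'   log-likelihood, iterations), `traces` (list of per-restart
#'   log-likelihood traces), `best_restart`, `label_map` (original fitted
#'   state index -> canonical position), and `master_seed`.
#' @export
fit_with_restarts <- function(data, n_states = 10, n_iters = 1500,
                              n_restarts = 10, master_seed = 1, ...) {
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  seeds <- derive_seeds(master_seed, n_restarts)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    fits[[r]] <- tryCatch(
      em_fit(data, n_states = n_states, n_iters = n_iters, seed = seeds[r], ...),
      error = function(e) {
        warnf("restart %d failed: %s", r, conditionMessage(e))
        NULL
      }
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stopf("all %d EM restarts failed", n_restarts)
  lls <- vapply(fits, function(f) if (is.null(f)) -Inf else f$loglik, numeric(1))
  best <- which.max(lls)
  rl <- canonical_relabel(fits[[best]]$params)
  structure(
    list(
      params = rl$params,
      restarts = data.frame(
        restart = seq_len(n_restarts), seed = seeds,
        loglik = lls, n_iter = vapply(fits, function(f) {
          if (is.null(f)) NA_integer_ else f$n_iter
        }, integer(1)),
        converged = ok
      ),
      traces = lapply(fits, function(f) if (is.null(f)) numeric(0) else f$trace),
      best_restart = best,
      label_map = stats::setNames(rl$params$state_labels[rl$map],
                                  paste0("fitted_", seq_len(n_states))),
      n_states = n_states,
      master_seed = master_seed
    ),
    class = "ahmm_fit"
  )
}

#' @export
print.ahmm_fit <- function(x, ...) {
  cat(sprintf("Autoregressive HMM fit: %d states, %d restart(s), best restart %d\n",
              x$n_states, nrow(x$restarts), x$best_restart))
  cat(sprintf("Best log-likelihood: %.3f\n", max(x$restarts$loglik)))
  print(x$params)
  invisible(x)
}

#' Serialize a fitted model (parameters, restart traces, seeds) to JSON
#'
#' @param fit An `ahmm_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
ahmm_fit_to_json <- function(fit, path) {
  x <- list(
    n_states = fit$n_states,
    master_seed = fit$master_seed,
    best_restart = fit$best_restart,
    label_map = as.list(fit$label_map),
    restarts = fit$restarts,
    traces = fit$traces,
    params = jsonlite::fromJSON(jsonlite::toJSON(
      unclass(fit$params), auto_unbox = TRUE, digits = NA))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
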