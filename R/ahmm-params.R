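#' Construct the parameter set of the autoregressive hidden Markov model
#'
#' The model assumes each mouse's visit sequence is governed by a latent
#' Markov chain over `N` hidden states. Conditional on the state at a visit,
#' the observations factorize as
#' \deqn{Normal(age; \mu_i, \sigma^2_i) \times Cat(sex) \times Cat(genotype)
#'       \times Normal(weight; \alpha_i + \delta_i [male] + \phi_i w_{prev},
#'       \sigma^2_{w,i}),}
#' i.e. age is a per-state Gaussian, sex and genotype are per-state
#' categoricals re-emitted at every visit, and weight follows a per-state
#' first-order autoregression on the previous measured weight with a
#' state-specific male intercept offset (the sex-weight interaction). The
#' first visit of a sequence, which has no autoregressive predecessor, uses a
#' separate per-state Gaussian with its own intercept, male offset, and
#' variance.
#'
#' @param pi Initial state distribution (length `N`, sums to 1).
#' @param A `N x N` row-stochastic transition matrix; `A[i, j]` is the
#'   probability of moving from state `i` to state `j` between consecutive
#'   measurements.
#' @param age_mean,age_var Per-state Gaussian parameters for age (months).
#' @param sex_probs `N x 2` matrix of per-state sex probabilities
#'   (columns `female`, `male`); rows sum to 1.
#' @param geno_probs `N x 3` matrix of per-state APOE genotype probabilities
#'   (columns `E3/3`, `E3/4`, `E4/4`); rows sum to 1.
#' @param ar_intercept,ar_male,ar_slope,ar_var Per-state weight
#'   autoregression: intercept (g), male offset (g), AR(1) slope, and
#'   innovation variance (g^2).
#' @param init_intercept,init_male,init_var Per-state first-visit weight
#'   Gaussian: intercept (g), male offset (g), variance (g^2).
#' @param state_labels Optional state labels; defaults to `LETTERS[1:N]`.
#' @param var_floor Lower bound enforced on all variances (g^2 or months^2).
#'
#' @return An object of class `ahmm_params`.
#' @export
ahmm_params <- function(pi, A, age_mean, age_var, sex_probs, geno_probs,
                        ar_intercept, ar_male, ar_slope, ar_var,
                        init_intercept, init_male, init_var,
                        state_labels = NULL, var_floor = 1e-3) {
  n <- length(pi)
  A <- as.matrix(A)
  sex_probs <- matrix(sex_probs, nrow = n, ncol = 2,
                      dimnames = list(NULL, SEX_LEVELS))
  geno_probs <- matrix(geno_probs, nrow = n, ncol = 3,
                       dimnames = list(NULL, GENO_LEVELS))
  labels <- state_labels %||%
    (if (n <= 26) LETTERS[seq_len(n)] else sprintf("S%02d", seq_len(n)))
  p <- structure(
    list(
      n_states = n, pi = as.numeric(pi), A = A,
      age_mean = as.numeric(age_mean), age_var = as.numeric(age_var),
      sex_probs = sex_probs, geno_probs = geno_probs,
      ar_intercept = as.numeric(ar_intercept),
      ar_male = as.numeric(ar_male),
      ar_slope = as.numeric(ar_slope),
      ar_var = as.numeric(ar_var),
      init_intercept = as.numeric(init_intercept),
      init_male = as.numeric(init_male),
      init_var = as.numeric(init_var),
      state_labels = as.character(labels),
      var_floor = var_floor
    ),
    class = "ahmm_params"
  )
  validate_ahmm_params(p)
  p
}

#' Validate an `ahmm_params` object
#'
#' Checks probability normalization (initial distribution, transition rows,
#' categorical emission rows), variance floors, and consistent dimensions.
#'
#' @param params An `ahmm_params` object.
#' @param tol Tolerance for probability sums.
#' @return `params`, invisibly; errors name the violated field.
#' @export
validate_ahmm_params <- function(params, tol = 1e-8) {
  n <- params$n_states
  if (n < 1) stopf("n_states must be >= 1")
  check_prob_vector(params$pi, "pi", tol)
  if (length(params$pi) != n) stopf("pi must have length n_states")
  check_stochastic_matrix(params$A, "A", tol)
  if (nrow(params$A) != n) stopf("A must be n_states x n_states")
  for (fld in c("age_mean", "age_var", "ar_intercept", "ar_male", "ar_slope",
                "ar_var", "init_intercept", "init_male", "init_var")) {
    v <- params[[fld]]
    if (length(v) != n || any(!is.finite(v))) {
      stopf("'%s' must be a finite vector of length n_states", fld)
    }
  }
  for (fld in c("age_var", "ar_var", "init_var")) {
    if (any(params[[fld]] < params$var_floor - 1e-12)) {
      stopf("'%s' contains a variance below the floor %g", fld, params$var_floor)
    }
  }
  for (i in seq_len(n)) {
    check_prob_vector(params$sex_probs[i, ], sprintf("sex_probs[%d,]", i), tol)
    check_prob_vector(params$geno_probs[i, ], sprintf("geno_probs[%d,]", i), tol)
  }
  if (length(params$state_labels) != n) {
    stopf("state_labels must have length n_states")
  }
  invisible(params)
}

#' Reorder states into canonical label order
#'
#' HMM likelihoods are invariant under state relabeling, so fitted state
#' indices are arbitrary. For stable naming across restarts, states are
#' sorted by their fitted stationary weight level, `alpha / (1 - phi)` when
#' `|phi| < 1` and `alpha` otherwise, ascending, and labeled `A`, `B`, ...
#'
#' @param params An `ahmm_params` object.
#' @return A list with `params` (relabeled) and `map`, an integer vector
#'   giving, for each original state index, its new position.
#' @export
canonical_relabel <- function(params, tol = 1e-8) {
  validate_ahmm_params(params, tol)
  phi <- params$ar_slope
  level <- ifelse(abs(phi) < 1, params$ar_intercept / (1 - phi),
                  params$ar_intercept)
  ord <- order(level, params$ar_intercept, seq_len(params$n_states))
  out <- params
  out$pi <- params$pi[ord]
  out$A <- params$A[ord, ord, drop = FALSE]
  for (fld in c("age_mean", "age_var", "ar_intercept", "ar_male", "ar_slope",
                "ar_var", "init_intercept", "init_male", "init_var")) {
    out[[fld]] <- params[[fld]][ord]
  }
  out$sex_probs <- params$sex_probs[ord, , drop = FALSE]
  out$geno_probs <- params$geno_probs[ord, , drop = FALSE]
  map <- match(seq_len(params$n_states), ord)
  list(params = out, map = map)
}

#' @export
print.ahmm_params <- function(x, ...) {
  cat(sprintf("Autoregressive HMM parameters: %d states (%s)\n",
              x$n_states, paste(x$state_labels, collapse = ", ")))
  lvl <- ifelse(abs(x$ar_slope) < 1, x$ar_intercept / (1 - x$ar_slope),
                x$ar_intercept)
  cat("Stationary weight level (female, g):",
      paste(sprintf("%.1f", lvl), collapse = ", "), "\n")
  cat("Transition diagonal:",
      paste(sprintf("%.2f", diag(x$A)), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize fitted model parameters to JSON
#'
#' @param params An `ahmm_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
ahmm_params_to_json <- function(params, path) {
  validate_ahmm_params(params)
  x <- unclass(params)
  x$A <- unname(apply(params$A, 1, function(r) r, simplify = FALSE))
  x$sex_probs <- unname(apply(params$sex_probs, 1, function(r) r, simplify = FALSE))
  x$geno_probs <- unname(apply(params$geno_probs, 1, function(r) r, simplify = FALSE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read model parameters from a JSON file written by [ahmm_params_to_json()]
#'
#' @param path JSON file path.
#' @return An `ahmm_params` object.
#' @export
ahmm_params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ahmm_params(
    pi = x$pi, A = as.matrix(x$A),
    age_mean = x$age_mean, age_var = x$age_var,
    sex_probs = as.matrix(x$sex_probs), geno_probs = as.matrix(x$geno_probs),
    ar_intercept = x$ar_intercept, ar_male = x$ar_male,
    ar_slope = x$ar_slope, ar_var = x$ar_var,
    init_intercept = x$init_intercept, init_male = x$init_male,
    init_var = x$init_var, state_labels = x$state_labels,
    var_floor = x$var_floor
  )
}

#' Export a transition matrix as CSV
#'
#' Writes the row-stochastic transition matrix with state labels as row and
#' column names, one row per origin state.
#'
#' @param params An `ahmm_params` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(params, path) {
  A <- params$A
  dimnames(A) <- list(params$state_labels, params$state_labels)
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  invisible(path)
}
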