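#' Per-state emission log-density of one observation
#'
#' Log of the product of the four conditional emission factors given hidden
#' state `state`: the age Gaussian, the sex and genotype categoricals, and
#' the weight density. When `prev_weight` is supplied the weight factor is
#' the AR(1) Gaussian `Normal(alpha_i + delta_i [male] + phi_i w_prev,
#' sigma^2_w,i)`; when it is `NULL` (first visit of a sequence) the separate
#' first-visit Gaussian is used. Zero-probability categorical components
#' (log 0) are clamped at the sentinel `-1e10` so downstream inference
#' treats the observation as effectively impossible without producing `NaN`
#' arithmetic.
#'
#' @param params An `ahmm_params` object.
#' @param state State index in `1..n_states`.
#' @param age Age at the visit, months.
#' @param weight Weight at the visit, grams.
#' @param sex `"female"` or `"male"`.
#' @param genotype `"E3/3"`, `"E3/4"`, or `"E4/4"`.
#' @param prev_weight Previous measured weight in grams, or `NULL` for the
#'   first visit.
#' @return Scalar log-density (finite; never below `-1e10` per factor).
#' @export
emission_logdensity <- function(params, state, age, weight, sex, genotype,
                                prev_weight = NULL) {
  validate_ahmm_params(params)
  i <- as.integer(state)
  if (i < 1 || i > params$n_states) stopf("invalid state index %d", i)
  if (!is.finite(age) || !is.finite(weight)) stopf("age and weight must be finite")
  s <- match_sex(sex)
  g <- match_genotype(genotype)
  male <- as.numeric(s == 2L)
  lp_age <- stats::dnorm(age, params$age_mean[i], sqrt(params$age_var[i]), log = TRUE)
  lp_sex <- log(params$sex_probs[i, s])
  lp_gen <- log(params$geno_probs[i, g])
  if (is.null(prev_weight)) {
    mu <- params$init_intercept[i] + params$init_male[i] * male
    lp_w <- stats::dnorm(weight, mu, sqrt(params$init_var[i]), log = TRUE)
  } else {
    if (!is.finite(prev_weight)) stopf("prev_weight must be finite")
    mu <- params$ar_intercept[i] + params$ar_male[i] * male +
      params$ar_slope[i] * prev_weight
    lp_w <- stats::dnorm(weight, mu, sqrt(params$ar_var[i]), log = TRUE)
  }
  max(sum(pmax(c(lp_age, lp_sex, lp_gen, lp_w), LOG_ZERO)), LOG_ZERO)
}

# Vectorized emission log-density matrix (n_obs x n_states) over a stack.
emission_matrix <- function(stack, params) {
  n <- params$n_states
  out <- matrix(0, nrow = stack$n_obs, ncol = n)
  age_sd <- sqrt(params$age_var)
  ar_sd <- sqrt(params$ar_var)
  init_sd <- sqrt(params$init_var)
  first <- stack$is_first
  for (i in seq_len(n)) {
    lp <- stats::dnorm(stack$age, params$age_mean[i], age_sd[i], log = TRUE)
    lp <- lp + pmax(log(params$sex_probs[i, ])[stack$sex_idx], LOG_ZERO)
    lp <- lp + pmax(log(params$geno_probs[i, ])[stack$geno_idx], LOG_ZERO)
    mu <- ifelse(first,
                 params$init_intercept[i] + params$init_male[i] * stack$male,
                 params$ar_intercept[i] + params$ar_male[i] * stack$male +
                   params$ar_slope[i] * stack$prev_weight)
    sd_w <- ifelse(first, init_sd[i], ar_sd[i])
    lp <- lp + stats::dnorm(stack$weight, mu, sd_w, log = TRUE)
    out[, i] <- pmax(lp, LOG_ZERO)
  }
  out
}
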