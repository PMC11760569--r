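test_that("emission log-density matches its closed form and components", {
  p <- ahmm_params(
    pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
    age_mean = c(0, 10), age_var = c(1, 4),
    sex_probs = matrix(0.5, 2, 2), geno_probs = matrix(1 / 3, 2, 3),
    ar_intercept = c(0, 5), ar_male = c(0, 1), ar_slope = c(0.5, 0.8),
    ar_var = c(1, 2), init_intercept = c(0, 25), init_male = c(0, 3),
    init_var = c(1, 2)
  )
  # all Gaussians at their means with unit variances, uniform categoricals
  got <- emission_logdensity(p, 1, age = 0, weight = 0, sex = "female",
                             genotype = "E3/3", prev_weight = 0)
  expect_equal(got, log(1 / (2 * pi)) + log(1 / 2) + log(1 / 3),
               tolerance = 1e-12)

  # component-wise oracle on random inputs
  set.seed(1)
  for (i in 1:20) {
    pr <- random_params(3)
    age <- runif(1, 0, 30)
    w <- runif(1, 10, 50)
    pw <- runif(1, 10, 50)
    st <- sample(3, 1)
    sx <- sample(c("female", "male"), 1)
    gn <- sample(c("E3/3", "E3/4", "E4/4"), 1)
    male <- as.numeric(sx == "male")
    expected <- unname(
      dnorm(age, pr$age_mean[st], sqrt(pr$age_var[st]), log = TRUE) +
      log(pr$sex_probs[st, sx]) + log(pr$geno_probs[st, gn]) +
      dnorm(w, pr$ar_intercept[st] + pr$ar_male[st] * male +
              pr$ar_slope[st] * pw, sqrt(pr$ar_var[st]), log = TRUE))
    expect_equal(emission_logdensity(pr, st, age, w, sx, gn, pw), expected,
                 tolerance = 1e-12)
  }
})

test_that("a zero-probability category hits the documented sentinel", {
  p <- random_params(2, seed = 3)
  p$sex_probs[1, ] <- c(1, 0)
  got <- emission_logdensity(p, 1, age = 10, weight = 25, sex = "male",
                             genotype = "E3/3", prev_weight = 24)
  expect_true(is.finite(got))
  expect_lte(got, -1e10 + 100)
})

test_that("single-state inference is deterministic and additive", {
  p <- random_params(1, seed = 5)
  s <- random_seq(6, seed = 6)
  fb <- forward_backward(s, p)
  expect_equal(as.numeric(fb$gamma), rep(1, 6))
  direct <- emission_logdensity(p, 1, s$age[1], s$weight[1], s$sex, s$genotype) +
    sum(vapply(2:6, function(t) {
      emission_logdensity(p, 1, s$age[t], s$weight[t], s$sex, s$genotype,
                          s$weight[t - 1])
    }, numeric(1)))
  expect_equal(fb$loglik, direct, tolerance = 1e-10)
  expect_identical(viterbi(s, p), rep(1L, 6))
})

test_that("identical emissions and symmetric dynamics give uniform posteriors", {
  p1 <- random_params(1, seed = 8)
  p <- ahmm_params(
    pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
    age_mean = rep(p1$age_mean, 2), age_var = rep(p1$age_var, 2),
    sex_probs = matrix(0.5, 2, 2), geno_probs = matrix(1 / 3, 2, 3),
    ar_intercept = rep(p1$ar_intercept, 2), ar_male = rep(p1$ar_male, 2),
    ar_slope = rep(p1$ar_slope, 2), ar_var = rep(p1$ar_var, 2),
    init_intercept = rep(p1$init_intercept, 2),
    init_male = rep(p1$init_male, 2), init_var = rep(p1$init_var, 2)
  )
  s <- random_seq(5, seed = 9)
  fb <- forward_backward(s, p)
  expect_equal(as.numeric(fb$gamma), rep(0.5, 10), tolerance = 1e-12)
})

test_that("posteriors, likelihood, and Viterbi match exhaustive enumeration", {
  set.seed(11)
  for (case in 1:25) {
    n <- sample(2:3, 1)
    k <- sample(3:5, 1)
    p <- random_params(n)
    s <- random_seq(k)
    fb <- forward_backward(s, p)
    en <- enum_inference(s, p)
    expect_equal(fb$loglik, en$loglik, tolerance = 1e-10)
    expect_equal(fb$gamma, en$gamma, tolerance = 1e-10)
    expect_equal(viterbi(s, p), en$map_path)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-10))
    if (!is.null(fb$xi)) {
      sums <- apply(fb$xi, 1, sum)
      expect_true(all(abs(sums - 1) < 1e-10))
    }
  }
})

test_that("cohort log-likelihood is the sum over independent sequences", {
  p <- random_params(3, seed = 13)
  seqs <- lapply(1:6, function(i) random_seq(sample(3:8, 1), id = paste0("m", i)))
  total <- cohort_loglik(seqs, p)
  per_seq <- vapply(seqs, function(s) forward_backward(s, p)$loglik, numeric(1))
  expect_equal(total, sum(per_seq), tolerance = 1e-10)
})

test_that("one-state EM reduces to weighted least squares on the AR design", {
  set.seed(17)
  seqs <- lapply(1:20, function(i) {
    k <- sample(4:8, 1)
    sx <- sample(c("female", "male"), 1)
    w <- cumsum(c(runif(1, 20, 30), rnorm(k - 1, 0.3, 0.8)))
    observation_sequence(paste0("m", i), sx,
                         sample(c("E3/3", "E3/4", "E4/4"), 1),
                         age = sort(runif(k, 5, 28)), weight = abs(w) + 5)
  })
  fit <- em_fit(seqs, n_states = 1, n_iters = 5, seed = 1)
  # oracle: ordinary least squares of weight on (1, male, prev_weight)
  df <- do.call(rbind, lapply(seqs, function(s) {
    k <- length(s$weight)
    data.frame(y = s$weight[-1], male = as.numeric(s$sex == "male"),
               prev = s$weight[-k])
  }))
  ols <- lm(y ~ male + prev, data = df)
  expect_equal(unname(fit$params$ar_intercept), unname(coef(ols)[1]),
               tolerance = 1e-6)
  expect_equal(unname(fit$params$ar_male), unname(coef(ols)[2]),
               tolerance = 1e-6)
  expect_equal(unname(fit$params$ar_slope), unname(coef(ols)[3]),
               tolerance = 1e-6)
  expect_equal(fit$params$A, matrix(1, 1, 1))
})

test_that("EM log-likelihood never decreases along the trace", {
  set.seed(19)
  for (trial in 1:4) {
    cfg <- progression_colony_config(n_mice = 40, seed = 600 + trial)
    ch <- simulate_cohort(cfg)
    fit <- suppressWarnings(em_fit(ch$seqs, n_states = 3, n_iters = 25,
                                   seed = trial, tol = 0))
    dips <- diff(fit$trace)
    expect_true(all(dips >= -1e-6 * abs(fit$trace[-1])),
                info = sprintf("trial %d min dip %.3g", trial, min(dips)))
  }
})

test_that("restart protocol is deterministic and selects the best likelihood", {
  cfg <- progression_colony_config(n_mice = 40, seed = 71)
  ch <- simulate_cohort(cfg)
  f1 <- suppressWarnings(fit_with_restarts(ch$seqs, n_states = 2, n_iters = 15,
                                           n_restarts = 3, master_seed = 42))
  f2 <- suppressWarnings(fit_with_restarts(ch$seqs, n_states = 2, n_iters = 15,
                                           n_restarts = 3, master_seed = 42))
  expect_equal(f1$params, f2$params)
  expect_identical(f1$restarts$seed, f2$restarts$seed)
  expect_gte(min(f1$restarts$loglik[f1$best_restart] - f1$restarts$loglik), 0)

  single <- suppressWarnings(em_fit(ch$seqs, n_states = 2, n_iters = 15,
                                    seed = f1$restarts$seed[1]))
  one <- suppressWarnings(fit_with_restarts(ch$seqs, n_states = 2, n_iters = 15,
                                            n_restarts = 1, master_seed = 42))
  expect_equal(one$restarts$loglik[1], single$loglik, tolerance = 1e-9)
})

test_that("canonical relabeling preserves the likelihood", {
  p <- random_params(3, seed = 23)
  seqs <- lapply(1:4, function(i) random_seq(5, id = paste0("m", i)))
  rl <- canonical_relabel(p)
  expect_equal(cohort_loglik(seqs, p), cohort_loglik(seqs, rl$params),
               tolerance = 1e-9)
  lvl <- rl$params$ar_intercept / (1 - rl$params$ar_slope)
  expect_true(all(diff(lvl) > 0))
})

test_that("fit serialization and parameter JSON round-trip", {
  cfg <- progression_colony_config(n_mice = 30, seed = 81)
  ch <- simulate_cohort(cfg)
  fit <- suppressWarnings(fit_with_restarts(ch$seqs, n_states = 2, n_iters = 10,
                                            n_restarts = 2, master_seed = 7))
  js <- withr::local_tempfile(fileext = ".json")
  ahmm_fit_to_json(fit, js)
  expect_true(file.exists(js))
  pj <- withr::local_tempfile(fileext = ".json")
  ahmm_params_to_json(fit$params, pj)
  back <- ahmm_params_from_json(pj)
  expect_equal(back$A, fit$params$A, tolerance = 1e-12)
  expect_equal(back$ar_slope, fit$params$ar_slope, tolerance = 1e-12)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(fit$params, csv)
  A_back <- as.matrix(utils::read.csv(csv, row.names = 1))
  expect_equal(unname(A_back), unname(fit$params$A), tolerance = 1e-12)
})
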