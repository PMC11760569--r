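test_that("configuration validation names the violated field", {
  expect_error(colony_config(n_mice = 0), "n_mice")
  expect_error(colony_config(sex_probs = c(female = 0.7, male = 0.7)),
               "sex_probs")
  expect_error(colony_config(visit_window = c(min = 10, max = 8)),
               "visit_window")
  expect_error(colony_config(missing_visit_prob = 1.5), "missing_visit_prob")
  bad_arch <- default_archetypes()
  bad_arch$weight_sd[2] <- 0
  expect_error(colony_config(state_archetypes = bad_arch), "weight_sd")
})

test_that("a single archetype with no growth chain forces self-transition", {
  cfg <- colony_config(
    n_mice = 5, state_archetypes = default_archetypes()[4, ],
    young_chain = NULL,
    branch_by_genotype = matrix(1, 3, 1),
    init_by_genotype = matrix(1, 3, 1), seed = 1
  )
  p <- generate_true_params(cfg)
  expect_identical(dim(p$A), c(1L, 1L))
  expect_equal(p$A[1, 1], 1.0)
})

test_that("true parameters are valid, row-stochastic, and deterministic", {
  cfg <- colony_config(n_mice = 10, seed = 7)
  p1 <- generate_true_params(cfg)
  p2 <- generate_true_params(cfg)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1$A), rep(1, p1$n_states), tolerance = 1e-12)
  expect_equal(sum(p1$pi), 1, tolerance = 1e-12)
  expect_s3_class(validate_ahmm_params(p1), "ahmm_params")
})

test_that("identical seeds reproduce identical colonies", {
  cfg <- colony_config(n_mice = 40, seed = 99)
  s1 <- simulate_colony(generate_true_params(cfg), cfg)
  s2 <- simulate_colony(generate_true_params(cfg), cfg)
  expect_identical(s1$colony, s2$colony)
  expect_identical(s1$truth$path, s2$truth$path)
  cfg2 <- colony_config(n_mice = 40, seed = 100)
  s3 <- simulate_colony(generate_true_params(cfg2), cfg2)
  expect_false(identical(s1$colony$weight_g, s3$colony$weight_g))
})

test_that("colony table and ground truth align row for row", {
  cfg <- colony_config(n_mice = 60, seed = 3)
  sim <- simulate_colony(generate_true_params(cfg), cfg)
  expect_equal(nrow(sim$colony), nrow(sim$truth$path))
  expect_identical(sim$colony$mouse_id, sim$truth$path$mouse_id)
  expect_equal(sim$colony$age_months, sim$truth$path$age_months)
  expect_equal(sim$colony$weight_g, sim$truth$path$weight_g)
  # ages strictly increasing and weights positive within each mouse
  by_mouse <- split(sim$colony$age_months, sim$colony$mouse_id)
  expect_true(all(vapply(by_mouse, function(a) all(diff(a) > 0), logical(1))))
  expect_true(all(sim$colony$weight_g > 0))
  # terminal state equals last path element per mouse
  last_states <- vapply(split(sim$truth$path$state, sim$truth$path$mouse_id),
                        function(s) s[length(s)], character(1))
  expect_identical(unname(last_states[sim$truth$terminal$mouse_id]),
                   sim$truth$terminal$state)
})

test_that("empirical sex fraction is within 3 SD of the binomial expectation", {
  cfg <- colony_config(n_mice = 500, seed = 11)
  sim <- simulate_colony(generate_true_params(cfg), cfg)
  first <- sim$colony[!duplicated(sim$colony$mouse_id), ]
  n_female <- sum(first$sex == "female")
  expect_lt(abs(n_female - 500 * 0.45), 3 * sqrt(500 * 0.45 * 0.55))
})

test_that("total missingness beyond the third visit leaves exactly 3 visits", {
  arch <- default_archetypes()
  arch$hazard <- 0
  yc <- young_chain_config(hazard = 0)
  cfg <- colony_config(n_mice = 30, state_archetypes = arch, young_chain = yc,
                       missing_visit_prob = 1, sacrifice_prob = 0, seed = 5)
  sim <- simulate_colony(generate_true_params(cfg), cfg)
  expect_true(all(table(sim$colony$mouse_id) == 3))
  # zero hazard: nobody dies, everyone censored alive
  expect_true(all(sim$truth$death$status == "alive"))
  expect_true(all(is.na(sim$truth$death$death_age)))
})

test_that("zero biomarker noise reproduces the archetype means exactly", {
  arch <- default_archetypes()
  arch$biomarker_sd <- 0
  arch$hazard <- 0
  cfg <- colony_config(n_mice = 80, state_archetypes = arch,
                       young_chain = young_chain_config(hazard = 0),
                       sacrifice_prob = 0, seed = 13)
  sim <- simulate_colony(generate_true_params(cfg), cfg)
  ph <- simulate_posthoc_measures(sim$truth, cfg)
  skip_if(nrow(ph$biomarkers) == 0)
  idx <- match(ph$biomarkers$true_state,
               tail(sim$truth$params$state_labels, cfg$k_arch))
  expect_equal(ph$biomarkers$abeta40, arch$biomarker_mean[idx], tolerance = 1e-12)
  expect_equal(ph$biomarkers$abeta42, 0.6 * arch$biomarker_mean[idx],
               tolerance = 1e-12)
  expect_true(all(ph$composition$fat >= 0))
  expect_true(all(ph$composition$lean >= 0))
  expect_true(all(ph$composition$free_water >= 0))
})

test_that("an age window with no visits yields empty tables with a warning", {
  cfg <- colony_config(n_mice = 20, seed = 2)
  sim <- simulate_colony(generate_true_params(cfg), cfg)
  expect_warning(
    ph <- simulate_posthoc_measures(sim$truth, cfg, age_window = c(40, 41)),
    "age window"
  )
  expect_identical(nrow(ph$biomarkers), 0L)
  expect_identical(nrow(ph$composition), 0L)
})

test_that("state-separated biomarkers give a powered Welch comparison", {
  # two archetypes with means 50 and 100 (sd 5): the t-test on
  # truth-labeled groups must reject at alpha = 0.01 in almost every
  # simulated colony
  arch <- default_archetypes()[c(4, 5), ]
  arch$biomarker_mean <- c(50, 100)
  arch$biomarker_sd <- 5
  arch$hazard <- 0
  rejections <- vapply(1:60, function(s) {
    cfg <- colony_config(
      n_mice = 70, state_archetypes = arch,
      young_chain = young_chain_config(n = 2, age_hi = 9, hazard = 0),
      branch_by_genotype = matrix(0.5, 3, 2),
      sacrifice_prob = 0, seed = 8000 + s
    )
    sim <- simulate_colony(generate_true_params(cfg), cfg)
    ph <- simulate_posthoc_measures(sim$truth, cfg)
    labs <- tail(sim$truth$params$state_labels, 2)
    a <- ph$biomarkers$abeta40[ph$biomarkers$true_state == labs[1]]
    b <- ph$biomarkers$abeta40[ph$biomarkers$true_state == labs[2]]
    if (length(a) < 2 || length(b) < 2) return(NA)
    welch_ttest(a, b)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rejections, na.rm = TRUE), 0.99)
})

test_that("true parameters outscore random perturbations in likelihood", {
  set.seed(42)
  wins <- 0
  trials <- 0
  for (s in 1:3) {
    cfg <- progression_colony_config(n_mice = 50, seed = 500 + s)
    ch <- simulate_cohort(cfg)
    ll_true <- cohort_loglik(ch$seqs, ch$true_params)
    for (r in 1:7) {
      p <- ch$true_params
      n <- p$n_states
      jitter_rows <- function(M) {
        M <- M * matrix(exp(rnorm(length(M), 0, 0.5)), nrow(M))
        M / rowSums(M)
      }
      p$A <- jitter_rows(p$A)
      p$pi <- as.numeric(jitter_rows(matrix(p$pi, 1)))
      p$ar_intercept <- p$ar_intercept * exp(rnorm(n, 0, 0.3))
      p$age_mean <- p$age_mean + rnorm(n, 0, 2)
      trials <- trials + 1
      wins <- wins + (ll_true > cohort_loglik(ch$seqs, p))
    }
  }
  expect_gte(wins / trials, 0.9)
})

test_that("colony CSV and ground-truth JSON round-trip through files", {
  cfg <- colony_config(n_mice = 15, seed = 4)
  sim <- simulate_colony(generate_true_params(cfg), cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_colony_csv(sim$colony, csv)
  write_ground_truth_json(sim$truth, js)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(sim$colony))
  expect_identical(back$mouse_id, sim$colony$mouse_id)
  expect_equal(back$weight_g, sim$colony$weight_g, tolerance = 1e-9)
  truth_back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(truth_back$path), nrow(sim$truth$path))
})
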