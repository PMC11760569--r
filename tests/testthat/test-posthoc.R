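test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  # no censoring: empirical survival
  km <- km_estimate(c(10, 20, 30), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # all censored: flat curve with warning
  expect_warning(km2 <- km_estimate(c(5, 8), c(0, 0)), "censored")
  expect_equal(km2$surv, c(1, 1))
  # mixed toy set, hand-computed:
  # t=4 (d=1, n=5): S=4/5; t=6 censored; t=9 (d=1, n=3): S=8/15;
  # t=11 censored; t=13 (d=1, n=1): S=0
  km3 <- km_estimate(c(4, 6, 9, 11, 13), c(1, 0, 1, 0, 1))
  expect_equal(km3$surv, c(4 / 5, 4 / 5, 8 / 15, 8 / 15, 0), tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 0))
  expect_equal(km3$n_risk, c(5, 4, 3, 2, 1))
})

test_that("median survival scans the curve for S <= 0.5", {
  km <- km_estimate(c(10, 20, 24, 30), c(1, 1, 1, 1))
  # S = .75, .5, .25, 0 -> first time S <= 0.5 is 20
  expect_equal(median_survival(km), 20)
  high <- km_estimate(c(10, 20, 30, 40), c(1, 0, 0, 0))
  expect_true(is.na(median_survival(high)))
  # oracle: direct scan
  set.seed(2)
  for (i in 1:10) {
    t <- sort(runif(12, 1, 30))
    e <- rbinom(12, 1, 0.7)
    km <- km_estimate(t, e)
    hit <- km$time[km$surv <= 0.5]
    expect_identical(median_survival(km),
                     if (length(hit)) hit[1] else NA_real_)
  }
})

test_that("log-rank test matches hand computation and degenerate cases", {
  # identical groups: statistic 0, p = 1
  rec <- data.frame(time = c(5, 10, 5, 10), event = 1,
                    group = c("a", "a", "b", "b"))
  lr <- logrank_test(rec)
  expect_equal(lr$chisq, 0, tolerance = 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)

  # hand-computed 2-group toy: group a deaths at 1, 2; group b death at 3
  # t=1: n=4 (2a, 2b), d=1 in a: E_a = 1/2, V = (2*2*1*3)/(16*3) = 1/4
  # t=2: n=3 (1a, 2b), d=1 in a: E_a = 1/3, V = (1*2*1*2)/(9*2) = 2/9
  # t=3: n=2 (0a, 2b), d=1 in b: E_a = 0,  V = 0
  # O_a - E_a = 2 - 5/6 = 7/6; chisq = (7/6)^2 / (1/4 + 2/9) = 2.882353
  rec2 <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                     group = c("a", "a", "b", "b"))
  lr2 <- logrank_test(rec2)
  expect_equal(lr2$chisq, (7 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-10)
  expect_identical(lr2$df, 1L)

  none <- data.frame(time = c(1, 2), event = 0, group = c("a", "b"))
  expect_warning(lr3 <- logrank_test(none), "no events")
  expect_true(is.na(lr3$chisq))
})

test_that("KM and log-rank agree with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(7)
  for (i in 1:12) {
    n <- sample(10:40, 1)
    time <- round(runif(n, 1, 30), 1)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1
    group <- sample(c("g1", "g2", "g3")[seq_len(sample(2:3, 1))], n,
                    replace = TRUE)
    if (length(unique(group)) < 2) group[1:2] <- c("g1", "g2")
    km <- km_estimate(time, event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    expect_equal(km$surv[match(sf$time, km$time)], sf$surv, tolerance = 1e-8)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
    lr <- logrank_test(data.frame(time = time, event = event, group = group))
    expect_equal(lr$chisq, unname(sd_$chisq), tolerance = 1e-8)
  }
})

test_that("survival records honor censoring and sacrifice rules", {
  birth <- as.Date("2019-01-01")
  mk <- function(id, death = as.Date(NA), cause = NA_character_) {
    structure(list(
      mouse_id = id, sex = "female", genotype = "E3/3", birth_date = birth,
      death_date = death, death_cause = cause, is_breeder = FALSE,
      records = data.frame(measurement_date = birth + c(200, 300),
                           age_months = c(200, 300) / 30.44,
                           weight_g = c(25, 26))),
      class = "mouse_series")
  }
  mice <- list(
    mk("dead", death = birth + 400, cause = "natural"),
    mk("alive"),
    mk("cut", death = birth + 350, cause = "sacrificed")
  )
  rec <- make_survival_records(mice)
  expect_setequal(rec$mouse_id, c("dead", "alive"))
  expect_equal(rec$event[rec$mouse_id == "dead"], 1L)
  expect_equal(rec$time_months[rec$mouse_id == "dead"], 400 / 30.44,
               tolerance = 1e-9)
  # censored mice contribute follow-up to the last measurement
  expect_equal(rec$event[rec$mouse_id == "alive"], 0L)
  expect_equal(rec$time_months[rec$mouse_id == "alive"], 300 / 30.44,
               tolerance = 1e-9)
  kept <- make_survival_records(mice, exclude_sacrificed = FALSE)
  expect_true("cut" %in% kept$mouse_id)
})

test_that("composition chi-square matches the Pearson formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  out <- contingency_chisq(tab)
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(out$p_value, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  same <- matrix(c(15, 15, 30, 30), 2, 2)
  out2 <- contingency_chisq(same)
  expect_equal(out2$statistic, 0, tolerance = 1e-12)
  expect_equal(out2$p_value, 1, tolerance = 1e-12)
  # empty column collapses with a warning
  tab3 <- as.table(matrix(c(5, 0, 8, 0, 4, 7), 3, 2, byrow = TRUE,
                          dimnames = list(c("g1", "g2", "g3"), c("x", "y"))))
  tab3["g2", ] <- c(8, 0)
  tab3["g1", ] <- c(5, 3)
  tab3["g3", ] <- c(4, 7)
  empty <- as.table(cbind(tab3, z = 0))
  expect_warning(out3 <- contingency_chisq(empty), "empty")
  expect_identical(dim(out3$observed), c(3L, 2L))
  # pairwise mode restricts to two groups
  pair <- contingency_chisq(as.table(tab3), pair = c("g1", "g3"))
  expect_identical(dim(pair$observed), c(2L, 2L))
})

test_that("Welch t statistic matches the textbook formula", {
  out <- welch_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(out$df, 4, tolerance = 1e-9)
  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  const <- welch_ttest(c(2, 2), c(2, 2))
  expect_equal(const$p_value, 1)
  # power on well-separated Gaussians
  set.seed(11)
  rej <- mean(replicate(300, {
    welch_ttest(rnorm(20), rnorm(20, 2))$p_value < 0.01
  }))
  expect_gte(rej, 0.95)
})

test_that("adipose index implements the body-fat formula", {
  expect_equal(adipose_index(10, 30, 0), 25)
  expect_equal(adipose_index(0, 25, 2), 0)
  set.seed(3)
  f <- runif(20, 0, 20)
  l <- runif(20, 5, 30)
  w <- runif(20, 0, 3)
  expect_equal(adipose_index(f, l, w), 100 * f / (f + l + w),
               tolerance = 1e-12)
  expect_true(all(adipose_index(f, l, w) >= 0 & adipose_index(f, l, w) <= 100))
  expect_error(adipose_index(-1, 10, 0), "non-negative")
  expect_error(adipose_index(0, 0, 0), "positive")
})

test_that("single-observation state inference follows Bayes' rule", {
  p1 <- random_params(1, seed = 41)
  out1 <- infer_state_single_obs(p1, age = 12, weight = 30, sex = "female",
                                 genotype = "E3/3")
  expect_equal(unname(out1$posterior), 1)

  # far-separated first-visit means: observation at state 1's mean dominates
  p2 <- random_params(2, seed = 42)
  p2$init_intercept <- c(20, 60)
  p2$init_male <- c(0, 0)
  p2$init_var <- c(1, 1)
  p2$age_mean <- c(12, 12)
  p2$age_var <- c(9, 9)
  p2$sex_probs <- matrix(0.5, 2, 2)
  p2$geno_probs <- matrix(1 / 3, 2, 3)
  p2$pi <- c(0.5, 0.5)
  p2$A <- matrix(0.5, 2, 2)
  out2 <- infer_state_single_obs(p2, age = 12, weight = 20, sex = "female",
                                 genotype = "E3/3")
  expect_gt(out2$posterior[[1]], 0.99)
  expect_identical(out2$state, "A")

  # Bayes-rule oracle with the stationary prior
  set.seed(43)
  for (i in 1:10) {
    p <- random_params(3)
    age <- runif(1, 5, 25)
    w <- runif(1, 15, 45)
    sx <- sample(c("female", "male"), 1)
    gn <- sample(c("E3/3", "E3/4", "E4/4"), 1)
    nu <- stationary_distribution(p$A, pi = p$pi)
    lp <- log(nu) + vapply(1:3, function(s) {
      emission_logdensity(p, s, age, w, sx, gn)
    }, numeric(1))
    expected <- exp(lp - max(lp))
    expected <- expected / sum(expected)
    got <- infer_state_single_obs(p, age, w, sx, gn)
    expect_equal(unname(got$posterior), expected, tolerance = 1e-12)
    got_init <- infer_state_single_obs(p, age, w, sx, gn,
                                       prior_mode = "initial")
    lp2 <- log(p$pi) + (lp - log(nu))
    expected2 <- exp(lp2 - max(lp2))
    expect_equal(unname(got_init$posterior), expected2 / sum(expected2),
                 tolerance = 1e-12)
  }
})

test_that("cross-sectional comparisons handle identical and sparse groups", {
  cs <- data.frame(
    measurement = "glucose",
    value = rep(5, 8),
    state = rep(c("B", "J"), each = 4)
  )
  out <- compare_cs_across_states(cs)
  expect_true(all(out$comparisons$p_value == 1))

  one_state <- data.frame(measurement = "glucose", value = rnorm(5),
                          state = c("B", "B", "B", "B", "J"))
  out2 <- compare_cs_across_states(one_state)
  expect_identical(nrow(out2$comparisons), 0L)
  expect_true("J" %in% out2$skipped$state)

  set.seed(5)
  cs3 <- data.frame(
    measurement = rep(c("glucose", "gait"), each = 30),
    value = c(rnorm(15, 5), rnorm(15, 9), rnorm(15, 1), rnorm(15, 1)),
    state = rep(rep(c("B", "F"), each = 15), 2)
  )
  out3 <- compare_cs_across_states(cs3)
  glu <- out3$comparisons[out3$comparisons$measurement == "glucose", ]
  expect_lt(glu$p_value, 0.001)
  expect_true(all(c("p_value", "p_holm") %in% names(out3$comparisons)))
  expect_gte(min(out3$comparisons$p_holm - out3$comparisons$p_value), 0)
})
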