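# Synthetic colony generation with known ground truth.
#
# Generative structure: every mouse enters the colony in a short chain of
# "young" growth states (low self-transition, so they are starting/
# intermediate states under the ending-state rule) and then branches into
# one of K persistent phenotype archetypes (high self-transition: the
# ending states). Weight follows the state's AR(1) emission, so after the
# branch it drifts from the young-adult level toward the archetype's
# stationary level, producing gain / loss / stable mean curves that
# diverge after the growth phase. Mortality and biomarker levels are
# state-dependent. This mirrors the structure such a model discovers on
# real colony data: young ages occupy transient states, old ages occupy
# weight-level-specific persistent states.

#' Default phenotype archetypes (the ending states)
#'
#' Five archetypes: three weight-loss states of increasing severity, one
#' stable state, and one weight-gain state. Columns: `name`;
#' `weight_intercept` (AR intercept alpha, g), `male_offset` (state AR male
#' intercept offset delta, g), `ar_slope` (phi), `weight_sd` (innovation
#' SD, g); `age_lo`/`age_hi` (months; the state's age-emission Gaussian is
#' centred on this occupancy window); `hazard` (deaths per month while in
#' the state); `biomarker_mean`/`biomarker_sd` (plasma biomarker level,
#' pg/mL-like units); `init_intercept`/`init_male`/`init_sd` (first-visit
#' weight Gaussian, used only when a mouse can start in the archetype);
#' `adipose_frac` (expected body-fat fraction for composition draws).
#'
#' With `phi = 0.93` the stationary female weights are 18, 21, 24, 31 and
#' 46 g; after branching at the end of the growth phase (~28 g) weights
#' drift toward these levels, giving roughly -22%, -15%, -9%, +6% and +35%
#' change from 12 months of age. The gain archetype carries the highest
#' hazard and biomarker mean, emulating the association between weight
#' gain, amyloid burden, and earlier death.
#'
#' @return A data frame with one row per archetype.
#' @export
default_archetypes <- function() {
  phi <- 0.85
  stationary <- c(16, 21, 26, 32, 45)
  data.frame(
    name = c("loss_deep", "loss_mid", "loss_mild", "stable", "gain"),
    weight_intercept = stationary * (1 - phi),
    male_offset = c(0.42, 0.42, 0.42, 0.42, 0.49),
    ar_slope = phi,
    weight_sd = c(0.8, 0.8, 0.8, 0.8, 1.0),
    age_lo = rep(9, 5),
    age_hi = rep(28, 5),
    hazard = c(0.020, 0.015, 0.010, 0.008, 0.045),
    biomarker_mean = c(35, 40, 45, 50, 90),
    biomarker_sd = c(8, 8, 8, 8, 12),
    init_intercept = stationary,
    init_male = rep(5, 5),
    init_sd = rep(2.0, 5),
    adipose_frac = c(0.10, 0.12, 0.14, 0.18, 0.36),
    stringsAsFactors = FALSE
  )
}

#' Default young growth-state chain
#'
#' The shared growth phase: `n` transient states traversed in order, each
#' with self-transition `self_prob` (kept below the 0.3 ending threshold)
#' and the remaining mass split between advancing along the chain and
#' branching early into an archetype (`early_branch` fraction). Weight
#' levels rise linearly from `level_start` to `level_end` g (female);
#' `age_lo`/`age_hi` is the age span the chain occupies.
#'
#' @param n Number of young states.
#' @param level_start,level_end Female weight level at chain start/end (g).
#' @param ar_slope,weight_sd AR(1) slope and innovation SD in young states.
#' @param male_offset Stationary male-female weight gap in young states (g).
#' @param self_prob Self-transition probability of each young state.
#' @param early_branch Fraction of each advance step that branches straight
#'   into an archetype rather than the next young state.
#' @param age_lo,age_hi Age span (months) of the growth phase.
#' @param init_level,init_male,init_sd First-visit weight Gaussian (g).
#' @param hazard Deaths per month while in the growth phase.
#' @return A list with the above fields.
#' @export
young_chain_config <- function(n = 4, level_start = 24.5, level_end = 28,
                               ar_slope = 0.5, weight_sd = 0.9,
                               male_offset = 4, self_prob = 0.22,
                               early_branch = 0.12,
                               age_lo = 6, age_hi = 11.5,
                               init_level = 24.5, init_male = 3.5,
                               init_sd = 1.8, hazard = 0.004) {
  list(n = as.integer(n), level_start = level_start, level_end = level_end,
       ar_slope = ar_slope, weight_sd = weight_sd, male_offset = male_offset,
       self_prob = self_prob, early_branch = early_branch,
       age_lo = age_lo, age_hi = age_hi, init_level = init_level,
       init_male = init_male, init_sd = init_sd, hazard = hazard)
}

#' Configuration of a synthetic colony with known ground truth
#'
#' The defaults emulate a large aging humanized-APOE colony: ~1,200 mice,
#' 45/55 female/male split, genotype mix 30% E3/3, 28% E3/4, 42% E4/4,
#' roughly monthly visits at unequal spacing from a first visit at 5-8
#' months of age up to 28 months, a shared growth phase branching into
#' five phenotype archetypes, state-dependent mortality, and
#' state-dependent biomarker means. Branching is genotype-coupled by
#' default so the gain archetype is enriched for E4/4 carriers.
#'
#' @param n_mice Number of mice.
#' @param state_archetypes Phenotype archetype table
#'   (see [default_archetypes()]).
#' @param young_chain Growth-phase chain (see [young_chain_config()]), or
#'   `NULL` for a colony whose mice start directly in the archetypes.
#' @param sex_probs Named probabilities for `female`, `male`.
#' @param genotype_probs Named probabilities for the three genotypes.
#' @param branch_by_genotype 3 x K matrix (rows `E3/3`, `E3/4`, `E4/4`):
#'   probability of branching into each archetype, per genotype. Used when
#'   `young_chain` is present and no explicit `transition_matrix` is given.
#' @param branch_sex_mult Optional 2 x K matrix (rows `female`, `male`) of
#'   multiplicative sex weights applied to the branch law (rows of the
#'   effective per-mouse branch distribution are renormalized); defaults
#'   to no sex effect. Lets archetypes differ in sex composition, as
#'   observed trajectory groups do.
#' @param transition_matrix Optional explicit row-stochastic matrix over
#'   all states (young chain first, then archetypes); overrides the built
#'   chain/branch structure and removes genotype coupling of transitions.
#' @param init_by_genotype Optional 3 x n_states start distribution per
#'   genotype. Default: all mice start in the first state (first young
#'   state, or first archetype when `young_chain` is `NULL`).
#' @param visit_spacing Named vector `mean`, `sd`: inter-visit gap in
#'   months (Gaussian, truncated below at 0.5).
#' @param visit_window Named vector `min`, `max`: age window of visits.
#' @param first_visit_range First visit age drawn uniformly in this range.
#' @param missing_visit_prob Probability a scheduled visit after the third
#'   is skipped.
#' @param sacrifice_prob Probability a mouse alive at its last visit is
#'   recorded as sacrificed (excluded from survival analysis downstream).
#' @param min_three_visit_fraction Post-simulation check: warn if fewer
#'   than this fraction of mice retain >= 3 visits.
#' @param seed Master seed; every random draw flows from it.
#' @return A validated list of class `colony_config`.
#' @export
colony_config <- function(n_mice = 1196,
                          state_archetypes = default_archetypes(),
                          young_chain = young_chain_config(),
                          sex_probs = c(female = 0.45, male = 0.55),
                          genotype_probs = c("E3/3" = 0.30, "E3/4" = 0.28,
                                             "E4/4" = 0.42),
                          branch_by_genotype = NULL,
                          branch_sex_mult = NULL,
                          transition_matrix = NULL,
                          init_by_genotype = NULL,
                          visit_spacing = c(mean = 1, sd = 0.25),
                          visit_window = c(min = 5, max = 28),
                          first_visit_range = c(5, 8),
                          missing_visit_prob = 0.1,
                          sacrifice_prob = 0.15,
                          min_three_visit_fraction = 0.8,
                          seed = 1L) {
  k_arch <- nrow(state_archetypes)
  n_young <- if (is.null(young_chain)) 0L else young_chain$n
  n_states <- n_young + k_arch
  if (is.null(branch_by_genotype)) {
    branch_by_genotype <- if (k_arch == 5) {
      # gain enriched in E4/4, losses in E3/4; E3/3 spread evenly
      rbind("E3/3" = c(0.14, 0.14, 0.14, 0.44, 0.14),
            "E3/4" = c(0.18, 0.19, 0.18, 0.37, 0.08),
            "E4/4" = c(0.11, 0.11, 0.11, 0.45, 0.22))
    } else {
      matrix(1 / k_arch, 3, k_arch, dimnames = list(GENO_LEVELS, NULL))
    }
  }
  if (is.null(branch_sex_mult)) {
    branch_sex_mult <- matrix(1, 2, k_arch, dimnames = list(SEX_LEVELS, NULL))
  }
  if (is.null(init_by_genotype)) {
    init_by_genotype <- matrix(0, 3, n_states,
                               dimnames = list(GENO_LEVELS, NULL))
    init_by_genotype[, 1] <- 1
  }
  cfg <- structure(
    list(n_mice = as.integer(n_mice), n_states = as.integer(n_states),
         n_young = as.integer(n_young), k_arch = as.integer(k_arch),
         state_archetypes = state_archetypes, young_chain = young_chain,
         sex_probs = sex_probs, genotype_probs = genotype_probs,
         branch_by_genotype = branch_by_genotype,
         branch_sex_mult = branch_sex_mult,
         transition_matrix = transition_matrix,
         init_by_genotype = init_by_genotype,
         visit_spacing = visit_spacing, visit_window = visit_window,
         first_visit_range = first_visit_range,
         missing_visit_prob = missing_visit_prob,
         sacrifice_prob = sacrifice_prob,
         min_three_visit_fraction = min_three_visit_fraction,
         seed = as.integer(seed)),
    class = "colony_config"
  )
  validate_colony_config(cfg)
  cfg
}

#' Validate a `colony_config`
#' @param config A `colony_config` object.
#' @return `config`, invisibly; errors name the violated field.
#' @export
validate_colony_config <- function(config) {
  if (config$n_mice <= 0) stopf("n_mice must be positive")
  check_prob_vector(config$sex_probs, "sex_probs", 1e-12)
  check_prob_vector(config$genotype_probs, "genotype_probs", 1e-12)
  if (!is.null(config$transition_matrix)) {
    check_stochastic_matrix(config$transition_matrix, "transition_matrix", 1e-12)
    if (nrow(config$transition_matrix) != config$n_states) {
      stopf("transition_matrix must be n_states x n_states (%d)", config$n_states)
    }
  }
  if (nrow(config$branch_by_genotype) != 3 ||
      ncol(config$branch_by_genotype) != config$k_arch) {
    stopf("branch_by_genotype must be 3 x k_arch")
  }
  for (g in 1:3) check_prob_vector(config$branch_by_genotype[g, ],
                                   sprintf("branch_by_genotype[%d,]", g), 1e-12)
  if (nrow(config$branch_sex_mult) != 2 ||
      ncol(config$branch_sex_mult) != config$k_arch ||
      any(config$branch_sex_mult < 0)) {
    stopf("branch_sex_mult must be a non-negative 2 x k_arch matrix")
  }
  if (nrow(config$init_by_genotype) != 3 ||
      ncol(config$init_by_genotype) != config$n_states) {
    stopf("init_by_genotype must be 3 x n_states")
  }
  for (g in 1:3) check_prob_vector(config$init_by_genotype[g, ],
                                   sprintf("init_by_genotype[%d,]", g), 1e-12)
  a <- config$state_archetypes
  if (any(a$weight_sd <= 0) || any(a$init_sd <= 0)) {
    stopf("state_archetypes weight_sd/init_sd must be > 0")
  }
  if (any(a$hazard < 0)) stopf("state_archetypes hazard must be >= 0")
  if (any(a$age_hi <= a$age_lo)) stopf("state_archetypes need age_lo < age_hi")
  y <- config$young_chain
  if (!is.null(y)) {
    if (y$n < 1) stopf("young_chain n must be >= 1 (or young_chain NULL)")
    if (y$self_prob < 0 || y$self_prob >= 1) stopf("young_chain self_prob must be in [0, 1)")
    if (y$early_branch < 0 || y$early_branch > 1) stopf("young_chain early_branch must be in [0, 1]")
    if (y$weight_sd <= 0 || y$init_sd <= 0) stopf("young_chain weight_sd/init_sd must be > 0")
    if (y$hazard < 0) stopf("young_chain hazard must be >= 0")
    if (y$age_hi <= y$age_lo) stopf("young_chain needs age_lo < age_hi")
  }
  vw <- config$visit_window
  if (vw[["min"]] < 0 || vw[["min"]] >= vw[["max"]]) {
    stopf("visit_window must satisfy 0 <= min < max")
  }
  if (config$missing_visit_prob < 0 || config$missing_visit_prob > 1) {
    stopf("missing_visit_prob must be in [0, 1]")
  }
  invisible(config)
}

# Transition matrix for one genotype: young-chain rows advance/branch with
# that genotype's branch law; archetype rows are persistent.
transition_matrix_for <- function(config, branch) {
  n <- config$n_states
  ny <- config$n_young
  k <- config$k_arch
  A <- matrix(0, n, n)
  y <- config$young_chain
  if (ny > 0) {
    for (i in seq_len(ny)) {
      A[i, i] <- y$self_prob
      move <- 1 - y$self_prob
      if (i < ny) {
        A[i, i + 1] <- move * (1 - y$early_branch)
        A[i, ny + seq_len(k)] <- move * y$early_branch * branch
      } else {
        A[i, ny + seq_len(k)] <- move * branch
      }
    }
  }
  # archetypes: persistent, with a small leak spread over the other
  # archetypes (none when there is only one)
  leak <- if (k > 1) 0.04 else 0
  for (j in seq_len(k)) {
    row <- rep(0, n)
    row[ny + j] <- 1 - leak
    if (k > 1) row[ny + setdiff(seq_len(k), j)] <- leak / (k - 1)
    A[ny + j, ] <- row
  }
  A
}

# Per-(genotype, sex) transition matrices as a 3 x 2 list matrix, honoring
# an explicit transition_matrix override.
transition_matrices <- function(config) {
  out <- vector("list", 6)
  dim(out) <- c(3, 2)
  for (g in 1:3) {
    for (s in 1:2) {
      out[[g, s]] <- if (!is.null(config$transition_matrix)) {
        config$transition_matrix
      } else {
        branch <- config$branch_by_genotype[g, ] * config$branch_sex_mult[s, ]
        transition_matrix_for(config, branch / sum(branch))
      }
    }
  }
  out
}

#' Ground-truth model parameters implied by a colony configuration
#'
#' Builds the `ahmm_params` object whose emission families match the
#' fitted model exactly. The transition matrix is the genotype-marginal
#' chain (young rows branch with the colony-mix-weighted branch law). Age
#' Gaussians cover each state's occupancy window: the young chain's span
#' is divided evenly across its states, and each archetype uses its
#' `age_lo`/`age_hi` window (`mean = (lo+hi)/2`, `sd = (hi-lo)/4`). The
#' per-state sex categorical equals the colony sex mix (states do not
#' depend on sex); the genotype categorical of an archetype is the
#' Bayes-inverted branch law, and of a young state the colony mix. The
#' initial distribution is the genotype-marginal start law. Deterministic
#' given the configuration.
#'
#' @param config A `colony_config`.
#' @return An `ahmm_params` object (the simulation ground truth).
#' @export
generate_true_params <- function(config) {
  validate_colony_config(config)
  a <- config$state_archetypes
  ny <- config$n_young
  k <- config$k_arch
  n <- config$n_states
  gp <- as.numeric(config$genotype_probs)
  sp <- as.numeric(config$sex_probs)

  A_list <- transition_matrices(config)
  A <- matrix(0, n, n)
  for (g in 1:3) for (s in 1:2) A <- A + gp[g] * sp[s] * A_list[[g, s]]

  pi <- as.numeric(gp %*% config$init_by_genotype)

  # sex and genotype composition per state: Bayes inversion of the
  # (genotype, sex)-coupled branch law; young states mirror the colony mix
  sex_probs <- matrix(sp, n, 2, byrow = TRUE)
  geno_probs <- matrix(gp, n, 3, byrow = TRUE)
  if (is.null(config$transition_matrix) && ny > 0) {
    joint_gs <- array(0, dim = c(3, 2, k))  # P(genotype, sex, archetype)
    for (g in 1:3) {
      for (s in 1:2) {
        branch <- config$branch_by_genotype[g, ] * config$branch_sex_mult[s, ]
        joint_gs[g, s, ] <- gp[g] * sp[s] * branch / sum(branch)
      }
    }
    for (j in seq_len(k)) {
      pj <- sum(joint_gs[, , j])
      if (pj > 0) {
        geno_probs[ny + j, ] <- apply(joint_gs[, , j], 1, sum) / pj
        sex_probs[ny + j, ] <- apply(joint_gs[, , j], 2, sum) / pj
      }
    }
  } else if (is.null(config$young_chain)) {
    joint <- config$init_by_genotype * gp  # 3 x n, rows genotypes
    cs <- colSums(joint)
    sub <- t(joint)
    sub[cs > 0, ] <- sub[cs > 0, , drop = FALSE] / cs[cs > 0]
    if (any(cs == 0)) {
      sub[cs == 0, ] <- matrix(gp, sum(cs == 0), 3, byrow = TRUE)
    }
    geno_probs <- sub
  }

  y <- config$young_chain
  if (ny > 0) {
    step <- (y$age_hi - y$age_lo) / ny
    young_age_mean <- y$age_lo + (seq_len(ny) - 0.5) * step
    young_age_sd <- rep(0.9 * step, ny)
    young_level <- seq(y$level_start, y$level_end, length.out = ny)
    young <- list(
      age_mean = young_age_mean, age_var = young_age_sd^2,
      ar_intercept = young_level * (1 - y$ar_slope),
      ar_male = rep(y$male_offset * (1 - y$ar_slope), ny),
      ar_slope = rep(y$ar_slope, ny),
      ar_var = rep(y$weight_sd^2, ny),
      init_intercept = rep(y$init_level, ny),
      init_male = rep(y$init_male, ny),
      init_var = rep(y$init_sd^2, ny)
    )
  } else {
    young <- lapply(stats::setNames(nm = c("age_mean", "age_var", "ar_intercept",
                                           "ar_male", "ar_slope", "ar_var",
                                           "init_intercept", "init_male",
                                           "init_var")),
                    function(f) numeric(0))
  }

  ahmm_params(
    pi = pi,
    A = A,
    age_mean = c(young$age_mean, (a$age_lo + a$age_hi) / 2),
    age_var = pmax(c(young$age_var, ((a$age_hi - a$age_lo) / 4)^2), 1e-3),
    sex_probs = sex_probs,
    geno_probs = geno_probs,
    ar_intercept = c(young$ar_intercept, a$weight_intercept),
    ar_male = c(young$ar_male, a$male_offset),
    ar_slope = c(young$ar_slope, a$ar_slope),
    ar_var = c(young$ar_var, a$weight_sd^2),
    init_intercept = c(young$init_intercept, a$init_intercept),
    init_male = c(young$init_male, a$init_male),
    init_var = c(young$init_var, a$init_sd^2),
    state_labels = if (n <= 26) LETTERS[seq_len(n)] else NULL
  )
}

# Per-state hazard vector (deaths per month), young chain first.
state_hazards <- function(config) {
  yh <- if (config$n_young > 0) rep(config$young_chain$hazard, config$n_young)
        else numeric(0)
  c(yh, config$state_archetypes$hazard)
}

#' Simulate a colony table and its ground truth
#'
#' For each mouse: sex and genotype are drawn from the configured mix; a
#' visit schedule starts uniformly in `first_visit_range` with Gaussian
#' inter-visit gaps truncated at 0.5 months, then visits after the third
#' are independently dropped with `missing_visit_prob` (each retained
#' measurement is one Markov step, matching the fitted model); the hidden
#' state path starts from the genotype's start law and follows the
#' genotype's transition matrix (young chain branching into archetypes);
#' the first weight is drawn from the state's first-visit Gaussian and
#' later weights from the state's AR(1) emission; a constant per-month
#' hazard attached to the current state can kill the mouse between visits
#' (exponential waiting time), truncating the series. Mice alive at their
#' last scheduled visit may be flagged as sacrificed.
#'
#' @param params Ground-truth `ahmm_params` from [generate_true_params()].
#' @param config The `colony_config` used to build `params`.
#' @return A list with `colony` (long-format data frame, one row per
#'   visit: mouse_id, sex, genotype, birth_date, death_date, death_cause,
#'   is_breeder, measurement_date, age_months, weight_g) and `truth`
#'   (class `colony_truth`: `path` data frame aligned row-for-row with
#'   `colony` carrying the true state per visit, `params`, `terminal`
#'   per-mouse terminal states, and `death` per-mouse death age/status).
#' @export
simulate_colony <- function(params, config) {
  validate_colony_config(config)
  validate_ahmm_params(params)
  seeds <- derive_seeds(config$seed, 2)
  with_seed(seeds[1], {
    n <- config$n_mice
    ns <- config$n_states
    hazards <- state_hazards(config)
    A_list <- transition_matrices(config)
    ids <- sprintf("M%04d", seq_len(n))
    sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = config$sex_probs)
    geno <- sample(GENO_LEVELS, n, replace = TRUE, prob = config$genotype_probs)
    birth <- as.Date("2018-06-01") + sample.int(550, n, replace = TRUE)

    rows <- vector("list", n)
    path_rows <- vector("list", n)
    terminal <- character(n)
    death_age <- rep(NA_real_, n)
    status <- character(n)

    for (m in seq_len(n)) {
      ages <- stats::runif(1, config$first_visit_range[1], config$first_visit_range[2])
      while (TRUE) {
        gap <- max(0.5, stats::rnorm(1, config$visit_spacing[["mean"]],
                                     config$visit_spacing[["sd"]]))
        nxt <- ages[length(ages)] + gap
        if (nxt > config$visit_window[["max"]]) break
        ages <- c(ages, nxt)
      }
      keep <- rep(TRUE, length(ages))
      if (length(ages) > 3) {
        keep[-(1:3)] <- stats::runif(length(ages) - 3) >= config$missing_visit_prob
      }
      ages <- ages[keep]
      k <- length(ages)

      male <- as.numeric(sex[m] == "male")
      g <- match_genotype(geno[m])
      A_g <- A_list[[g, match_sex(sex[m])]]
      states <- integer(k)
      weights <- numeric(k)
      states[1] <- sample.int(ns, 1, prob = config$init_by_genotype[g, ])
      weights[1] <- max(stats::rnorm(1, params$init_intercept[states[1]] +
                                       params$init_male[states[1]] * male,
                                     sqrt(params$init_var[states[1]])), 1)
      died_at <- NA_real_
      last <- k
      for (t in seq_len(k)) {
        if (t > 1) {
          states[t] <- sample.int(ns, 1, prob = A_g[states[t - 1], ])
          mu <- params$ar_intercept[states[t]] + params$ar_male[states[t]] * male +
            params$ar_slope[states[t]] * weights[t - 1]
          weights[t] <- max(stats::rnorm(1, mu, sqrt(params$ar_var[states[t]])), 1)
        }
        if (t < k) {
          h <- hazards[states[t]]
          if (h > 0) {
            wait <- stats::rexp(1, h)
            if (wait < ages[t + 1] - ages[t]) {
              died_at <- ages[t] + wait
              last <- t
              break
            }
          }
        }
      }
      ages <- ages[seq_len(last)]
      states <- states[seq_len(last)]
      weights <- weights[seq_len(last)]

      if (!is.na(died_at)) {
        status[m] <- "natural"
        death_age[m] <- died_at
      } else if (stats::runif(1) < config$sacrifice_prob) {
        status[m] <- "sacrificed"
        death_age[m] <- ages[length(ages)] + 0.1
      } else {
        status[m] <- "alive"
      }
      terminal[m] <- params$state_labels[states[length(states)]]

      dates <- birth[m] + round(ages * MONTH_DAYS)
      death_date <- if (status[m] == "alive") as.Date(NA) else
        birth[m] + round(death_age[m] * MONTH_DAYS)
      rows[[m]] <- data.frame(
        mouse_id = ids[m], sex = sex[m], genotype = geno[m],
        birth_date = birth[m], death_date = death_date,
        death_cause = if (status[m] == "alive") NA_character_ else status[m],
        is_breeder = FALSE,
        measurement_date = dates, age_months = ages, weight_g = weights,
        stringsAsFactors = FALSE
      )
      path_rows[[m]] <- data.frame(
        mouse_id = ids[m], visit = seq_along(ages), age_months = ages,
        weight_g = weights, state = params$state_labels[states],
        stringsAsFactors = FALSE
      )
    }

    colony <- do.call(rbind, rows)
    rownames(colony) <- NULL
    path <- do.call(rbind, path_rows)
    rownames(path) <- NULL
    frac3 <- mean(tabulate(factor(path$mouse_id, levels = ids)) >= 3)
    if (frac3 < config$min_three_visit_fraction) {
      warnf("only %.1f%% of mice retain >= 3 visits (configured minimum %.1f%%)",
            100 * frac3, 100 * config$min_three_visit_fraction)
    }
    truth <- structure(
      list(path = path, params = params,
           terminal = data.frame(mouse_id = ids, state = terminal,
                                 stringsAsFactors = FALSE),
           death = data.frame(mouse_id = ids, death_age = death_age,
                              status = status, stringsAsFactors = FALSE),
           config_seed = config$seed),
      class = "colony_truth"
    )
    list(colony = colony, truth = truth)
  })
}

# Archetype index of a state label (NA for young states).
archetype_index <- function(config, state_labels, states) {
  idx <- match(states, state_labels) - config$n_young
  idx[idx < 1] <- NA_integer_
  idx
}

#' Simulate post-hoc biomarker and body-composition tables
#'
#' For each mouse with a retained visit inside `age_window` (default 12-14
#' months, the window in which plasma amyloid is reliably detectable) and
#' already branched into an archetype at that visit, one biomarker pair is
#' drawn from the archetype's biomarker Gaussian (the Abeta42-like value
#' at 60% of the Abeta40-like mean and SD), and one body-composition
#' triple (fat, lean, free water, all >= 0 g) is drawn around the
#' archetype's adipose fraction applied to the visit weight.
#'
#' @param truth A `colony_truth` from [simulate_colony()].
#' @param config The matching `colony_config`.
#' @param age_window Numeric length-2 selection window in months.
#' @return A list of class `posthoc_tables` with data frames `biomarkers`
#'   (mouse_id, age_months, weight_g, true_state, abeta40, abeta42) and
#'   `composition` (mouse_id, age_months, weight_g, true_state, fat, lean,
#'   free_water). Empty selections yield empty data frames with a warning.
#' @export
simulate_posthoc_measures <- function(truth, config, age_window = c(12, 14)) {
  validate_colony_config(config)
  if (!inherits(truth, "colony_truth")) stopf("truth must be a 'colony_truth'")
  seeds <- derive_seeds(config$seed, 2)
  with_seed(seeds[2], {
    p <- truth$path
    sel <- p[p$age_months >= age_window[1] & p$age_months <= age_window[2], ,
             drop = FALSE]
    sel <- sel[!duplicated(sel$mouse_id), , drop = FALSE]
    if (nrow(sel)) {
      ai <- archetype_index(config, truth$params$state_labels, sel$state)
      sel <- sel[!is.na(ai), , drop = FALSE]
      ai <- ai[!is.na(ai)]
    }
    if (!nrow(sel)) {
      warnf("no archetype-state visits fall in the age window [%g, %g]; returning empty tables",
            age_window[1], age_window[2])
      empty_bio <- data.frame(mouse_id = character(0), age_months = numeric(0),
                              weight_g = numeric(0), true_state = character(0),
                              abeta40 = numeric(0), abeta42 = numeric(0))
      empty_comp <- data.frame(mouse_id = character(0), age_months = numeric(0),
                               weight_g = numeric(0), true_state = character(0),
                               fat = numeric(0), lean = numeric(0),
                               free_water = numeric(0))
      return(structure(list(biomarkers = empty_bio, composition = empty_comp),
                       class = "posthoc_tables"))
    }
    arche <- config$state_archetypes
    m40 <- arche$biomarker_mean[ai]
    s40 <- arche$biomarker_sd[ai]
    bio <- data.frame(
      mouse_id = sel$mouse_id, age_months = sel$age_months,
      weight_g = sel$weight_g, true_state = sel$state,
      abeta40 = stats::rnorm(nrow(sel), m40, s40),
      abeta42 = stats::rnorm(nrow(sel), 0.6 * m40, 0.6 * s40),
      stringsAsFactors = FALSE
    )
    frac <- pmin(pmax(stats::rnorm(nrow(sel), arche$adipose_frac[ai], 0.03), 0.02), 0.6)
    fat <- frac * sel$weight_g
    water <- pmax(stats::rnorm(nrow(sel), 0.05 * sel$weight_g, 0.2), 0)
    lean <- pmax(sel$weight_g - fat - water + stats::rnorm(nrow(sel), 0, 0.3), 0.1)
    comp <- data.frame(
      mouse_id = sel$mouse_id, age_months = sel$age_months,
      weight_g = sel$weight_g, true_state = sel$state,
      fat = fat, lean = lean, free_water = water,
      stringsAsFactors = FALSE
    )
    structure(list(biomarkers = bio, composition = comp),
              class = "posthoc_tables")
  })
}

#' Write a colony table as CSV (UTF-8, header, ISO-8601 dates)
#' @param colony Colony data frame from [simulate_colony()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_colony_csv <- function(colony, path) {
  out <- colony
  for (col in c("birth_date", "death_date", "measurement_date")) {
    out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write ground truth as JSON
#' @param truth A `colony_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  x <- list(
    path = truth$path, terminal = truth$terminal, death = truth$death,
    config_seed = truth$config_seed,
    params = jsonlite::fromJSON(jsonlite::toJSON(
      unclass(truth$params), auto_unbox = TRUE, digits = NA))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
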