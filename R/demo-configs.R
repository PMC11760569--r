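# Reference study designs used for parameter-recovery and end-to-end
# trajectory-recovery experiments, plus the agreement metric that scores a
# fitted grouping against simulation ground truth.

#' Three-state progression study design
#'
#' A single-track aging design used for parameter recovery: every mouse
#' traverses young -> middle -> old states (a left-to-right chain with no
#' back-transitions), with weight levels 18, 30, 42 g (female), a fast
#' AR(1) pull to the level (`phi = 0.3`), and age-emission windows matched
#' to the realized occupancy of each state under roughly monthly visits
#' from 5 to 22 months. States are simultaneously age bands and weight
#' levels, which makes the generative parameters identifiable to the
#' fitted model family. The first-visit weight spread is wide (SD 3.5 g),
#' which supplies high-leverage regression pairs that pin down the young
#' state's AR slope; the later states get theirs from the level snaps at
#' each transition.
#'
#' @param n_mice Number of mice.
#' @param seed Master seed.
#' @return A `colony_config`.
#' @export
progression_colony_config <- function(n_mice = 300, seed = 1) {
  phi <- 0.3
  arch <- data.frame(
    name = c("young", "mid", "old"),
    weight_intercept = c(18, 30, 42) * (1 - phi),
    male_offset = rep(3 * (1 - phi), 3),
    ar_slope = rep(phi, 3),
    weight_sd = rep(0.8, 3),
    age_lo = c(1.4, 5.4, 11.1),
    age_hi = c(10.6, 15.8, 25.7),
    hazard = rep(0, 3),
    biomarker_mean = c(30, 50, 80), biomarker_sd = rep(8, 3),
    init_intercept = c(18, 30, 42), init_male = rep(3, 3),
    init_sd = rep(3.5, 3),
    adipose_frac = c(0.1, 0.2, 0.3),
    stringsAsFactors = FALSE
  )
  A <- matrix(c(0.72, 0.28, 0,
                0,    0.84, 0.16,
                0,    0,    1), 3, 3, byrow = TRUE)
  init_g <- matrix(rep(c(1, 0, 0), each = 3), 3, 3)
  colony_config(
    n_mice = n_mice, state_archetypes = arch, young_chain = NULL,
    transition_matrix = A, init_by_genotype = init_g,
    visit_window = c(min = 5, max = 22), first_visit_range = c(5, 5.5),
    visit_spacing = c(mean = 1, sd = 0.2), missing_visit_prob = 0.03,
    sacrifice_prob = 0, seed = seed
  )
}

#' Five-archetype branching study design
#'
#' A well-separated trajectory-discovery design: a four-state young growth
#' chain (ages ~5-11, weight 25-27 g female) branches into five persistent
#' phenotype archetypes with stationary levels 13, 20, 27, 34 and 42 g and
#' per-archetype approach speeds chosen so that downward snaps respect the
#' 20%-per-month exclusion rule while upward snaps are fast. Branching is
#' strongly sex- and genotype-coupled (e.g. deep loss male-dominant, gain
#' enriched for E4/4), giving each archetype a categorical fingerprint as
#' observed trajectory groups have. Visits are spaced ~1.6 months with 15%
#' missingness over ages 5-16.8, so each mouse contributes a handful of
#' growth-phase and archetype-phase measurements. The gain archetype
#' carries the highest hazard and biomarker mean, the deep-loss archetype
#' the lowest weight.
#'
#' @param n_mice Number of mice.
#' @param seed Master seed.
#' @return A `colony_config`.
#' @export
branching_colony_config <- function(n_mice = 600, seed = 1) {
  levels <- c(13, 20, 27, 34, 42)
  phis <- c(0.6, 0.45, 0.5, 0.4, 0.35)
  arch <- data.frame(
    name = c("loss_deep", "loss_mid", "stable", "gain_mild", "gain"),
    weight_intercept = levels * (1 - phis),
    male_offset = 5 * (1 - phis),
    ar_slope = phis,
    weight_sd = c(0.6, 0.6, 0.6, 0.6, 0.8),
    age_lo = rep(9.9, 5), age_hi = rep(16.9, 5),
    hazard = c(0.020, 0.012, 0.008, 0.015, 0.045),
    biomarker_mean = c(35, 40, 50, 70, 90),
    biomarker_sd = c(8, 8, 8, 10, 12),
    init_intercept = levels, init_male = rep(5, 5), init_sd = rep(1.2, 5),
    adipose_frac = c(0.10, 0.13, 0.18, 0.27, 0.36),
    stringsAsFactors = FALSE
  )
  yc <- young_chain_config(
    n = 4, level_start = 25, level_end = 27, ar_slope = 0.5,
    weight_sd = 0.6, male_offset = 4, self_prob = 0.20, early_branch = 0.05,
    age_lo = 6, age_hi = 10.8, init_level = 25, init_male = 3.5,
    init_sd = 1.0, hazard = 0.003
  )
  bg <- rbind("E3/3" = c(0.10, 0.15, 0.45, 0.25, 0.05),
              "E3/4" = c(0.35, 0.25, 0.25, 0.10, 0.05),
              "E4/4" = c(0.08, 0.12, 0.30, 0.15, 0.35))
  bsm <- rbind(female = c(0.2, 1.6, 1.0, 0.3, 1.5),
               male   = c(1.8, 0.4, 1.0, 1.7, 0.5))
  colony_config(
    n_mice = n_mice, state_archetypes = arch, young_chain = yc,
    branch_by_genotype = bg, branch_sex_mult = bsm,
    visit_window = c(min = 5, max = 16.8), missing_visit_prob = 0.15,
    visit_spacing = c(mean = 1.6, sd = 0.35), sacrifice_prob = 0.1,
    seed = seed
  )
}

#' Score a fitted trajectory grouping against simulation ground truth
#'
#' Matches each fitted ending state to a distinct true phenotype archetype
#' (greedily, by overlap) and reports the fraction of truth-archetype
#' -terminal mice whose fitted group matches their true archetype.
#'
#' @param assignments Output of [assign_terminal_states()].
#' @param classification Output of [classify_states()] for the same fit.
#' @param truth A `colony_truth`.
#' @param config The `colony_config` that produced `truth` (identifies
#'   which states are archetypes).
#' @return A list: `agreement` (fraction in `[0, 1]`), `n_ending` (number
#'   of fitted ending states), `mapping` (fitted label -> true archetype
#'   label), `table` (fitted x truth contingency table).
#' @export
trajectory_agreement <- function(assignments, classification, truth, config) {
  truth_term <- stats::setNames(truth$terminal$state, truth$terminal$mouse_id)
  tt <- truth_term[assignments$mouse_id]
  arch_labels <- utils::tail(truth$params$state_labels, config$k_arch)
  tab <- table(factor(assignments$state, levels = unique(assignments$state)),
               factor(tt, levels = truth$params$state_labels))
  agree <- 0
  used <- character(0)
  mapping <- character(0)
  for (lbl in classification$ending_labels) {
    cand <- setdiff(arch_labels, used)
    if (!length(cand) || !(lbl %in% rownames(tab))) next
    row <- tab[lbl, cand, drop = FALSE]
    j <- which.max(row)
    agree <- agree + max(row)
    used <- c(used, cand[j])
    mapping[lbl] <- cand[j]
  }
  n_arch <- sum(tt %in% arch_labels)
  list(agreement = if (n_arch > 0) agree / n_arch else NA_real_,
       n_ending = length(classification$ending_labels),
       mapping = mapping, table = tab)
}
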