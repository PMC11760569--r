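# Post-hoc validation battery: survival, composition, biomarkers,
# single-observation state inference for cross-sectional data.

#' Build per-mouse survival records from a cohort
#'
#' Time-to-event is measured from birth to death (event) or to the last
#' weight measurement (censored) in months. Mice flagged as sacrificed are
#' excluded from survival analysis entirely: their endpoint reflects an
#' experimental schedule, not mortality.
#'
#' @param mice List of `mouse_series`.
#' @param groups Optional named group label per mouse id (e.g. trajectory
#'   assignments); mice without a label get `NA`.
#' @param exclude_sacrificed Drop mice whose `death_cause` is
#'   `"sacrificed"` (default TRUE).
#' @return A data frame: `mouse_id`, `time_months` (> 0), `event` (1 =
#'   death, 0 = censored), `group`.
#' @export
make_survival_records <- function(mice, groups = NULL,
                                  exclude_sacrificed = TRUE) {
  rows <- lapply(mice, function(m) {
    cause <- tolower(m$death_cause %||% NA_character_)
    if (exclude_sacrificed && !is.na(cause) && cause == "sacrificed") {
      return(NULL)
    }
    died <- !is.na(m$death_date) && (is.na(cause) || cause != "sacrificed")
    time <- if (died) {
      as.numeric(m$death_date - m$birth_date) / MONTH_DAYS
    } else {
      max(m$records$age_months)
    }
    data.frame(mouse_id = m$mouse_id, time_months = time,
               event = as.integer(died), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    stopf("no mice available for survival analysis")
  }
  out <- out[out$time_months > 0, , drop = FALSE]
  out$group <- if (is.null(groups)) NA_character_ else
    unname(groups[out$mouse_id])
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit survival estimate
#'
#' @param time Event/censoring times (> 0), or a data frame with columns
#'   `time_months` and `event`.
#' @param event Event indicator (1 = death, 0 = censored).
#' @return A data frame of class `km_curve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (non-increasing, starting from S(0) = 1 before the first row).
#' @export
km_estimate <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time_months %||% time$time
  }
  if (!length(time)) stopf("need at least one survival record")
  if (any(time <= 0)) stopf("survival times must be positive")
  event <- as.integer(event)
  o <- order(time)
  time <- time[o]
  event <- event[o]
  ut <- unique(time)
  n <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  at_risk <- n
  for (i in seq_along(ut)) {
    here <- time == ut[i]
    d <- sum(event[here])
    c_ <- sum(!event[here])
    n_risk[i] <- at_risk
    n_event[i] <- d
    n_censor[i] <- c_
    if (d > 0) s <- s * (1 - d / at_risk)
    surv[i] <- s
    at_risk <- at_risk - d - c_
  }
  if (all(event == 0)) {
    warnf("all records censored: survival curve is flat at 1")
  }
  structure(
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv),
    class = c("km_curve", "data.frame")
  )
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest observed time at which the survival estimate drops to 0.5
#' or below; `NA` when the curve never reaches 0.5.
#'
#' @param km A `km_curve` from [km_estimate()].
#' @return Time in the curve's units, or `NA_real_`.
#' @export
median_survival <- function(km) {
  hit <- which(km$surv <= 0.5)
  if (!length(hit)) return(NA_real_)
  km$time[hit[1]]
}

#' K-sample log-rank test
#'
#' Standard log-rank comparison of survival across K groups: at each event
#' time the observed group-wise death counts are compared with their
#' hypergeometric expectations, and the chi-square statistic is formed from
#' the first K-1 groups with the exact hypergeometric covariance
#' (generalized inverse for degenerate tables). The p-value is the upper
#' chi-square tail on K-1 degrees of freedom.
#'
#' @param records Data frame with columns `time_months` (or `time`),
#'   `event`, `group`; or a list of per-group record data frames.
#' @return A list: `chisq`, `df`, `p_value`, `observed` and `expected`
#'   event counts per group. `NA` statistics with a warning when no events
#'   occurred.
#' @export
logrank_test <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(seq_along(records), function(i) {
      d <- records[[i]]
      d$group <- names(records)[i] %||% as.character(i)
      d
    }))
  }
  time <- records$time_months %||% records$time
  event <- as.integer(records$event)
  group <- factor(records$group)
  K <- nlevels(group)
  if (K < 2) stopf("log-rank test needs at least two groups")
  if (sum(event) == 0) {
    warnf("no events in any group: log-rank statistic is undefined")
    return(list(chisq = NA_real_, df = K - 1L, p_value = NA_real_,
                observed = table(group[event == 1]),
                expected = rep(NA_real_, K)))
  }
  ev_times <- sort(unique(time[event == 1]))
  O <- numeric(K)
  E <- numeric(K)
  V <- matrix(0, K, K)
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event == 1 & time == t)
    n_kj <- tabulate(group[at_risk], K)
    d_kj <- tabulate(group[event == 1 & time == t], K)
    O <- O + d_kj
    E <- E + n_kj * d_j / n_j
    if (n_j > 1) {
      p <- n_kj / n_j
      Vt <- (diag(p, K) - p %o% p) * d_j * (n_j - d_j) / (n_j - 1)
      V <- V + Vt
    }
  }
  idx <- seq_len(K - 1)
  z <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chisq <- as.numeric(t(z) %*% MASS::ginv(Vi) %*% z)
  df <- K - 1L
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       observed = stats::setNames(O, levels(group)),
       expected = stats::setNames(E, levels(group)))
}

#' Pearson chi-square test of group composition
#'
#' Tests whether a categorical attribute (sex or genotype) is distributed
#' identically across groups, on the K x L contingency table without
#' continuity correction. Empty rows or columns are collapsed with a
#' warning. Supply `pair` to run a pairwise 2 x L comparison between two
#' groups.
#'
#' @param group Group label per mouse (factor/character), or a contingency
#'   table/matrix (in which case `value` is ignored).
#' @param value Attribute value per mouse.
#' @param pair Optional length-2 vector of group labels for a pairwise
#'   comparison.
#' @return A list: `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
contingency_chisq <- function(group, value = NULL, pair = NULL) {
  tab <- if (is.table(group) || is.matrix(group)) {
    as.table(as.matrix(group))
  } else {
    table(group, value)
  }
  if (!is.null(pair)) {
    if (length(pair) != 2 || !all(pair %in% rownames(tab))) {
      stopf("'pair' must name two groups present in the table")
    }
    tab <- tab[pair, , drop = FALSE]
  }
  empty_r <- rowSums(tab) == 0
  empty_c <- colSums(tab) == 0
  if (any(empty_r) || any(empty_c)) {
    warnf("collapsing %d empty row(s) and %d empty column(s)",
          sum(empty_r), sum(empty_c))
    tab <- tab[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stopf("contingency table needs at least 2 non-empty rows and columns")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, observed = ht$observed, expected = ht$expected)
}

#' Two-sample t test (Welch by default)
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param var_equal Use the pooled-variance Student t instead of Welch's
#'   unequal-variance t (default FALSE).
#' @return A list: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_ttest <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stopf("each sample needs at least 2 finite values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate: both samples constant; t.test() refuses, define the limit
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p_value = if (equal) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Adipose index (percent body fat) from body composition
#'
#' `100 * fat / (fat + lean + free_water)`; all masses must be
#' non-negative with a positive total. Vectorized.
#'
#' @param fat,lean,free_water Masses in grams.
#' @return Percent body fat in `[0, 100]`.
#' @export
adipose_index <- function(fat, lean, free_water) {
  if (any(fat < 0 | lean < 0 | free_water < 0, na.rm = TRUE)) {
    stopf("masses must be non-negative")
  }
  total <- fat + lean + free_water
  if (any(total <= 0, na.rm = TRUE)) stopf("total mass must be positive")
  100 * fat / total
}

#' Infer the hidden state from a single cross-sectional observation
#'
#' For a mouse observed once (age, weight, sex, genotype, no previous
#' weight), the posterior over hidden states is proportional to a prior
#' times the single-visit emission density (which uses the first-visit
#' weight Gaussian). The default prior is the stationary distribution of
#' the fitted transition matrix - the long-run state occupancy - with the
#' fitted initial distribution available as an alternative.
#'
#' @param fit An `ahmm_fit` or `ahmm_params`.
#' @param age,weight,sex,genotype The single observation.
#' @param prior_mode `"stationary"` (default) or `"initial"`.
#' @return A list: `posterior` (named by state label, sums to 1), `state`
#'   (argmax label), `confidence`.
#' @export
infer_state_single_obs <- function(fit, age, weight, sex, genotype,
                                   prior_mode = c("stationary", "initial")) {
  prior_mode <- match.arg(prior_mode)
  params <- if (inherits(fit, "ahmm_fit")) fit$params else fit
  validate_ahmm_params(params)
  prior <- if (prior_mode == "stationary") {
    stationary_distribution(params$A, pi = params$pi)
  } else {
    params$pi
  }
  lp <- vapply(seq_len(params$n_states), function(i) {
    emission_logdensity(params, i, age, weight, sex, genotype,
                        prev_weight = NULL)
  }, numeric(1))
  lpost <- log(pmax(prior, 1e-300)) + lp
  if (all(!is.finite(lpost)) || logsumexp(lpost) <= log(1e-300)) {
    stopf("all-zero posterior: no state can explain the observation")
  }
  post <- exp(lpost - logsumexp(lpost))
  post <- post / sum(post)
  names(post) <- params$state_labels
  idx <- which.max(post)
  list(posterior = post, state = params$state_labels[idx],
       confidence = unname(post[idx]))
}

#' Compare cross-sectional measurements across inferred hidden states
#'
#' For each measurement type, runs pairwise Welch t tests between every
#' pair of inferred states holding at least two records. Unadjusted
#' p-values are reported alongside a Holm-adjusted column (adjusted within
#' measurement). States with fewer than two records are skipped with a
#' note.
#'
#' @param cs Data frame with columns `measurement`, `value`, and `state`
#'   (the inferred hidden-state label, e.g. from
#'   [infer_state_single_obs()]).
#' @return A list: `comparisons` (data frame of pairwise tests) and
#'   `skipped` (data frame of measurement/state cells with < 2 records).
#' @export
compare_cs_across_states <- function(cs) {
  need <- c("measurement", "value", "state")
  miss <- setdiff(need, names(cs))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  comparisons <- list()
  skipped <- list()
  for (meas in unique(cs$measurement)) {
    d <- cs[cs$measurement == meas & is.finite(cs$value), , drop = FALSE]
    counts <- table(d$state)
    ok_states <- names(counts)[counts >= 2]
    small <- names(counts)[counts < 2]
    if (length(small)) {
      skipped[[length(skipped) + 1]] <- data.frame(
        measurement = meas, state = small,
        n = as.integer(counts[small]), stringsAsFactors = FALSE)
    }
    if (length(ok_states) < 2) next
    prs <- utils::combn(sort(ok_states), 2)
    res <- lapply(seq_len(ncol(prs)), function(j) {
      a <- d$value[d$state == prs[1, j]]
      b <- d$value[d$state == prs[2, j]]
      tt <- welch_ttest(a, b)
      data.frame(measurement = meas, state_a = prs[1, j], state_b = prs[2, j],
                 n_a = length(a), n_b = length(b),
                 mean_a = tt$mean_a, mean_b = tt$mean_b,
                 t = tt$t, df = tt$df, p_value = tt$p_value,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
    comparisons[[length(comparisons) + 1]] <- res
  }
  list(
    comparisons = if (length(comparisons)) do.call(rbind, comparisons) else
      data.frame(measurement = character(0), state_a = character(0),
                 state_b = character(0), n_a = integer(0), n_b = integer(0),
                 mean_a = numeric(0), mean_b = numeric(0), t = numeric(0),
                 df = numeric(0), p_value = numeric(0), p_holm = numeric(0)),
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(measurement = character(0), state = character(0),
                 n = integer(0))
  )
}
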