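# Trajectory discovery from a fitted transition matrix.

#' Classify hidden states as starting, intermediate, or ending
#'
#' Ending states are states a chain tends to arrive in and stay in: a state
#' is ending when its self-transition probability exceeds `threshold`
#' (default 0.3, strict inequality on the diagonal). Among non-ending
#' states, those whose incoming probability mass from other states falls at
#' or below the `starting_quantile` of the non-ending incoming masses are
#' labeled starting; the rest are intermediate.
#'
#' @param A Row-stochastic transition matrix (or an `ahmm_params` /
#'   `ahmm_fit`, from which the matrix and labels are taken).
#' @param threshold Ending-state diagonal threshold (default 0.3).
#' @param starting_quantile Quantile of incoming mass separating starting
#'   from intermediate among non-ending states (default 0.5).
#' @param labels Optional state labels.
#' @return A list of class `state_classification`: `states` data frame
#'   (label, role, self_prob, incoming), `ending_labels`, and `threshold`.
#' @export
classify_states <- function(A, threshold = 0.3, starting_quantile = 0.5,
                            labels = NULL) {
  if (inherits(A, "ahmm_fit")) A <- A$params
  if (inherits(A, "ahmm_params")) {
    labels <- labels %||% A$state_labels
    A <- A$A
  }
  check_stochastic_matrix(A, "A")
  n <- nrow(A)
  labels <- labels %||% (if (n <= 26) LETTERS[seq_len(n)] else sprintf("S%02d", seq_len(n)))
  self_prob <- diag(A)
  incoming <- colSums(A) - self_prob
  ending <- self_prob > threshold
  role <- rep("intermediate", n)
  role[ending] <- "ending"
  non_end <- which(!ending)
  if (length(non_end)) {
    cut <- stats::quantile(incoming[non_end], starting_quantile, names = FALSE)
    role[non_end[incoming[non_end] <= cut]] <- "starting"
  }
  structure(
    list(
      states = data.frame(label = labels, role = role, self_prob = self_prob,
                          incoming = incoming, stringsAsFactors = FALSE),
      ending_labels = labels[ending],
      threshold = threshold
    ),
    class = "state_classification"
  )
}

#' @export
print.state_classification <- function(x, ...) {
  cat(sprintf("State classification (ending if self-transition > %.2f)\n",
              x$threshold))
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Decode each mouse's terminal hidden state
#'
#' The default decodes the state "a mouse ends in" as the argmax of the
#' smoothed posterior at the final visit (forward-backward); the
#' alternative takes the last state of the Viterbi path. The reported
#' confidence is the smoothed posterior mass of the chosen state at the
#' final visit. Ties break toward the lower canonical label.
#'
#' @param seqs List of `observation_sequence` objects.
#' @param fit An `ahmm_fit` (or `ahmm_params`).
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @return A data frame: `mouse_id`, `state` (label), `state_index`,
#'   `confidence`.
#' @export
assign_terminal_states <- function(seqs, fit, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  params <- if (inherits(fit, "ahmm_fit")) fit$params else fit
  validate_ahmm_params(params)
  out <- lapply(seqs, function(s) {
    fb <- tryCatch(forward_backward(s, params), error = function(e) {
      stopf("inference failed for mouse %s: %s", s$mouse_id, conditionMessage(e))
    })
    gk <- fb$gamma[nrow(fb$gamma), ]
    idx <- if (method == "posterior") {
      which.max(gk)  # first max = lower index on ties
    } else {
      path <- viterbi(s, params)
      path[length(path)]
    }
    data.frame(mouse_id = s$mouse_id, state = params$state_labels[idx],
               state_index = idx, confidence = gk[idx],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group mice into trajectories by ending state
#'
#' Mice whose terminal state is an ending state form one trajectory group
#' per ending state; mice terminating in starting/intermediate states are
#' returned as unassigned (they have no stable end state). The partition is
#' exhaustive: every assigned mouse appears in exactly one group or in the
#' unassigned set.
#'
#' @param assignments Output of [assign_terminal_states()].
#' @param classification Output of [classify_states()] from the same fit.
#' @return A list of class `trajectory_grouping`: `groups` (named list of
#'   `trajectory_group`s: label, mouse_ids, n) and `unassigned` (mouse
#'   ids).
#' @export
group_by_trajectory <- function(assignments, classification) {
  ending <- classification$ending_labels
  in_end <- assignments$state %in% ending
  groups <- lapply(ending, function(lbl) {
    ids <- assignments$mouse_id[assignments$state == lbl]
    structure(list(label = lbl, mouse_ids = ids, n = length(ids)),
              class = "trajectory_group")
  })
  names(groups) <- ending
  groups <- groups[vapply(groups, function(g) g$n > 0, logical(1))]
  structure(
    list(groups = groups, unassigned = assignments$mouse_id[!in_end],
         n_total = nrow(assignments)),
    class = "trajectory_grouping"
  )
}

#' @export
print.trajectory_grouping <- function(x, ...) {
  cat(sprintf("Trajectory grouping: %d groups, %d/%d mice unassigned\n",
              length(x$groups), length(x$unassigned), x$n_total))
  for (g in x$groups) cat(sprintf("  %s: %d mice\n", g$label, g$n))
  invisible(x)
}

# Member (age, weight) rows of a group from a sequence list.
group_records <- function(group, seqs) {
  ids <- vapply(seqs, `[[`, character(1), "mouse_id")
  sel <- seqs[ids %in% group$mouse_ids]
  if (!length(sel)) {
    return(data.frame(mouse_id = character(0), age = numeric(0),
                      weight = numeric(0)))
  }
  data.frame(
    mouse_id = rep(vapply(sel, `[[`, character(1), "mouse_id"),
                   vapply(sel, function(s) length(s$age), integer(1))),
    age = unlist(lapply(sel, `[[`, "age")),
    weight = unlist(lapply(sel, `[[`, "weight")),
    stringsAsFactors = FALSE
  )
}

#' Mean +/- SD weight curve of a trajectory group
#'
#' Ages are binned into `bin_width`-month bins centered on integer
#' multiples of the width (matching a monthly weighing cadence); bins with
#' fewer than `min_n` member mice are omitted. The SD is the sample
#' standard deviation over member weights in the bin.
#'
#' @param group A `trajectory_group`.
#' @param seqs The cohort's observation sequences.
#' @param min_n Minimum mice per bin (default 3).
#' @param bin_width Age bin width in months (default 1).
#' @return A data frame: `label`, `age_bin`, `n`, `mean`, `sd`.
#' @export
trajectory_curve <- function(group, seqs, min_n = 3, bin_width = 1) {
  rec <- group_records(group, seqs)
  if (!nrow(rec)) {
    return(data.frame(label = character(0), age_bin = numeric(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0)))
  }
  bin <- round(rec$age / bin_width) * bin_width
  # one value per mouse per bin (a mouse weighed twice in a bin contributes
  # its mean) so n counts mice, matching the minimum-3-mice rule
  key <- paste(rec$mouse_id, bin, sep = "\r")
  per_mouse <- tapply(rec$weight, key, mean)
  bins <- as.numeric(sub("^.*\r", "", names(per_mouse)))
  n <- tapply(rep(1, length(per_mouse)), bins, sum)
  m <- tapply(as.numeric(per_mouse), bins, mean)
  s <- tapply(as.numeric(per_mouse), bins, stats::sd)
  out <- data.frame(label = group$label, age_bin = as.numeric(names(n)),
                    n = as.integer(n), mean = as.numeric(m), sd = as.numeric(s),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$n >= min_n, , drop = FALSE]
  out[order(out$age_bin), , drop = FALSE]
}

#' Percent weight change of a group from a reference age to trajectory end
#'
#' Computes `100 * (m_end - m_ref) / m_ref`, where `m_ref` is the group
#' mean weight at the curve bin nearest `ref_age` (within `ref_window`
#' months) and `m_end` is the mean at the last bin satisfying the
#' minimum-mice rule. Negative values indicate loss. The default anchor of
#' 12 months marks the end of the growth phase (middle age).
#'
#' @param group A `trajectory_group`, or a curve data frame from
#'   [trajectory_curve()].
#' @param seqs Cohort sequences (ignored when a curve is supplied).
#' @param ref_age Reference age in months (default 12).
#' @param ref_window Maximum distance of the anchor bin from `ref_age`.
#' @param min_n,bin_width Passed to [trajectory_curve()].
#' @return Signed percent change, or `NA` with a `reason` attribute when no
#'   bin lies within the reference window or no later bin exists.
#' @export
percent_weight_change <- function(group, seqs = NULL, ref_age = 12,
                                  ref_window = 1, min_n = 3, bin_width = 1) {
  curve <- if (is.data.frame(group)) group else
    trajectory_curve(group, seqs, min_n = min_n, bin_width = bin_width)
  if (!nrow(curve)) {
    return(structure(NA_real_, reason = "empty curve"))
  }
  d <- abs(curve$age_bin - ref_age)
  if (min(d) > ref_window) {
    return(structure(NA_real_,
                     reason = sprintf("no curve bin within %g months of %g",
                                      ref_window, ref_age)))
  }
  ref_idx <- which.min(d)
  end_idx <- nrow(curve)
  if (end_idx <= ref_idx) {
    return(structure(NA_real_, reason = "no curve bin after the reference age"))
  }
  100 * (curve$mean[end_idx] - curve$mean[ref_idx]) / curve$mean[ref_idx]
}

#' Sex/genotype composition of trajectory groups
#'
#' @param grouping A `trajectory_grouping`.
#' @param seqs Cohort sequences.
#' @return A data frame with one row per (group, sex) x genotype count
#'   cell: `label`, `sex`, `genotype`, `n`.
#' @export
group_composition <- function(grouping, seqs) {
  ids <- vapply(seqs, `[[`, character(1), "mouse_id")
  sex <- vapply(seqs, `[[`, character(1), "sex")
  geno <- vapply(seqs, `[[`, character(1), "genotype")
  out <- lapply(grouping$groups, function(g) {
    sel <- ids %in% g$mouse_ids
    tab <- table(factor(sex[sel], SEX_LEVELS), factor(geno[sel], GENO_LEVELS))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("sex", "genotype", "n")
    cbind(label = g$label, df, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stationary distribution of a transition matrix
#'
#' Solves `nu A = nu`, `sum(nu) = 1` by eigen-decomposition of the
#' transpose. If the unit eigenvalue is not unique to numerical tolerance
#' (reducible or periodic chains, e.g. the identity matrix), the function
#' falls back to propagating `pi` through a long power of `A` and warns
#' that no unique stationary law exists.
#'
#' @param A Row-stochastic matrix.
#' @param pi Fallback initial distribution (default uniform).
#' @param tol Tolerance for eigenvalue uniqueness and the fixed-point
#'   residual.
#' @return A probability vector `nu` with `nu A = nu` when unique.
#' @export
stationary_distribution <- function(A, pi = NULL, tol = 1e-9) {
  check_stochastic_matrix(A, "A")
  n <- nrow(A)
  if (n == 1) return(1)
  pi <- pi %||% rep(1 / n, n)
  e <- eigen(t(A))
  ev <- e$values
  unit <- which(abs(ev - 1) < 1e-6)
  if (length(unit) != 1 || sum(abs(abs(ev) - 1) < 1e-6) > 1) {
    warnf("transition matrix has no unique stationary distribution; returning long-run occupancy from the supplied initial distribution")
    v <- pi
    for (i in seq_len(1024)) v <- as.numeric(v %*% A)
    return(v / sum(v))
  }
  v <- Re(e$vectors[, unit])
  v <- abs(v) / sum(abs(v))
  # polish with power iterations to the requested tolerance
  for (i in seq_len(10000)) {
    v2 <- as.numeric(v %*% A)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

#' Export trajectory groups and curves as CSV/JSON artifacts
#'
#' @param grouping A `trajectory_grouping`.
#' @param assignments Terminal-state assignments (for confidences).
#' @param curves Data frame of stacked [trajectory_curve()] outputs.
#' @param pct_changes Named numeric vector of percent changes per group.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_trajectory_artifacts <- function(grouping, assignments, curves,
                                       pct_changes, dir) {
  groups_csv <- file.path(dir, "groups.csv")
  assigned <- assignments
  assigned$assigned_group <- ifelse(
    assignments$mouse_id %in% unlist(lapply(grouping$groups, `[[`, "mouse_ids")),
    assignments$state, "unassigned")
  utils::write.csv(assigned, groups_csv, row.names = FALSE)
  curves_csv <- file.path(dir, "curves.csv")
  utils::write.csv(curves, curves_csv, row.names = FALSE)
  summary_json <- file.path(dir, "trajectory_summary.json")
  jsonlite::write_json(
    list(
      n_total = grouping$n_total,
      n_unassigned = length(grouping$unassigned),
      groups = lapply(grouping$groups, function(g) {
        list(label = g$label, n = g$n,
             percent_weight_change =
               if (g$label %in% names(pct_changes)) pct_changes[[g$label]] else NULL)
      })
    ),
    summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(groups_csv, curves_csv, summary_json))
}
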