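#' Construct a single observation sequence
#'
#' One mouse's static covariates plus its ordered (age, weight) measurement
#' sequence, the unit of data consumed by the model.
#'
#' @param mouse_id Identifier.
#' @param sex `"female"` or `"male"`.
#' @param genotype `"E3/3"`, `"E3/4"`, or `"E4/4"`.
#' @param age Strictly increasing ages at measurement, in months.
#' @param weight Positive weights, in grams, same length as `age`.
#' @return An object of class `observation_sequence`.
#' @export
observation_sequence <- function(mouse_id, sex, genotype, age, weight) {
  age <- as.numeric(age)
  weight <- as.numeric(weight)
  if (length(age) != length(weight) || length(age) < 1) {
    stopf("age and weight must be equal-length, non-empty vectors")
  }
  if (any(diff(age) <= 0)) stopf("ages must be strictly increasing (mouse %s)", mouse_id)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stopf("weights must be finite and positive (mouse %s)", mouse_id)
  }
  structure(
    list(mouse_id = as.character(mouse_id),
         sex = SEX_LEVELS[match_sex(sex)],
         genotype = GENO_LEVELS[match_genotype(genotype)],
         age = age, weight = weight),
    class = "observation_sequence"
  )
}

#' Convert a cohort to model-ready observation sequences
#'
#' Accepts either a list of `mouse_series` objects (see
#' [load_colony_table()]) or a long-format colony table with columns
#' `mouse_id`, `sex`, `genotype`, `age_months`, `weight_g`. Sequences
#' shorter than `min_len` measurements carry too little longitudinal signal
#' and are dropped with a warning.
#'
#' @param x Cohort (list of `mouse_series` or long-format data frame).
#' @param min_len Minimum sequence length retained (default 3).
#' @return A list of `observation_sequence` objects.
#' @export
as_observation_sequences <- function(x, min_len = 3) {
  seqs <- if (is.data.frame(x)) {
    need <- c("mouse_id", "sex", "genotype", "age_months", "weight_g")
    miss <- setdiff(need, names(x))
    if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
    lapply(split(x, x$mouse_id), function(d) {
      d <- d[order(d$age_months), , drop = FALSE]
      observation_sequence(d$mouse_id[1], d$sex[1], d$genotype[1],
                           d$age_months, d$weight_g)
    })
  } else {
    lapply(x, function(m) {
      observation_sequence(m$mouse_id, m$sex, m$genotype,
                           m$records$age_months, m$records$weight_g)
    })
  }
  keep <- vapply(seqs, function(s) length(s$age) >= min_len, logical(1))
  if (any(!keep)) {
    warnf("dropping %d sequence(s) with fewer than %d measurements",
          sum(!keep), min_len)
  }
  unname(seqs[keep])
}

# Flatten a list of sequences into parallel vectors with per-sequence index
# ranges; everything downstream (emission matrix, EM sufficient statistics)
# is vectorized over this stack.
build_stack <- function(seqs) {
  k <- vapply(seqs, function(s) length(s$age), integer(1))
  idx_end <- cumsum(k)
  idx_start <- idx_end - k + 1L
  age <- unlist(lapply(seqs, `[[`, "age"), use.names = FALSE)
  weight <- unlist(lapply(seqs, `[[`, "weight"), use.names = FALSE)
  prev_weight <- unlist(lapply(seqs, function(s) c(NA_real_, s$weight[-length(s$weight)])),
                        use.names = FALSE)
  is_first <- unlist(lapply(k, function(n) c(TRUE, rep(FALSE, n - 1L))),
                     use.names = FALSE)
  sex_idx <- rep(vapply(seqs, function(s) match_sex(s$sex), integer(1)), k)
  geno_idx <- rep(vapply(seqs, function(s) match_genotype(s$genotype), integer(1)), k)
  list(
    n_seq = length(seqs), k = k, idx_start = idx_start, idx_end = idx_end,
    n_obs = sum(k), age = age, weight = weight, prev_weight = prev_weight,
    is_first = is_first, male = as.numeric(sex_idx == 2L),
    sex_idx = sex_idx, geno_idx = geno_idx,
    mouse_ids = vapply(seqs, `[[`, character(1), "mouse_id")
  )
}
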