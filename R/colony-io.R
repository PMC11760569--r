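# Reading colony tables and applying the cohort exclusion rules.

COLONY_COLUMN_ALIASES <- list(
  mouse_id = c("mouse_id", "id", "mouse", "animal_id"),
  sex = c("sex"),
  genotype = c("genotype", "apoe", "apoe_genotype"),
  birth_date = c("birth_date", "dob", "date_of_birth"),
  death_date = c("death_date", "dod", "date_of_death"),
  death_cause = c("death_cause", "cause_of_death", "death_reason"),
  is_breeder = c("is_breeder", "breeder"),
  measurement_date = c("measurement_date", "date", "weigh_date", "collection_date"),
  weight_g = c("weight_g", "weight", "weight_grams"),
  age_months = c("age_months", "age")
)

match_colony_columns <- function(nms) {
  lower <- tolower(trimws(nms))
  out <- list()
  for (canon in names(COLONY_COLUMN_ALIASES)) {
    hit <- which(lower %in% COLONY_COLUMN_ALIASES[[canon]])
    if (length(hit)) out[[canon]] <- nms[hit[1]]
  }
  out
}

parse_date_col <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXt")) return(as.Date(x))
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  as.Date(x, format = "%Y-%m-%d")
}

#' Read a long-format colony table into per-mouse series
#'
#' Reads the standard colony layout (one row per weight measurement with
#' the mouse's static covariates repeated) from CSV or XLSX. Column names
#' are matched case-insensitively with common aliases (`id`, `weight`,
#' `date`, ...). Age is taken from an `age_months` column when present,
#' otherwise derived as `(measurement_date - birth_date) / 30.44` days.
#' Malformed rows (unparseable dates or weights, non-positive weight) are
#' collected into the returned report rather than silently dropped.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param format One of `"auto"` (by extension), `"csv"`, `"xlsx"`.
#' @return A list with `mice` (list of `mouse_series`: static fields plus a
#'   `records` data frame sorted by age) and `row_errors` (data frame of
#'   rejected input rows with reasons).
#' @export
load_colony_table <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stopf("reading XLSX requires the 'readxl' package; convert to CSV or install it")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  colony_from_table(raw)
}

#' Build per-mouse series from an in-memory colony table
#'
#' Same contract as [load_colony_table()] but starting from a data frame
#' (e.g. the output of [simulate_colony()]).
#'
#' @param raw Long-format colony data frame.
#' @return A list with `mice` and `row_errors` (see [load_colony_table()]).
#' @export
colony_from_table <- function(raw) {
  cols <- match_colony_columns(names(raw))
  required <- c("mouse_id", "sex", "genotype", "measurement_date", "weight_g")
  # age-only tables (no dates) are accepted when age_months is present
  if (!is.null(cols$age_months)) {
    required <- setdiff(required, "measurement_date")
  }
  miss <- setdiff(required, names(cols))
  if (length(miss)) {
    stopf("colony table is missing required column(s): %s",
          paste(miss, collapse = ", "))
  }
  n <- nrow(raw)
  get <- function(canon) if (is.null(cols[[canon]])) NULL else raw[[cols[[canon]]]]

  id <- as.character(get("mouse_id"))
  sex_raw <- get("sex")
  geno_raw <- get("genotype")
  bdate <- if (!is.null(get("birth_date"))) parse_date_col(get("birth_date")) else as.Date(rep(NA, n))
  ddate <- if (!is.null(get("death_date"))) parse_date_col(get("death_date")) else as.Date(rep(NA, n))
  dcause <- if (!is.null(get("death_cause"))) as.character(get("death_cause")) else rep(NA_character_, n)
  breeder <- if (!is.null(get("is_breeder"))) {
    b <- get("is_breeder")
    if (is.logical(b)) b else tolower(trimws(as.character(b))) %in% c("true", "1", "yes", "y")
  } else rep(FALSE, n)
  mdate <- if (!is.null(get("measurement_date"))) parse_date_col(get("measurement_date")) else as.Date(rep(NA, n))
  weight <- suppressWarnings(as.numeric(get("weight_g")))
  age <- if (!is.null(get("age_months"))) suppressWarnings(as.numeric(get("age_months"))) else rep(NA_real_, n)
  derived_age <- as.numeric(mdate - bdate) / MONTH_DAYS
  age <- ifelse(is.na(age), derived_age, age)

  bad_weight <- is.na(weight) | !is.finite(weight) | weight <= 0
  bad_age <- is.na(age) | !is.finite(age)
  row_errors <- data.frame(
    row = c(which(bad_weight), which(bad_age & !bad_weight)),
    mouse_id = id[c(which(bad_weight), which(bad_age & !bad_weight))],
    reason = c(rep("unparseable_weight", sum(bad_weight)),
               rep("unparseable_date_or_age", sum(bad_age & !bad_weight))),
    stringsAsFactors = FALSE
  )
  keep <- !(bad_weight | bad_age)

  mice <- lapply(split(which(keep), id[keep]), function(rows) {
    o <- rows[order(age[rows], mdate[rows])]
    structure(
      list(
        mouse_id = id[o[1]],
        sex = SEX_LEVELS[match_sex(sex_raw[o[1]])],
        genotype = GENO_LEVELS[match_genotype(geno_raw[o[1]])],
        birth_date = bdate[o[1]],
        death_date = ddate[o[1]],
        death_cause = dcause[o[1]],
        is_breeder = isTRUE(breeder[o[1]]),
        records = data.frame(
          measurement_date = mdate[o], age_months = age[o], weight_g = weight[o],
          stringsAsFactors = FALSE
        )
      ),
      class = "mouse_series"
    )
  })
  list(mice = unname(mice), row_errors = row_errors)
}

#' Preprocessing thresholds for cohort exclusion rules
#'
#' @param min_age_months Records at younger ages are dropped (default 5).
#' @param min_points Minimum remaining measurements per mouse (default 3).
#' @param max_monthly_loss Maximum tolerated fractional weight loss per
#'   month between consecutive measurements (default 0.20).
#' @param exclude_breeders Drop mice flagged as breeders (default TRUE).
#' @param min_gap_days Consecutive pairs closer than this many days are not
#'   evaluated for rapid loss (default 15): over very short gaps the
#'   per-month extrapolation of a small dip becomes unstable.
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_age_months = 5, min_points = 3,
                              max_monthly_loss = 0.20, exclude_breeders = TRUE,
                              min_gap_days = 15) {
  if (min_age_months < 0 || min_points < 1 || max_monthly_loss < 0 ||
      min_gap_days < 0) {
    stopf("preprocessing thresholds must be non-negative (min_points >= 1)")
  }
  structure(
    list(min_age_months = min_age_months, min_points = as.integer(min_points),
         max_monthly_loss = max_monthly_loss,
         exclude_breeders = isTRUE(exclude_breeders),
         min_gap_days = min_gap_days),
    class = "preprocess_config"
  )
}

# Monthly fractional loss between consecutive records of one mouse.
# Normalized to a 30.44-day month by the actual gap; pairs closer than
# min_gap_days are skipped.
monthly_loss_rates <- function(rec, min_gap_days) {
  k <- nrow(rec)
  if (k < 2) return(numeric(0))
  gap_days <- if (all(!is.na(rec$measurement_date))) {
    as.numeric(diff(rec$measurement_date))
  } else {
    diff(rec$age_months) * MONTH_DAYS
  }
  raw_loss <- -diff(rec$weight_g) / rec$weight_g[-k]
  rate <- raw_loss * (MONTH_DAYS / gap_days)
  rate[gap_days < min_gap_days] <- NA_real_
  rate
}

#' Apply the cohort exclusion rules
#'
#' Rules are applied in a fixed order: (1) breeders out (diet change
#' confound); (2) record-level date sanity - measurements dated before
#' birth or after death are dropped; (3) records at ages below
#' `min_age_months` are dropped; (4) mice with a normalized monthly weight
#' loss exceeding `max_monthly_loss` between consecutive remaining records
#' are excluded; (5) mice with fewer than `min_points` remaining records
#' are excluded. Record-level sanitation precedes the mouse-level counts so
#' the minimum-points rule applies to clean records only.
#'
#' @param mice List of `mouse_series` (from [load_colony_table()]).
#' @param rules A `preprocess_config`.
#' @return A list with `retained` (list of `mouse_series` with filtered
#'   records) and `report` (class `exclusion_report`): per-mouse and
#'   per-record exclusion reasons and a per-rule reconciliation of counts.
#' @export
apply_exclusions <- function(mice, rules = preprocess_config()) {
  if (!inherits(rules, "preprocess_config")) {
    rules <- do.call(preprocess_config, rules)
  }
  n0 <- length(mice)
  mouse_excl <- data.frame(mouse_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  rec_excl <- data.frame(mouse_id = character(0), visit = integer(0),
                         reason = character(0), stringsAsFactors = FALSE)
  stage_counts <- list()
  note_stage <- function(rule, n_mice, n_records) {
    stage_counts[[length(stage_counts) + 1]] <<- data.frame(
      rule = rule, n_mice = n_mice, n_records = n_records,
      stringsAsFactors = FALSE)
  }
  n_rec <- function(ms) sum(vapply(ms, function(m) nrow(m$records), integer(1)))
  note_stage("input", length(mice), n_rec(mice))

  # 1. breeders
  if (rules$exclude_breeders) {
    is_b <- vapply(mice, function(m) isTRUE(m$is_breeder), logical(1))
    if (any(is_b)) {
      mouse_excl <- rbind(mouse_excl, data.frame(
        mouse_id = vapply(mice[is_b], `[[`, character(1), "mouse_id"),
        reason = "breeder", stringsAsFactors = FALSE))
    }
    mice <- mice[!is_b]
  }
  note_stage("breeder", length(mice), n_rec(mice))

  # 2. record-level date sanity; 3. minimum-age records
  mice <- lapply(mice, function(m) {
    rec <- m$records
    visit <- seq_len(nrow(rec))
    bad_date <- rep(FALSE, nrow(rec))
    if (!is.na(m$birth_date)) {
      bad_date <- bad_date | (!is.na(rec$measurement_date) &
                                rec$measurement_date < m$birth_date)
    }
    if (!is.na(m$death_date)) {
      bad_date <- bad_date | (!is.na(rec$measurement_date) &
                                rec$measurement_date > m$death_date)
    }
    bad_date <- bad_date | rec$age_months < 0
    under <- !bad_date & rec$age_months < rules$min_age_months
    if (any(bad_date)) {
      rec_excl <<- rbind(rec_excl, data.frame(
        mouse_id = m$mouse_id, visit = visit[bad_date], reason = "date_error",
        stringsAsFactors = FALSE))
    }
    if (any(under)) {
      rec_excl <<- rbind(rec_excl, data.frame(
        mouse_id = m$mouse_id, visit = visit[under], reason = "under_age",
        stringsAsFactors = FALSE))
    }
    m$records <- rec[!(bad_date | under), , drop = FALSE]
    rownames(m$records) <- NULL
    m
  })
  note_stage("date_and_age_records", length(mice), n_rec(mice))

  # 4. rapid monthly loss
  rapid <- vapply(mice, function(m) {
    r <- monthly_loss_rates(m$records, rules$min_gap_days)
    any(!is.na(r) & r > rules$max_monthly_loss)
  }, logical(1))
  if (any(rapid)) {
    mouse_excl <- rbind(mouse_excl, data.frame(
      mouse_id = vapply(mice[rapid], `[[`, character(1), "mouse_id"),
      reason = "rapid_loss", stringsAsFactors = FALSE))
  }
  mice <- mice[!rapid]
  note_stage("rapid_loss", length(mice), n_rec(mice))

  # 5. minimum remaining points
  few <- vapply(mice, function(m) nrow(m$records) < rules$min_points, logical(1))
  if (any(few)) {
    mouse_excl <- rbind(mouse_excl, data.frame(
      mouse_id = vapply(mice[few], `[[`, character(1), "mouse_id"),
      reason = "too_few_points", stringsAsFactors = FALSE))
  }
  mice <- mice[!few]
  note_stage("min_points", length(mice), n_rec(mice))

  report <- structure(
    list(mouse_exclusions = mouse_excl, record_exclusions = rec_excl,
         stages = do.call(rbind, stage_counts),
         n_input = n0, n_retained = length(mice),
         rules = rules),
    class = "exclusion_report"
  )
  stopifnot(report$n_input == report$n_retained + nrow(mouse_excl))
  list(retained = mice, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d mice in, %d retained, %d excluded\n",
              x$n_input, x$n_retained, nrow(x$mouse_exclusions)))
  if (nrow(x$mouse_exclusions)) {
    print(table(x$mouse_exclusions$reason))
  }
  cat("Per-rule counts:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Write an exclusion report as CSV (per-mouse reasons) plus JSON (full)
#' @param report An `exclusion_report`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_exclusion_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$mouse_exclusions, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(mouse_exclusions = report$mouse_exclusions,
         record_exclusions = report$record_exclusions,
         stages = report$stages, n_input = report$n_input,
         n_retained = report$n_retained,
         rules = unclass(report$rules)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' Summarize an analysis-ready cohort
#'
#' @param mice Non-empty list of `mouse_series`.
#' @param bin_width Age bin width in months for the weight summary curves.
#' @return A list of class `cohort_summary`: mouse and datapoint counts,
#'   sex and genotype percentages, counts of mice weighed more than 5 and
#'   more than 10 times, and mean +/- SD weight per age bin overall and by
#'   sex.
#' @export
summarize_cohort <- function(mice, bin_width = 1) {
  if (!length(mice)) stopf("cohort is empty")
  ids <- vapply(mice, `[[`, character(1), "mouse_id")
  sex <- vapply(mice, `[[`, character(1), "sex")
  geno <- vapply(mice, `[[`, character(1), "genotype")
  npts <- vapply(mice, function(m) nrow(m$records), integer(1))
  age <- unlist(lapply(mice, function(m) m$records$age_months))
  weight <- unlist(lapply(mice, function(m) m$records$weight_g))
  sex_rec <- rep(sex, npts)
  bin <- round(age / bin_width) * bin_width
  curve <- function(b, w) {
    agg_n <- tapply(w, b, length)
    data.frame(age_bin = as.numeric(names(agg_n)), n = as.integer(agg_n),
               mean = as.numeric(tapply(w, b, mean)),
               sd = as.numeric(tapply(w, b, stats::sd)),
               row.names = NULL)
  }
  by_sex <- do.call(rbind, lapply(SEX_LEVELS, function(s) {
    sel <- sex_rec == s
    if (!any(sel)) return(NULL)
    cbind(sex = s, curve(bin[sel], weight[sel]))
  }))
  structure(
    list(
      n_mice = length(mice), n_datapoints = sum(npts),
      sex_pct = 100 * prop.table(table(factor(sex, SEX_LEVELS))),
      genotype_pct = 100 * prop.table(table(factor(geno, GENO_LEVELS))),
      n_weighed_gt5 = sum(npts > 5), n_weighed_gt10 = sum(npts > 10),
      pct_weighed_gt5 = 100 * mean(npts > 5),
      pct_weighed_gt10 = 100 * mean(npts > 10),
      weight_curve = curve(bin, weight),
      weight_curve_by_sex = by_sex
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d mice, %d datapoints\n", x$n_mice, x$n_datapoints))
  cat(sprintf("Sex: %.0f%% female / %.0f%% male; genotypes: %s\n",
              x$sex_pct[["female"]], x$sex_pct[["male"]],
              paste(sprintf("%s %.0f%%", names(x$genotype_pct), x$genotype_pct),
                    collapse = ", ")))
  cat(sprintf("Weighed >5 times: %d (%.0f%%); >10 times: %d (%.0f%%)\n",
              x$n_weighed_gt5, x$pct_weighed_gt5,
              x$n_weighed_gt10, x$pct_weighed_gt10))
  invisible(x)
}
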