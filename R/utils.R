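# Internal constants and helpers shared across modules.

SEX_LEVELS <- c("female", "male")
GENO_LEVELS <- c("E3/3", "E3/4", "E4/4")

# Mean Gregorian month, used to convert day differences to months.
MONTH_DAYS <- 30.44

# Sentinel for log(0): emission log-densities are clamped here so that chain
# inference sees an effectively impossible observation without propagating
# -Inf through arithmetic.
LOG_ZERO <- -1e10

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive independent sub-seeds from a master seed
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Floor a non-negative vector and renormalize to sum 1
#' @noRd
floor_normalize <- function(p, floor = 1e-12) {
  p <- pmax(p, floor)
  p / sum(p)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob_vector <- function(p, name, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < -tol)) {
    stopf("'%s' must be a non-negative probability vector", name)
  }
  if (abs(sum(p) - 1) > max(tol, 1e-8)) {
    stopf("'%s' must sum to 1 (got %.12f)", name, sum(p))
  }
  invisible(TRUE)
}

check_stochastic_matrix <- function(A, name = "A", tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stopf("'%s' must be a square matrix", name)
  }
  if (any(!is.finite(A)) || any(A < -1e-12)) {
    stopf("'%s' must have finite non-negative entries", name)
  }
  rs <- rowSums(A)
  if (any(abs(rs - 1) > tol)) {
    stopf("rows of '%s' must sum to 1 (max deviation %.3e)", name, max(abs(rs - 1)))
  }
  invisible(TRUE)
}

# FNV-1a hash of a character scalar; used to stamp pipeline artifacts with a
# reproducible configuration fingerprint without an external digest dependency.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

match_sex <- function(sex) {
  idx <- match(tolower(as.character(sex)), SEX_LEVELS)
  if (any(is.na(idx))) {
    bad <- unique(as.character(sex)[is.na(idx)])
    stopf("unrecognized sex value(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(SEX_LEVELS, collapse = "/"))
  }
  idx
}

match_genotype <- function(genotype) {
  g <- toupper(gsub("\\s", "", as.character(genotype)))
  g <- sub("^APOE", "E", g)
  idx <- match(g, GENO_LEVELS)
  if (any(is.na(idx))) {
    bad <- unique(as.character(genotype)[is.na(idx)])
    stopf("unrecognized APOE genotype value(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(GENO_LEVELS, collapse = ", "))
  }
  idx
}
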