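# Internal helpers shared across the package.

#' Gauss error function
#'
#' `erf(x)` expressed through the normal CDF, used by the clustering
#' coefficient soft threshold.
#'
#' @param x numeric vector.
#' @return numeric vector of erf values in (-1, 1).
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Round a percentage half away from zero
#'
#' Integer percentage with ties rounded away from zero (so 78.5 -> 79),
#' the convention used for all cohort summary percentages.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @return integer percentage.
#' @export
percent_round <- function(count, total) {
  stopifnot(length(count) == length(total) || length(total) == 1L)
  if (any(total <= 0)) stop("percentage denominator must be positive")
  p <- 100 * count / total
  as.integer(trunc(p + 0.5 * sign(p)))
}

# Population (1/n) variance and sd; the z-normalization convention.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards. seed = NULL leaves RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
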