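#' Evaluate code under a fixed RNG seed, restoring the RNG state afterwards
#'
#' All stochastic operations in the package (rarefaction, permutation tests,
#' community detection, simulation) funnel their `seed` argument through this
#' helper so that a call with `seed = NULL` leaves the session RNG untouched
#' and a call with an integer seed is bit-reproducible and side-effect free.
#'
#' @param seed integer seed or `NULL` (use the current RNG stream).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' One master seed drives every stochastic pipeline stage; each stage gets a
#' distinct, reproducible sub-seed derived from the stage name so that adding
#' or reordering stages does not perturb the streams of the others. Kept
#' strictly below 2^31 so the result is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stage stage name, e.g. `"rarefy"`.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master))
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.double(master)) * 31 + h * 7919) %% 2147483647)
}

#' Percentage of a count over a total, rounded to two decimals
#'
#' Uses round-half-even (the behaviour of [round()]), the convention used for
#' every percentage the package prints.
#'
#' @param count numerator count(s).
#' @param total denominator total.
#' @return numeric percentage(s) on the 0--100 scale, 2 decimal places.
#' @export
pct <- function(count, total) {
  if (any(total <= 0)) stop("`total` must be positive", call. = FALSE)
  round(100 * count / total, 2)
}

#' Significance stars for a p-value
#'
#' `ns` for p > 0.05, `*` for 0.01 < p <= 0.05, `**` for 0.001 < p <= 0.01,
#' `***` for p <= 0.001.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return character vector of star labels.
#' @export
star_label <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "***" else if (pi <= 0.01) "**" else if (pi <= 0.05) "*" else "ns"
  }, character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Enumerate all distinct permutations of a label multiset
#'
#' Used by the exact (complete-enumeration) mode of the permutation tests.
#' The number of distinct arrangements is the multinomial coefficient of the
#' label counts; enumeration is refused above `limit`.
#'
#' @param labels vector of group labels.
#' @param limit maximum number of arrangements to enumerate.
#' @return matrix with one arrangement per row.
#' @keywords internal
multiset_permutations <- function(labels, limit = 50000L) {
  labels <- as.character(labels)
  counts <- table(labels)
  n_arr <- exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1)))
  if (n_arr > limit) {
    stop(sprintf(
      "exact enumeration would require %.0f arrangements (limit %d); use random permutations",
      n_arr, limit
    ), call. = FALSE)
  }
  rec <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    out <- lapply(unique(v), function(a) {
      cbind(a, rec(v[-match(a, v)]), deparse.level = 0)
    })
    do.call(rbind, out)
  }
  rec(labels)
}
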