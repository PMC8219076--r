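# Per-sample richness and diversity estimators, plus between-group tests.
# Conventions: Shannon uses the natural log; Simpson is reported as the
# unbiased dominance D = sum n_i(n_i - 1) / (N(N - 1)), so LOWER values mean
# MORE diverse communities; Chao1 uses the bias-corrected (+1) denominator.

#' Good's coverage of a sample
#'
#' `1 - F1/N` where `F1` is the number of singleton taxa and `N` the total
#' read count: the estimated fraction of the community captured.
#'
#' @param counts integer vector of per-taxon counts for one sample.
#' @return coverage in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  counts <- check_sample_counts(counts)
  n <- sum(counts)
  if (n < 1) stop("empty sample", call. = FALSE)
  1 - sum(counts == 1) / n
}

#' Chao1 richness estimate (bias-corrected)
#'
#' `S_obs + F1(F1 - 1) / (2 (F2 + 1))` with `F1`, `F2` the singleton and
#' doubleton counts. The +1 in the denominator keeps the estimator defined
#' when no doubletons are observed.
#'
#' @param counts integer vector of per-taxon counts for one sample.
#' @return estimate, always at least the observed richness.
#' @export
chao1 <- function(counts) {
  counts <- check_sample_counts(counts)
  if (sum(counts) < 1) stop("empty sample", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimate
#'
#' Abundance-based coverage estimator with the standard rare/abundant split
#' at `rare_cutoff` reads: `S_abund + S_rare / C_ace + (F1 / C_ace) gamma^2`,
#' where `C_ace = 1 - F1 / N_rare` is the sample coverage of the rare class
#' and `gamma^2` the coefficient-of-variation correction (floored at 0).
#' When every rare read is a singleton, `C_ace = 0` and the estimator is
#' undefined; the function then falls back to [chao1()] and flags the value
#' with attribute `chao1_fallback = TRUE`.
#'
#' @param counts integer vector of per-taxon counts for one sample.
#' @param rare_cutoff maximum count of a "rare" taxon (default 10).
#' @return estimate, with attribute `chao1_fallback`.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- check_sample_counts(counts)
  if (sum(counts) < 1) stop("empty sample", call. = FALSE)
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) {
    return(structure(s_abund, chao1_fallback = FALSE))
  }
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    return(structure(chao1(counts), chao1_fallback = TRUE))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  gamma2 <- max(
    (s_rare / c_ace) * sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fi) /
      (n_rare * (n_rare - 1)) - 1,
    0
  )
  structure(s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2,
            chao1_fallback = FALSE)
}

#' Shannon diversity index
#'
#' `-sum p_i log(p_i)` over taxa with positive counts; natural log by
#' default.
#'
#' @param counts integer vector of per-taxon counts for one sample.
#' @param base logarithm base (default `exp(1)`).
#' @return non-negative diversity value.
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_sample_counts(counts)
  if (sum(counts) < 1) stop("empty sample", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Simpson dominance index
#'
#' Unbiased repeat probability `D = sum n_i(n_i - 1) / (N(N - 1))`: the
#' chance that two reads drawn without replacement belong to the same taxon.
#' Lower values indicate more diverse communities.
#'
#' @param counts integer vector of per-taxon counts for one sample.
#' @return dominance in \[0, 1\].
#' @export
simpson <- function(counts) {
  counts <- check_sample_counts(counts)
  n <- sum(counts)
  if (n < 2) stop("Simpson dominance needs at least 2 reads", call. = FALSE)
  sum(counts * (counts - 1)) / (n * (n - 1))
}

check_sample_counts <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("sample counts must be non-negative integers", call. = FALSE)
  }
  as.numeric(round(counts))
}

#' Alpha-diversity table for every sample
#'
#' @param table count table (typically rarefied).
#' @param rare_cutoff ACE rare/abundant cutoff.
#' @param base Shannon log base.
#' @return data frame with one row per sample: `sample_id`, `observed`,
#'   `coverage`, `chao1`, `ace`, `ace_chao1_fallback`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(table, rare_cutoff = 10, base = exp(1)) {
  x <- as_count_table(table)
  rows <- lapply(colnames(x), function(s) {
    v <- x[, s]
    a <- ace(v, rare_cutoff = rare_cutoff)
    data.frame(
      sample_id = s,
      observed = sum(v > 0),
      coverage = goods_coverage(v),
      chao1 = chao1(v),
      ace = as.numeric(a),
      ace_chao1_fallback = isTRUE(attr(a, "chao1_fallback")),
      shannon = shannon(v, base = base),
      simpson = simpson(v),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# H statistic of the Kruskal-Wallis test with midranks and tie correction;
# shared by the asymptotic and exact-permutation paths.
kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0) # every observation tied at one value
  h / corr
}

#' Univariate between-group test of an alpha-diversity measure
#'
#' Student's t-test (two groups, equal-variance), one-way ANOVA, or
#' Kruskal--Wallis with midranks and tie correction. Significance stars
#' follow the usual thresholds (see [star_label()]). When every observation
#' is constant within groups the parametric tests are degenerate; the
#' contract is p = 1 for equal group means and p = 0 otherwise.
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels aligned with `values`.
#' @param test one of `"t"`, `"anova"`, `"kruskal"`.
#' @param exact for `"kruskal"`, compute the p-value by complete enumeration
#'   of the label assignments instead of the chi-square approximation.
#' @return data frame with `statistic_name`, `statistic`, `p_value`,
#'   `groups`, `star`.
#' @export
group_test <- function(values, groups, test = c("t", "anova", "kruskal"),
                       exact = FALSE) {
  test <- match.arg(test)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (test %in% c("t", "anova") && any(sizes < 2)) {
    stop("each group needs at least two values for t/ANOVA", call. = FALSE)
  }
  if (test == "t" && length(sizes) != 2) {
    stop("the t-test compares exactly two groups", call. = FALSE)
  }

  zero_var <- all(tapply(values, groups, function(v) stats::var(v) == 0))
  if (test %in% c("t", "anova") && zero_var) {
    means <- tapply(values, groups, mean)
    equal <- max(means) - min(means) < 1e-12
    res <- data.frame(
      statistic_name = if (test == "t") "t" else "F",
      statistic = if (equal) 0 else Inf,
      p_value = if (equal) 1 else 0,
      groups = paste(names(sizes), collapse = " vs "),
      stringsAsFactors = FALSE
    )
    res$star <- star_label(res$p_value)
    return(res)
  }

  if (test == "t") {
    ht <- stats::t.test(values ~ factor(groups), var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value; name <- "t"
  } else if (test == "anova") {
    ht <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value; name <- "F"
  } else {
    if (length(unique(values)) == 1L) {
      stat <- 0; p <- 1
    } else {
      stat <- kruskal_h(values, groups)
      if (exact) {
        perms <- multiset_permutations(groups)
        hs <- apply(perms, 1, function(g) kruskal_h(values, g))
        p <- mean(hs >= stat - 1e-12)
      } else {
        p <- stats::kruskal.test(values, factor(groups))$p.value
      }
    }
    name <- "H"
  }
  res <- data.frame(statistic_name = name, statistic = stat, p_value = p,
                    groups = paste(names(sizes), collapse = " vs "),
                    stringsAsFactors = FALSE)
  res$star <- star_label(res$p_value)
  res
}
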