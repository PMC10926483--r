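# Nonparametric group comparisons for consumption, spontaneous-behavior and
# expression-style tables: Kruskal-Wallis with tie-corrected H, Mann-Whitney
# U post hocs, Bonferroni adjustment. Thin, tidy-output wrappers around the
# standard tests.

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic on midranks with a chi-square reference on
#' g - 1 degrees of freedom.
#'
#' @param value numeric observations.
#' @param group group label per observation (>= 2 non-empty groups).
#' @param p_method `"chisq"` (default) for the asymptotic chi-square
#'   reference, or `"permutation"` for a Monte-Carlo permutation p-value,
#'   preferable at small sample sizes where the chi-square approximation is
#'   rough.
#' @param n_perm permutations for `p_method = "permutation"`.
#' @param seed optional seed for the permutation draw.
#' @return one-row data.frame: `method`, `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(value, group, p_method = c("chisq", "permutation"),
                           n_perm = 10000, seed = NULL) {
  p_method <- match.arg(p_method)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop_invalid("need at least 2 non-empty groups")
  if (length(value) < 3L) stop_invalid("need total n >= 3")
  df <- nlevels(droplevels(group)) - 1L
  if (length(unique(value)) == 1L) {
    # all observations identical: no evidence of any group difference
    return(data.frame(method = "kruskal_wallis", statistic = 0,
                      df = df, p_value = 1))
  }
  kt <- stats::kruskal.test(value, group)
  p <- kt$p.value
  if (p_method == "permutation") {
    h_obs <- unname(kt$statistic)
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i)
        unname(stats::kruskal.test(value, sample(group))$statistic),
        numeric(1)) >= h_obs - 1e-12)
    })
    p <- (1 + exceed) / (n_perm + 1)
  }
  data.frame(method = paste0("kruskal_wallis_", p_method),
             statistic = unname(kt$statistic),
             df = df, p_value = p)
}

#' Mann-Whitney U test
#'
#' Midrank U statistic. The p-value is exact (full enumeration) when both
#' samples are tie-free and `na * nb <= exact_limit`; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_limit largest `na * nb` for which the exact path is taken.
#' @return one-row data.frame: `method`, `statistic` (U for sample `a`),
#'   `p_value`, `exact` (logical).
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less", "greater"),
                           exact_limit = 400) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L)
    stop_invalid("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) * length(b) <= exact_limit
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  data.frame(method = "mann_whitney_u", statistic = unname(wt$statistic),
             p_value = wt$p.value, exact = exact)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size `m` and caps at 1.
#'
#' @param p numeric p-values.
#' @param m family size (defaults to `length(p)`; must be >= `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop_invalid("m must be >= length(p)")
  pmin(1, p * m)
}

#' Pairwise Mann-Whitney comparisons with Bonferroni correction
#'
#' Runs [mann_whitney_u()] for every contrast of each treatment level against
#' the reference level (or all pairs when `ref` is `NULL`) and Bonferroni
#' adjusts over the family of comparisons performed.
#'
#' @param value numeric observations.
#' @param group group label per observation.
#' @param ref reference level to contrast against, or `NULL` for all pairs.
#' @return data.frame with one row per contrast: `group1`, `group2`,
#'   `statistic`, `p_value`, `p_adjusted`, `m`.
#' @export
pairwise_mann_whitney <- function(value, group, ref = NULL) {
  group <- as.factor(group)
  lev <- levels(droplevels(group))
  pairs <- if (is.null(ref)) utils::combn(lev, 2L, simplify = FALSE)
           else lapply(setdiff(lev, ref), function(g) c(ref, g))
  rows <- lapply(pairs, function(pr) {
    res <- mann_whitney_u(value[group == pr[1L]], value[group == pr[2L]])
    data.frame(group1 = pr[1L], group2 = pr[2L],
               statistic = res$statistic, p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_value, nrow(out))
  out$m <- nrow(out)
  out
}
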