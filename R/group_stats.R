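#' Normality-gated two-group comparison
#'
#' The comparison protocol used for all two-condition contrasts: each group
#' is first tested for normality with Shapiro-Wilk; if both groups pass
#' (p >= `alpha_normality`), an unpaired two-tailed Student's t test (pooled
#' variance) is used, otherwise a Mann-Whitney U test (exact when the
#' smaller group has <= 8 observations and there are no ties, normal
#' approximation with tie and continuity correction otherwise).
#'
#' @param a,b numeric vectors, each with >= 3 observations.
#' @param alpha_normality significance level of the normality gate
#'   (default 0.05).
#' @param test `"auto"` applies the gate; `"t"` or `"mann_whitney"` force a
#'   branch.
#' @param welch use the Welch (unequal-variance) t test instead of the
#'   pooled Student's t.
#' @return An object of class `group_comparison`: a one-row tibble with
#'   `test_name` (`"t_test_two_tailed"` or `"mann_whitney_u"`),
#'   `statistic`, `p_value`, `n_a`, `n_b`, `normality_p_a`,
#'   `normality_p_b`.
#' @examples
#' compare_two_groups(rnorm(10), rnorm(10, 1))
#' @export
compare_two_groups <- function(a, b, alpha_normality = 0.05,
                               test = c("auto", "t", "mann_whitney"),
                               welch = FALSE) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop_bad("each group needs >= 3 observations (normality test undefined below 3)")
  sw_a <- stats::shapiro.test(a)$p.value
  sw_b <- stats::shapiro.test(b)$p.value
  use_t <- switch(test,
                  auto = sw_a >= alpha_normality && sw_b >= alpha_normality,
                  t = TRUE, mann_whitney = FALSE)
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = !welch,
                        alternative = "two.sided")
    name <- "t_test_two_tailed"
  } else {
    pooled <- c(a, b)
    exact <- min(length(a), length(b)) <= 8L &&
      !any(duplicated(pooled))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    name <- "mann_whitney_u"
  }
  out <- tibble(test_name = name,
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                n_a = length(a), n_b = length(b),
                normality_p_a = sw_a, normality_p_b = sw_b)
  class(out) <- c("group_comparison", class(out))
  out
}

#' One-way ANOVA across three or more groups
#'
#' Fixed-effects one-way ANOVA with F on `(k - 1, N - k)` degrees of
#' freedom; groups may have unequal sizes.
#'
#' @param groups list of >= 3 numeric vectors, each with >= 2 observations.
#' @return An object of class `group_comparison`: one-row tibble with
#'   `test_name = "one_way_anova"`, `statistic` (F), `p_value`, `df1`,
#'   `df2` and the group sizes packed as a list column `n`.
#' @export
compare_multi_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop_bad("need >= 3 groups; use compare_two_groups() for 2 conditions")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop_bad("each group needs >= 2 observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  out <- tibble(test_name = "one_way_anova",
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                df1 = unname(ht$parameter[1]),
                df2 = unname(ht$parameter[2]),
                n = list(as.integer(sizes)))
  class(out) <- c("group_comparison", class(out))
  out
}

#' Tidy / glance methods for group comparisons
#'
#' Both return the comparison as a plain tibble; `glance()` keeps only the
#' test name, statistic and p value.
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "group_comparison")
  as_tibble(out)
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tidy.group_comparison(x)[, c("test_name", "statistic", "p_value")]
}
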