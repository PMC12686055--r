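#' Compare two groups of per-neuron measurements
#'
#' The comparisons used for per-neuron metrics in this workflow: Welch
#' two-sample t-test (pooled-variance optional), Mann-Whitney U with exact
#' enumeration for small samples, Wilcoxon signed-rank of one group against
#' a hypothetical value (1 for baseline-normalized cluster areas), and
#' Kruskal-Wallis for more than two groups (pass a list via `values_a`).
#'
#' The Mann-Whitney p-value is computed by exact enumeration over all
#' assignments of the pooled observations to the two groups whenever the
#' smaller group has at most 8 observations (midranks handle ties), and by
#' the normal approximation with tie correction otherwise. The signed-rank
#' test vs the hypothetical value enumerates all sign patterns exactly for
#' n <= 15 (zeros dropped, midranks for tied magnitudes).
#'
#' @param values_a Numeric vector (or list of vectors for
#'   `"kruskal_wallis"`).
#' @param values_b Numeric vector; ignored for the one-sample signed-rank
#'   test.
#' @param test `"t"`, `"mann_whitney_u"`, `"wilcoxon_signed_rank_vs_1"` or
#'   `"kruskal_wallis"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param mu Hypothetical value for the signed-rank test (default 1).
#' @return Object of class `test_result`: `test`, `statistic`, `p_value`,
#'   `summaries` (per-group mean, sem, median, IQR), `alternative`.
#' @examples
#' compare_groups(c(1, 2), c(3, 4), test = "mann_whitney_u",
#'                alternative = "less")$p_value  # 1/6
#' @export
compare_groups <- function(values_a, values_b = NULL,
                           test = c("t", "mann_whitney_u",
                                    "wilcoxon_signed_rank_vs_1",
                                    "kruskal_wallis"),
                           alternative = c("two.sided", "less", "greater"),
                           var_equal = FALSE, mu = 1) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (test == "kruskal_wallis") {
    groups <- if (is.list(values_a)) values_a else list(values_a, values_b)
    kt <- stats::kruskal.test(groups)
    return(new_test_result(test, unname(kt$statistic), kt$p.value,
                           groups, "two.sided"))
  }
  if (test == "wilcoxon_signed_rank_vs_1") {
    stopifnot(is.numeric(values_a), length(values_a) >= 1L)
    res <- signed_rank_exact(values_a, mu = mu, alternative = alternative)
    return(new_test_result(test, res$statistic, res$p_value,
                           list(a = values_a), alternative, mu = mu))
  }
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) >= 2L, length(values_b) >= 2L)
  if (test == "t") {
    tt <- stats::t.test(values_a, values_b, alternative = alternative,
                        var.equal = var_equal)
    return(new_test_result(test, unname(tt$statistic), tt$p.value,
                           list(a = values_a, b = values_b), alternative))
  }
  res <- mann_whitney_u(values_a, values_b, alternative = alternative)
  new_test_result(test, res$statistic, res$p_value,
                  list(a = values_a, b = values_b), alternative,
                  exact = res$exact)
}

new_test_result <- function(test, statistic, p_value, groups, alternative, ...) {
  summaries <- lapply(groups, function(v) {
    list(n = length(v), mean = mean(v), sem = sd(v) / sqrt(length(v)),
         median = median(v), iqr = unname(quantile(v, c(0.25, 0.75))))
  })
  structure(
    list(test = test, statistic = statistic, p_value = p_value,
         summaries = summaries, alternative = alternative, ...),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$alternative))
  invisible(x)
}

# U statistic for sample a vs b, with 0.5 credit for ties.
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (direction of
#'   `a` relative to `b`).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default enumerates when `min(n) <= 8` and the number of group
#'   assignments is manageable.
#' @return List with `statistic` (U for `a`), `p_value`, `exact`.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  n1 <- length(a); n2 <- length(b)
  u <- u_statistic(a, b)
  if (is.null(exact)) {
    exact <- min(n1, n2) <= 8L && choose(n1 + n2, n1) <= 5e5
  }
  if (exact) {
    pooled <- c(a, b)
    r <- rank(pooled)
    sets <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(us <= u)
    p_ge <- mean(us >= u)
  } else {
    # normal approximation with tie correction
    r <- rank(c(a, b))
    n <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    mu_u <- n1 * n2 / 2
    z_le <- (u + 0.5 - mu_u) / sigma   # continuity-corrected
    z_ge <- (u - 0.5 - mu_u) / sigma
    p_le <- stats::pnorm(z_le)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
  }
  p <- switch(alternative,
    less = p_le, greater = p_ge,
    two.sided = min(1, 2 * min(p_le, p_ge))
  )
  list(statistic = u, p_value = p, exact = exact)
}

#' Wilcoxon signed-rank test against a hypothetical value
#'
#' Tests whether paired-normalized values differ from a hypothetical value
#' (1 for a cluster-area series normalized to its own pre-treatment
#' baseline). Zero differences are dropped; tied absolute differences get
#' midranks; for n <= `max_exact` the null distribution is enumerated over
#' all 2^n sign patterns, otherwise the normal approximation with tie
#' correction is used.
#'
#' @param x Numeric vector.
#' @param mu Hypothetical value, default 1.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param max_exact Largest n for exact sign-flip enumeration.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `exact`, `n_used`.
#' @export
signed_rank_exact <- function(x, mu = 1,
                              alternative = c("two.sided", "less", "greater"),
                              max_exact = 15L) {
  alternative <- match.arg(alternative)
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all values equal the hypothetical value", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= max_exact) {
    # enumerate all sign patterns: distribution of V under the null
    vs <- 0
    for (i in seq_len(n)) {
      vs <- c(vs, vs + r[i])  # running convolution over sign choices
    }
    p_le <- mean(vs <= v)
    p_ge <- mean(vs >= v)
    exact <- TRUE
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    p_le <- stats::pnorm((v + 0.5 - mu_v) / sigma)
    p_ge <- stats::pnorm((v - 0.5 - mu_v) / sigma, lower.tail = FALSE)
    exact <- FALSE
  }
  p <- switch(alternative,
    less = p_le, greater = p_ge,
    two.sided = min(1, 2 * min(p_le, p_ge))
  )
  list(statistic = v, p_value = p, exact = exact, n_used = n)
}

#' Two-way factorial ANOVA with Type II sums of squares
#'
#' For factorial designs such as treatment x time. Uses Type II sums of
#' squares via `car::Anova` when available, falling back to sequential
#' (Type I) `stats::anova` otherwise.
#'
#' @param data Data frame.
#' @param formula Model formula, e.g. `value ~ treatment * time`.
#' @return A data frame of effects with `sum_sq`, `df`, `statistic`,
#'   `p_value`.
#' @export
anova_two_way <- function(data, formula) {
  fit <- stats::lm(formula, data = data)
  if (requireNamespace("car", quietly = TRUE)) {
    tab <- car::Anova(fit, type = 2)
    out <- data.frame(effect = rownames(tab), sum_sq = tab[["Sum Sq"]],
                      df = tab[["Df"]], statistic = tab[["F value"]],
                      p_value = tab[["Pr(>F)"]])
  } else {
    tab <- stats::anova(fit)
    out <- data.frame(effect = rownames(tab), sum_sq = tab[["Sum Sq"]],
                      df = tab[["Df"]], statistic = tab[["F value"]],
                      p_value = tab[["Pr(>F)"]])
  }
  tibble::as_tibble(out)
}
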