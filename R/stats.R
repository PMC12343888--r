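# Significance machinery applied to endpoint tables.  The t and F statistics
# are computed from their textbook formulas so small printed tables can be
# checked by hand; distribution functions come from base R.

#' Two-sample t test (pooled or Welch)
#'
#' The two-tailed unpaired t test: pooled-variance by default (Student's
#' form), with a Welch option.  When both groups have zero variance and
#' equal means the p value is 1 by convention.
#'
#' @param x,y numeric samples, each of length >= 2
#' @param variance_mode `"pooled"` or `"welch"`
#' @return a `TestResult` list: `statistic`, `degrees_of_freedom`,
#'   `p_value`, `test_name`, `group_ns`
#' @export
t_test_two_sample <- function(x, y, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / (nx - 1)
  vy <- sum((y - my)^2) / (ny - 1)
  if (vx == 0 && vy == 0) {
    if (mx == my)
      return(list(statistic = 0, degrees_of_freedom = nx + ny - 2,
                  p_value = 1,
                  test_name = paste0("two-sample t (", variance_mode, ")"),
                  group_ns = c(nx, ny)))
    stop("zero variance in both groups with unequal means")
  }
  if (variance_mode == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  stat <- (mx - my) / se
  list(statistic = stat, degrees_of_freedom = df,
       p_value = 2 * pt(-abs(stat), df),
       test_name = paste0("two-sample t (", variance_mode, ")"),
       group_ns = c(nx, ny))
}

#' One-way ANOVA with Tukey's pairwise comparisons
#'
#' The F statistic is the between-group over within-group mean square;
#' pairwise comparisons use the studentized-range distribution
#' (Tukey-Kramer for unequal group sizes).
#'
#' @param groups list of >= 3 numeric samples, each of length >= 2
#' @return a `TestResult` list: `statistic` (F), `degrees_of_freedom`
#'   (`c(between, within)`), `p_value`, `test_name`, `group_ns`, plus
#'   `tukey` (data frame `group1`, `group2`, `diff`, `p_adj`)
#' @export
anova_oneway_tukey <- function(groups) {
  k <- length(groups)
  if (k < 3) stop("fewer than 3 groups: use t_test_two_sample")
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1
  df_w <- N - k
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  F_stat <- ms_b / ms_w
  pairs <- utils::combn(k, 2)
  tk <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[j] - means[i]
    se <- sqrt(ms_w / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(diff) / se
    c(i, j, diff, ptukey(q, k, df_w, lower.tail = FALSE))
  })
  names_g <- names(groups)
  if (is.null(names_g)) names_g <- paste0("g", seq_len(k))
  list(statistic = F_stat, degrees_of_freedom = c(between = df_b,
                                                  within = df_w),
       p_value = pf(F_stat, df_b, df_w, lower.tail = FALSE),
       test_name = "one-way ANOVA",
       group_ns = ns,
       tukey = data.frame(group1 = names_g[tk[1, ]],
                          group2 = names_g[tk[2, ]],
                          diff = tk[3, ], p_adj = tk[4, ]))
}

#' Trapezoidal area under a curve
#'
#' \eqn{\sum_i \tfrac12 (v_i + v_{i+1}) (t_{i+1} - t_i)}; linear in the
#' values and additive over adjacent time intervals.
#'
#' @param values numeric vector
#' @param times strictly increasing numeric vector of equal length (>= 2)
#' @return the trapezoidal integral
#' @export
auc_trapezoid <- function(values, times) {
  if (length(values) != length(times) || length(times) < 2)
    stop("values and times must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(0.5 * (values[-1] + values[-length(values)]) * diff(times))
}
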