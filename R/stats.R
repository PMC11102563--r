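#' Mean and standard error
#'
#' Values are summarized as mean +/- SE with the sample (n-1) standard
#' deviation: `se = sd(x) / sqrt(n)`.
#'
#' @param x numeric vector; `n >= 1` for the mean, `n >= 2` for the SE.
#' @return List with `mean`, `se` (`NA` and flagged when `n = 1`), `n`.
#' @export
mean_se <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("mean_se: empty input")
  list(mean = mean(x),
       se = if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_,
       n = length(x),
       se_defined = length(x) >= 2)
}

#' Round half away from zero
#'
#' Report-text rounding convention (so 0.5 rounds to 1, -0.5 to -1),
#' as opposed to R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

group_summaries <- function(lst) {
  do.call(rbind, lapply(names(lst), function(g) {
    s <- mean_se(lst[[g]])
    data.frame(group = g, n = s$n, mean = s$mean, se = s$se)
  }))
}

#' Two-sample t test (pooled or Welch)
#'
#' Two-tailed comparison of two groups; `welch = TRUE` applies the
#' Welch-Satterthwaite correction for unequal variances. When both groups
#' have zero variance and equal means the statistic is 0 with p = 1.
#'
#' @param x,y numeric vectors, each `n >= 2`.
#' @param welch use the Welch correction.
#' @return List of class `group_comparison`: `test_name`, `statistic`
#'   (t), `p_value`, `df`, `groups` (n, mean, se per group).
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  gs <- group_summaries(list(x = x, y = y))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(statistic = 0, p.value = 1,
                  parameter = length(x) + length(y) - 2)
    } else {
      res <- list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0,
                  parameter = length(x) + length(y) - 2)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = !welch)
    res <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
                parameter = unname(ht$parameter))
  }
  structure(list(test_name = if (welch) "welch_t" else "student_t",
                 statistic = res$statistic, p_value = res$p.value,
                 df = res$parameter, groups = gs),
            class = "group_comparison")
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U statistic with midrank ties; the two-tailed p-value is exact for
#' small samples without ties (`min(n) <= exact_max`) and uses the
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x,y numeric vectors, each `n >= 1`.
#' @param exact `"auto"` (default rule above), `"exact"`, or `"approx"`.
#' @param exact_max largest min-group size for which the auto rule picks
#'   the exact distribution.
#' @return A `group_comparison` with `statistic` = U.
#' @export
mann_whitney <- function(x, y, exact = c("auto", "exact", "approx"),
                         exact_max = 8L) {
  exact <- match.arg(exact)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(exact,
                      auto = min(length(x), length(y)) <= exact_max && !ties,
                      exact = TRUE,
                      approx = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  structure(list(test_name = "mann_whitney",
                 statistic = unname(ht$statistic),  # W equals U for x vs y
                 p_value = ht$p.value,
                 df = NA_real_,
                 groups = group_summaries(list(x = x, y = y))),
            class = "group_comparison")
}

#' One-way analysis of variance
#'
#' Classic F test (`MS_between / MS_within`). Identical groups, or zero
#' within-group variance with equal means, give F = 0 with p = 1.
#'
#' @param groups list of numeric samples, `>= 2` groups with `n >= 2` each.
#' @return A `group_comparison` with `statistic` = F and `df` = c(df1, df2).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("anova_oneway: every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(vals) - length(groups)
  gm <- vapply(groups, mean, numeric(1))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    res <- if (max(gm) == min(gm)) list(statistic = 0, p.value = 1)
           else list(statistic = Inf, p.value = 0)
  } else {
    ht <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
    res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(list(test_name = "anova_oneway", statistic = res$statistic,
                 p_value = res$p.value, df = c(df1, df2),
                 groups = group_summaries(groups)),
            class = "group_comparison")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_(i) = min over j >= rank(i) of (m * p_(j) / j)`, capped at 1;
#' monotone non-decreasing in the sorted order and never below the raw
#' maximum p.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
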