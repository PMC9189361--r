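#' Ordinary least-squares fit of Y on X
#'
#' Fits `y = slope * x + intercept` by OLS and reports the two-sided p-value
#' of the slope from the t statistic on `n - 2` degrees of freedom, together
#' with an equation string rendered at 4 significant digits in the style of
#' clinical correlation tables (`"Y = -0.3209*X + 1.332"`).
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must not be
#'   constant.
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept`, `n`, `r_squared`, `p_slope`, `se_slope`, `equation`.
#' @export
#' @examples
#' fit_linear(0:9, -0.3209 * 0:9 + 1.332)$equation
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("At least 3 complete observations are required.")
  if (sd(x) == 0) abort("`x` is constant; the design is degenerate.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless input warns about perfect fit
  cf <- sm$coefficients
  slope <- cf["x", "Estimate"]
  se <- cf["x", "Std. Error"]
  p <- max(cf["x", "Pr(>|t|)"], .Machine$double.xmin)
  structure(list(
    slope = slope,
    intercept = cf["(Intercept)", "Estimate"],
    n = n,
    r_squared = sm$r.squared,
    p_slope = p,
    se_slope = se,
    equation = format_equation(slope, cf["(Intercept)", "Estimate"])
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s  (n = %d, r2 = %.3f, P = %.3g)\n",
              x$equation, x$n, x$r_squared, x$p_slope))
  invisible(x)
}

#' @export
tidy.regression_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope),
    p.value = c(NA_real_, x$p_slope)
  )
}

#' @export
glance.regression_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_slope, nobs = x$n,
         equation = x$equation)
}

#' Stage-wise association report
#'
#' For each myeloma stage group, fits the three pairwise linear associations
#' reported in stage-wise correlation tables: miR-23 on uPA (`"uPA with
#' miR-23"`), miR-23 on methylation rate, and uPA on methylation rate. The
#' expected slope signs (negative, negative, positive) reflect promoter
#' hypermethylation silencing the microRNA and thereby derepressing its
#' target.
#'
#' @param cohort A `cohort_table` data frame with columns `group`,
#'   `meth_rate`, `mir23`, `upa`.
#' @param stages Groups to report (default: the four myeloma stage groups).
#' @return A tibble of class `stage_association`: `stage`, `association`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n`, `equation`,
#'   `expected_sign`, `sign_ok`.
#' @export
#' @examples
#' stage_association_report(simulate_cohort(seed = 1))
stage_association_report <- function(cohort, stages = mm_groups()) {
  needed <- c("group", "meth_rate", "mir23", "upa")
  miss <- setdiff(needed, names(cohort))
  if (length(miss) > 0) {
    abort(sprintf("Cohort is missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (!all(stages %in% cohort$group)) {
    abort("Every requested stage must be present in the cohort.")
  }
  specs <- tibble(
    association = c("uPA with miR-23", "miR-23 with methylation",
                    "uPA with methylation"),
    xvar = c("upa", "meth_rate", "meth_rate"),
    yvar = c("mir23", "mir23", "upa"),
    expected_sign = c(-1, -1, 1)
  )
  out <- purrr::map(stages, function(st) {
    sub <- cohort[cohort$group == st, ]
    purrr::pmap(specs, function(association, xvar, yvar, expected_sign) {
      f <- fit_linear(sub[[xvar]], sub[[yvar]])
      tibble(stage = st, association = association, slope = f$slope,
             intercept = f$intercept, r_squared = f$r_squared,
             p_value = f$p_slope, n = f$n, equation = f$equation,
             expected_sign = expected_sign,
             sign_ok = sign(f$slope) == expected_sign)
    }) |> bind_rows()
  }) |> bind_rows()
  class(out) <- c("stage_association", class(out))
  out
}

#' Compare a measurement across groups
#'
#' One-way ANOVA omnibus test followed by all pairwise Welch (unequal
#' variance) t-tests with Bonferroni correction over the pairwise family:
#' adjusted p = min(1, m * p_raw) with `m` the number of comparisons (all
#' pairs by default).
#'
#' @param data A data frame.
#' @param value,group Column names (strings or bare names) of the measurement
#'   and the grouping variable.
#' @param alpha Significance level for the flags.
#' @param m Bonferroni multiplier; defaults to the number of pairwise
#'   comparisons.
#' @return An object of class `group_comparison` with elements `omnibus`
#'   (F statistic, dfs, p), `pairwise` (per-pair Welch t with raw and
#'   adjusted p and significance flag) and `means` (per-group n/mean/sd,
#'   sorted by mean).
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' compare_groups(cohort, upa, group)
compare_groups <- function(data, value, group, alpha = 0.05, m = NULL) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  v <- data[[value]]
  g <- as.character(data[[group]])
  stopifnot(is.numeric(v), length(v) == length(g))
  counts <- table(g)
  if (length(counts) < 2) abort("At least two groups are required.")
  if (any(counts < 2)) abort("Every group needs at least 2 observations.")

  fit <- aov(v ~ factor(g))
  tab <- anova(fit)
  omnibus <- tibble(statistic = tab$`F value`[1], df_between = tab$Df[1],
                    df_within = tab$Df[2], p_value = tab$`Pr(>F)`[1])

  pairs <- utils::combn(sort(names(counts)), 2)
  m <- m %||% ncol(pairs)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    x1 <- v[g == g1]; x2 <- v[g == g2]
    tt <- tryCatch(t.test(x1, x2), error = function(e) NULL)
    if (is.null(tt)) {  # both groups constant; equal means => no difference
      tibble(group1 = g1, group2 = g2, mean_diff = mean(x1) - mean(x2),
             statistic = 0, p_raw = 1)
    } else {
      tibble(group1 = g1, group2 = g2, mean_diff = mean(x1) - mean(x2),
             statistic = unname(tt$statistic), p_raw = tt$p.value)
    }
  }) |> bind_rows() |>
    mutate(p_adj = pmin(1, m * .data$p_raw),
           significant = .data$p_adj < alpha)

  means <- tibble(group = g, value = v) |>
    group_by(group) |>
    summarise(n = n(), mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop") |>
    arrange(.data$mean)

  structure(list(omnibus = omnibus, pairwise = pairwise, means = means,
                 value = value, alpha = alpha, m = m),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F(%d, %d) = %.3f, P = %.3g\n",
              x$value, x$omnibus$df_between, x$omnibus$df_within,
              x$omnibus$statistic, x$omnibus$p_value))
  cat(sprintf("  group means (ascending): %s\n",
              paste(x$means$group, collapse = " < ")))
  cat(sprintf("  %d of %d Bonferroni-adjusted pairs significant at alpha = %g\n",
              sum(x$pairwise$significant), nrow(x$pairwise), x$alpha))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @export
glance.group_comparison <- function(x, ...) x$omnibus

#' Two-group sample size from a power specification
#'
#' Normal-approximation sample size per group for a two-sided two-sample
#' comparison at standardized effect size `delta`:
#' `n = 2 * (z_{1-alpha/2} + z_{power})^2 / delta^2`, rounded up.
#'
#' @param delta Standardized effect size (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power (1 - beta).
#' @return Integer sample size per group.
#' @export
#' @examples
#' required_sample_size(1)  # 16
required_sample_size <- function(delta, alpha = 0.05, power = 0.8) {
  if (delta <= 0) abort("`delta` must be positive.")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  as.integer(ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / delta^2))
}
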