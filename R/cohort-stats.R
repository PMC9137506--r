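#' Group summary statistics (n, mean, SD)
#'
#' Summary-statistic container for two-sample tests computable without raw
#' data, e.g. from a published cohort table.
#'
#' @param n Sample size (>= 2).
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  check_number(n, "n", min = 2)
  check_number(mean, "mean")
  check_number(sd, "sd", min = 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

# Accept a group_summary or a raw numeric vector.
as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  if (is.numeric(g) && length(g) >= 2L)
    return(group_summary(length(g), mean(g), stats::sd(g)))
  stop_bad("expected a group_summary or a numeric vector of length >= 2")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) or unequal-variance (Welch) two-sample
#' t-test computed from (n, mean, SD) triples, with `variant = "auto"`
#' choosing between them by a two-sided F pretest of variance homogeneity
#' ([variant_select()]). Zero-variance degenerate inputs give t = 0 when
#' the means agree and a signed infinite t (flagged) otherwise.
#'
#' @param g1,g2 [group_summary()] objects (or raw numeric vectors).
#' @param variant `"pooled"`, `"welch"`, or `"auto"`.
#' @param homogeneity_alpha Level of the F pretest used by `"auto"`.
#' @return Object of class `t_test_result`: `t`, `df` (fractional for
#'   Welch), `p` (two-sided), `variant`, `infinite` flag.
#' @export
t_from_summary <- function(g1, g2, variant = c("auto", "pooled", "welch"),
                           homogeneity_alpha = 0.05) {
  variant <- match.arg(variant)
  g1 <- as_group_summary(g1)
  g2 <- as_group_summary(g2)
  if (variant == "auto")
    variant <- variant_select(g1, g2, alpha = homogeneity_alpha)
  n1 <- g1$n; n2 <- g2$n
  v1 <- g1$sd^2; v2 <- g2$sd^2
  delta <- g1$mean - g2$mean
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se2 <= 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    df <- if (variant == "pooled") n1 + n2 - 2 else NA_real_
    return(structure(list(t = t, df = df, p = p, variant = variant,
                          infinite = is.infinite(t)),
                     class = "t_test_result"))
  }
  t <- delta / sqrt(se2)
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 variant = variant, infinite = FALSE),
            class = "t_test_result")
}

#' Choose the t-test variant by a variance-homogeneity F pretest
#'
#' Two-sided F test of the variance ratio at level `alpha` (default
#' 0.05): the Welch test is selected when homogeneity is rejected, the
#' pooled test otherwise.
#'
#' @param g1,g2 [group_summary()] objects (or raw numeric vectors).
#' @param alpha Pretest level.
#' @return `"pooled"` or `"welch"`.
#' @export
variant_select <- function(g1, g2, alpha = 0.05) {
  g1 <- as_group_summary(g1)
  g2 <- as_group_summary(g2)
  if (g1$sd == 0 && g2$sd == 0) return("pooled")
  if (g1$sd == 0 || g2$sd == 0) return("welch")
  f <- g1$sd^2 / g2$sd^2
  pf_low <- stats::pf(f, g1$n - 1, g2$n - 1)
  p <- 2 * min(pf_low, 1 - pf_low)
  if (p < alpha) "welch" else "pooled"
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y Paired finite numeric vectors, length >= 3, each with
#'   positive variance.
#' @return List with `r`, `p` (two-sided, from the t transform with n - 2
#'   degrees of freedom), `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_bad("`x` and `y` must be paired")
  if (length(x) < 3L) stop_bad("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_bad("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_bad("zero variance in `x` or `y`; correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, m * p)` for each p-value; `m` defaults to the number of
#' p-values supplied but may be larger when the family includes tests not
#' passed in.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Family size (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_bad("p-values must lie in [0, 1]")
  check_number(m, "m", min = 1)
  pmin(1, m * p_values)
}

#' Read a cohort summary table
#'
#' Reads a CSV with columns `variable`, `group`, `n`, `mean`, `sd` (one
#' row per variable per group). The package ships such a table at
#' `system.file("extdata", "gonogo_cohort_summary.csv", package =
#' "permbold")`: the sociodemographic, task-performance, impulsiveness
#' (BIS-11) and substance-use summaries of a 30 + 30 cohort of abstinent
#' alcohol-use-disorder and control participants from a Go/NoGo response
#' inhibition study. Note: the Go and NoGo accuracy rows of that source
#' table carry each other's printed test statistics (recomputation from
#' the summaries shows the t/df pairs swapped), so accuracy-row statistics
#' should be recomputed, not quoted.
#'
#' @param path CSV path.
#' @return `data.frame` with the five columns, `group` as character.
#' @export
read_group_summaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "group", "n", "mean", "sd")
  if (!all(need %in% names(df)))
    stop_bad("summary table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Two-sample tests for every variable of a summary table
#'
#' For each variable with two group rows, selects the t-test variant by
#' the homogeneity pretest and computes the test from the summaries;
#' optionally Bonferroni-adjusts the p-values.
#'
#' @param summaries A [read_group_summaries()] data frame.
#' @param bonferroni_m Family size for adjustment (`NULL` = no
#'   adjustment).
#' @param homogeneity_alpha Level of the variance pretest.
#' @return `data.frame`: `variable`, `t`, `df`, `p`, `variant`, and
#'   `p_adjusted` when requested.
#' @export
cohort_table_tests <- function(summaries, bonferroni_m = NULL,
                               homogeneity_alpha = 0.05) {
  vars <- unique(summaries$variable)
  rows <- lapply(vars, function(v) {
    sub <- summaries[summaries$variable == v, ]
    if (nrow(sub) != 2L)
      stop_bad("variable \"", v, "\" must have exactly 2 group rows")
    g1 <- group_summary(sub$n[1L], sub$mean[1L], sub$sd[1L])
    g2 <- group_summary(sub$n[2L], sub$mean[2L], sub$sd[2L])
    r <- t_from_summary(g1, g2, "auto", homogeneity_alpha)
    data.frame(variable = v, t = r$t, df = r$df, p = r$p,
               variant = r$variant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(bonferroni_m))
    out$p_adjusted <- bonferroni_adjust(out$p, bonferroni_m)
  out
}
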