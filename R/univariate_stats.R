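signal_test <- function(test_name, statistic, p_value, n, tails = "two") {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, tails = tails),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s, %s-tailed)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/"), x$tails))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Decides between parametric and nonparametric downstream tests:
#' `"parametric"` iff the Shapiro-Wilk p-value is at least `alpha`.
#'
#' @param values Numeric vector, n >= 3, non-constant.
#' @param alpha Gate level; default 0.05.
#' @return `"parametric"` or `"nonparametric"`, with the Shapiro-Wilk
#'   result attached as attribute `"test"`.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    stop("shapiro_gate needs at least 3 non-missing values", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  out <- if (sw$p.value >= alpha) "parametric" else "nonparametric"
  attr(out, "test") <- signal_test("Shapiro-Wilk", sw$statistic, sw$p.value,
                                   length(values))
  out
}

#' Two-group comparison with normality-gated dispatch
#'
#' Runs the two-tailed test matching the design: Welch two-sample t
#' (parametric, unpaired), paired t (parametric, paired), Wilcoxon
#' rank-sum W (nonparametric, unpaired) or Wilcoxon signed-rank V
#' (nonparametric, paired). Nonparametric tests use exact p-values where
#' `stats::wilcox.test` provides them (small samples, no ties) and the
#' continuity-corrected normal approximation otherwise; zero differences
#' are dropped by the signed-rank test.
#'
#' @param a,b Numeric vectors. When `paired = TRUE` they must have equal
#'   length and are compared element-wise.
#' @param paired Paired design? Default `FALSE`.
#' @param parametric Use the t-test family? Typically the output of
#'   [shapiro_gate()] `== "parametric"`.
#' @return A `signal_test`.
#' @export
compare_groups <- function(a, b, paired = FALSE, parametric = TRUE) {
  if (paired && length(a) != length(b)) {
    stop("paired comparison needs equal-length vectors", call. = FALSE)
  }
  if (!paired) {
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
  } else {
    keep <- !(is.na(a) | is.na(b))
    a <- a[keep]
    b <- b[keep]
  }
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (paired && all(a == b)) {
    # all differences zero: statistic at its null centre, maximal p
    name <- if (parametric) "Paired t-test" else "Wilcoxon signed-rank test"
    return(signal_test(name, 0, 1, length(a)))
  }
  if (parametric) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
    name <- if (paired) "Paired t-test" else "Welch two-sample t-test"
    signal_test(name, tt$statistic, tt$p.value,
                if (paired) length(a) else c(length(a), length(b)))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = paired, correct = TRUE))
    name <- if (paired) "Wilcoxon signed-rank test" else
      "Wilcoxon rank-sum test"
    signal_test(name, wt$statistic, wt$p.value,
                if (paired) length(a) else c(length(a), length(b)))
  }
}

#' Pearson correlation test
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both non-constant.
#' @return A `signal_test` with the correlation coefficient as statistic
#'   (attribute `"r"` also set) and the two-tailed p from the t transform.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- signal_test("Pearson correlation", ct$estimate, ct$p.value,
                     length(x))
  attr(out, "r") <- unname(ct$estimate)
  out
}
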