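## Group summaries and two-sample t machinery, implemented from the
## classical formulas (pooled-variance Student t for unpaired data,
## one-sample t on differences for paired data). Heavier designs
## (ANOVA, post-hoc corrections) are outside this package's remit and
## belong to standard statistics routines.

#' Summarise groups as mean and SEM
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length as `values`.
#' @return A data frame with `group`, `n`, `mean`, `sem`
#'   (`sd/sqrt(n)` with the n-1 sample standard deviation; `NA` for
#'   singleton groups).
#' @examples
#' summarize_groups(c(3, 5, 1, 2, 3, 4, 5), rep(c("a", "b"), c(2, 5)))
#' @export
summarize_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length")
  if (any(is.na(values))) stop("'values' contains NA")
  labs <- unique(groups)
  if (!length(labs))
    return(data.frame(group = character(0), n = integer(0),
                      mean = numeric(0), sem = numeric(0)))
  out <- do.call(rbind, lapply(labs, function(g) {
    v <- values[groups == g]
    if (!length(v)) stop(sprintf("group '%s' is empty", g))
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
                     else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample Student t test (pooled variance) or paired t test
#'
#' Unpaired: classical pooled-variance Student t with
#' `df = n_a + n_b - 2`. Paired: one-sample t on the within-pair
#' differences with `df = n - 1`. Two-sided p values from the t
#' distribution. Degenerate zero-variance inputs are flagged rather than
#' producing infinite statistics: equal means give `t = 0, p = 1`;
#' unequal means with zero variance are reported with
#' `degenerate = TRUE` and `p = 0`.
#'
#' @param a,b Numeric vectors (paired: equal length >= 2; unpaired: each
#'   length >= 2).
#' @param paired Logical.
#' @return An object of class `t_test_result`: `t`, `df`, `p`, `paired`,
#'   `degenerate`.
#' @export
two_sample_t <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(is.na(a)) || any(is.na(b))) stop("inputs contain NA")
  if (paired) {
    if (length(a) != length(b))
      stop("paired test requires equal-length samples")
    if (length(a) < 2L) stop("paired test requires n >= 2")
    d <- a - b
    n <- length(d)
    df <- n - 1
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      if (mean(d) == 0)
        return(.t_result(0, df, 1, TRUE, FALSE))
      return(.t_result(sign(mean(d)) * Inf, df, 0, TRUE, TRUE))
    }
    t <- mean(d) / (sd_d / sqrt(n))
  } else {
    if (length(a) < 2L || length(b) < 2L)
      stop("unpaired test requires n >= 2 in each sample")
    na <- length(a); nb <- length(b)
    df <- na + nb - 2
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
    if (sp2 == 0) {
      if (mean(a) == mean(b))
        return(.t_result(0, df, 1, FALSE, FALSE))
      return(.t_result(sign(mean(a) - mean(b)) * Inf, df, 0, FALSE, TRUE))
    }
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- 2 * stats::pt(-abs(t), df)
  .t_result(t, df, p, paired, FALSE)
}

.t_result <- function(t, df, p, paired, degenerate) {
  structure(list(t = t, df = df, p = p, paired = paired,
                 degenerate = degenerate),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4g, df = %g, p = %.4g%s\n",
              if (x$paired) "paired" else "unpaired (pooled)",
              x$t, x$df, x$p,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Fold change between two group means
#'
#' @param reference_mean Reference (denominator) mean, > 0.
#' @param comparison_mean Comparison (numerator) mean.
#' @return `comparison_mean / reference_mean`.
#' @examples
#' fold_change(2, 6)  # 3.0
#' @export
fold_change <- function(reference_mean, comparison_mean) {
  if (!is.numeric(reference_mean) || reference_mean <= 0)
    stop("'reference_mean' must be positive")
  comparison_mean / reference_mean
}
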