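#' Within/between-group variance decomposition
#'
#' One-way decomposition of the total variation of per-tumor estimates
#' into within-mouse and between-mouse components, supporting
#' unbalanced groups:
#' `MSW = sum_ij (y_ij - ybar_i)^2 / (N - k)` and
#' `MSB = sum_i n_i (ybar_i - ybar)^2 / (k - 1)`, with the F statistic
#' `MSB/MSW` referred to `F(k-1, N-k)`. Computed through a standard
#' one-way ANOVA fit.
#'
#' @param values Numeric vector of per-tumor estimates.
#' @param groups Group (mouse) labels, same length.
#' @return A list of class `variance_decomposition` with `msw`, `msb`,
#'   `df_within`, `df_between`, `f_stat`, `p_value`.
#' @examples
#' variance_components(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
#' @export
variance_components <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("need at least two groups")
  if (n - k < 1L) stop("within-group mean square undefined: all groups singleton")
  # suppress the lm warning on perfect within-group fits (MSW = 0 is a
  # legitimate degenerate input; the F statistic is then Inf)
  a <- suppressWarnings(stats::anova(stats::lm(values ~ groups)))
  structure(
    list(msw = a$`Mean Sq`[2L], msb = a$`Mean Sq`[1L],
         df_within = a$Df[2L], df_between = a$Df[1L],
         f_stat = a$`F value`[1L], p_value = a$`Pr(>F)`[1L]),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("MSW = %.4g (df %d), MSB = %.4g (df %d), F = %.3f, p = %.4g\n",
              x$msw, x$df_within, x$msb, x$df_between, x$f_stat, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged); invariant
#' under strictly monotone transforms of either variable, so it
#' measures monotone (possibly nonlinear) association.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return A list with `rho` and the two-sided `p_value` (asymptotic).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Two-sample t-test
#'
#' Pooled-variance Student's t by default (`df = n1 + n2 - 2`), with a
#' Welch variant available; two-sided p-value.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param welch Use the Welch unequal-variance form.
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (!welch && stats::var(x) + stats::var(y) == 0 && mean(x) == mean(y)) {
    # identical constant samples: define t = 0, p = 1
    return(list(t = 0, df = length(x) + length(y) - 2L, p_value = 1))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Nadaraya-Watson kernel regression
#'
#' Gaussian-kernel local constant smoother
#' `m(x0) = sum_i K((x_i - x0)/h) y_i / sum_i K((x_i - x0)/h)`, with the
#' bandwidth defaulting to Silverman's rule of thumb on `x`
#' ([stats::bw.nrd0()]).
#'
#' @param x,y Data (n >= 5).
#' @param bandwidth Kernel bandwidth (> 0); default Silverman's rule.
#' @param grid Evaluation points; default 100 equally spaced over
#'   `range(x)`.
#' @return A list with `grid`, `fit`, and `bandwidth`.
#' @export
kernel_smoother <- function(x, y, bandwidth = NULL, grid = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100L)
  fit <- vapply(grid, function(x0) {
    w <- stats::dnorm((x - x0) / bandwidth)
    if (sum(w) == 0) {
      # numerically empty neighbourhood: fall back to the nearest point
      y[which.min(abs(x - x0))]
    } else {
      sum(w * y) / sum(w)
    }
  }, numeric(1L))
  list(grid = grid, fit = fit, bandwidth = bandwidth)
}

#' Summary row of a sample
#'
#' Mean, spread and five-number summary in the layout used for
#' goodness-of-fit tables. `sd` is the sample standard deviation and
#' `se` is `sd/sqrt(n)`; both conventions are reported explicitly
#' because summary tables in this literature sometimes print the SD
#' under a "Std. Err." heading. Quantiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param values Numeric vector (n >= 1).
#' @return A one-row `data.frame` with `n, mean, sd, se, min, q1,
#'   median, q3, max`.
#' @export
summarize_values <- function(values) {
  stopifnot(length(values) >= 1L)
  n <- length(values)
  s <- if (n > 1L) stats::sd(values) else 0
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                       type = 7)
  data.frame(n = n, mean = mean(values), sd = s, se = s / sqrt(n),
             min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L])
}
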