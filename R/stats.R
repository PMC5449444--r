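# Group-level statistics: classic Student's t-test for independent
# samples and Pearson correlation (thin wrappers around stats::).

#' Independent-samples Student's t-test
#'
#' Pooled-variance two-sample t-test with a two-sided p-value from the t
#' distribution with `n_a + n_b - 2` degrees of freedom (`var.equal`
#' Student test; set `welch = TRUE` for the unequal-variance variant).
#' Degenerate inputs with zero pooled variance return `t = 0, p = 1` when
#' the means are equal and raise an error otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch correction instead of pooled variance.
#' @return A list: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
ttest_independent <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation; the p-value comes from the t transform
#' with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}
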