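# Penetrance and two-by-two phenotype statistics ------------------------

#' Two-by-two analysis of phenotype proportions
#'
#' Compare the proportion of embryos with a phenotype between two groups:
#' reports both an exact p value (Fisher's exact test, two-sided by the
#' minimum-likelihood convention) and an asymptotic p value (Pearson
#' chi-square, 1 df, no continuity correction), plus the sample odds
#' ratio `(a d) / (b c)` (with 0.5 added to every cell when any cell is
#' zero).
#'
#' @param a,b Group-1 counts with / without the phenotype.
#' @param c_,d Group-2 counts with / without the phenotype.
#' @param labels Optional pair of group names.
#' @return A `two_by_two` object: `p1`, `p2` (percentages with the
#'   phenotype per group), `exact_p`, `asymptotic_p`, `odds_ratio`,
#'   `counts`.
#' @examples
#' two_by_two(202, 154, 279, 119)
#' @export
two_by_two <- function(a, b, c_, d, labels = c("group1", "group2")) {
  counts <- c(a = a, b = b, c = c_, d = d)
  stop_if_not(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  stop_if_not(a + b > 0 && c_ + d > 0, "row totals must be positive")
  m <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  exact_p <- stats::fisher.test(m)$p.value
  asym_p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  or <- if (any(counts == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  structure(list(labels = labels,
                 p1 = 100 * a / (a + b), p2 = 100 * c_ / (c_ + d),
                 exact_p = exact_p, asymptotic_p = asym_p,
                 odds_ratio = or, counts = counts),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("<two_by_two> proportion comparison\n")
  cat(sprintf("  %s: %.2f%% (%d/%d)   %s: %.2f%% (%d/%d)\n",
              x$labels[1], x$p1, x$counts["a"],
              x$counts["a"] + x$counts["b"],
              x$labels[2], x$p2, x$counts["c"],
              x$counts["c"] + x$counts["d"]))
  cat(sprintf("  exact p = %.4g, asymptotic p = %.4g, odds ratio = %.3g\n",
              x$exact_p, x$asymptotic_p, x$odds_ratio))
  invisible(x)
}

#' Penetrance with an exact binomial confidence interval
#'
#' Fraction of individuals showing a phenotype, as a percentage, with the
#' 95% Clopper-Pearson (exact binomial) confidence interval.
#'
#' @param k Count with the phenotype (0 <= k <= n).
#' @param n Total scored (>= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `percent`, `ci_lower`, `ci_upper` (percent), `k`, `n`.
#' @examples
#' penetrance(7, 8)
#' @export
penetrance <- function(k, n, conf_level = 0.95) {
  stop_if_not(is.numeric(n) && length(n) == 1L && n >= 1 && n == round(n),
              "`n` must be a positive integer")
  stop_if_not(is.numeric(k) && length(k) == 1L && k >= 0 && k <= n &&
                k == round(k), "`k` must be an integer in [0, n]")
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  list(percent = 100 * k / n,
       ci_lower = 100 * ci[1], ci_upper = 100 * ci[2],
       k = as.integer(k), n = as.integer(n), conf_level = conf_level)
}
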