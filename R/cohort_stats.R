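stat_report <- function(test, statistic, p, n, estimate = NA_real_,
                        flags = character(0)) {
  structure(list(test = test, statistic = statistic, p = p, n = n,
                 estimate = estimate, flags = flags),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic %s, p %s, n %d%s\n",
              x$test,
              if (is.na(x$statistic)) "-" else sprintf("%.4g", x$statistic),
              if (is.na(x$p)) "-" else sprintf("%.4g", x$p), x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Paired t test
#'
#' Two-sided one-sample t test on the paired differences (n - 1 degrees of
#' freedom). Constant differences (zero variance) make t undefined; the
#' report is then flagged `"degenerate"` with `NA` statistic and p.
#'
#' @param x,y Paired numeric vectors of equal length >= 2; `NA` pairs are
#'   dropped.
#' @return A `stat_report` (estimate = mean difference x - y).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  if (sd(d) == 0)
    return(stat_report("paired_t", NA_real_, NA_real_, n,
                       estimate = mean(d), flags = "degenerate"))
  ht <- stats::t.test(x, y, paired = TRUE)
  stat_report("paired_t", unname(ht$statistic), ht$p.value, n,
              estimate = unname(ht$estimate))
}

#' Welch two-sample t test
#'
#' Two-sided unequal-variance (Welch) t test comparing two independent
#' groups, e.g. untreated versus treated lesions.
#'
#' @param x,y Numeric vectors (>= 2 finite values each, not both constant).
#' @return A `stat_report` (estimate = mean(x) - mean(y)).
#' @export
two_sample_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  if (sd(x) == 0 && sd(y) == 0)
    return(stat_report("two_sample_t", NA_real_, NA_real_,
                       length(x) + length(y),
                       estimate = mean(x) - mean(y), flags = "degenerate"))
  ht <- stats::t.test(x, y, var.equal = FALSE)
  stat_report("two_sample_t", unname(ht$statistic), ht$p.value,
              length(x) + length(y),
              estimate = unname(ht$estimate[1] - ht$estimate[2]))
}

#' Pearson correlation test
#'
#' Pearson's r with a two-sided p value from the t transform on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors with >= 3 complete pairs and positive
#'   variance each.
#' @return A `stat_report` (estimate = r; statistic = t).
#' @export
pearson <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs for correlation")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  stat_report("pearson", unname(ht$statistic), ht$p.value, n,
              estimate = unname(ht$estimate))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: with the p values sorted ascending,
#' `adjusted_i = min_{j >= i} (p_j * m / j)`, capped at 1, returned in the
#' original order. `NA` entries are passed through.
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
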