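# Non-parametric monotonic trend inference: Mann-Kendall test with tie
# correction and Sen's slope estimator.

# Exact null distribution of the Mann-Kendall score S for tie-free series of
# length n: S = T - 2*I where T = n(n-1)/2 and I is the number of inversions
# of a uniform random permutation. Counts of permutations by inversion number
# are built by polynomial convolution (Mahonian numbers).
mk_exact_cdf <- function(n) {
  counts <- 1
  for (i in 2:n) counts <- convolve(counts, rep(1, i), type = "open")
  probs <- counts / sum(counts)         # P(I = 0..n(n-1)/2)
  s_vals <- n * (n - 1) / 2 - 2 * (seq_along(probs) - 1)
  list(s = s_vals, p = probs)           # s decreasing
}

#' Mann-Kendall trend test
#'
#' Tests for a monotonic trend in a time series. The score is
#' `S = sum over i<j of sign(x_j - x_i)`; its variance carries the standard
#' tie correction `var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over
#' tie groups of size `t`. The normal deviate uses a continuity correction
#' (`Z = (S -+ 1)/sqrt(var(S))` toward zero, `Z = 0` when `S = 0`) and a
#' two-sided p-value. For short tie-free series (`n <= exact_n`) the exact
#' permutation-null distribution of S is used instead of the normal
#' approximation.
#'
#' @param value series values; `NA`s are dropped (with their days).
#' @param day optional day coordinates (only used to order the series).
#' @param exact_n largest tie-free length for which the exact null is used.
#' @return an object of class `mann_kendall` with elements `n`, `S`,
#'   `var_S`, `Z`, `p_value`, `tau`, `method`.
#' @export
mann_kendall <- function(value, day = NULL, exact_n = 10L) {
  if (!is.null(day)) {
    keep <- !is.na(value)
    o <- order(day[keep])
    x <- value[keep][o]
  } else {
    x <- value[!is.na(value)]
  }
  n <- length(x)
  if (n < 3L) stop("Mann-Kendall test needs at least 3 non-missing values",
                   call. = FALSE)
  sgn <- sign(outer(x, x, "-"))
  S <- sum(sgn[lower.tri(sgn)])         # sign(x_j - x_i) over i < j
  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  if (var_S == 0) {                     # all values tied
    Z <- 0
    p <- 1
    method <- "degenerate (all tied)"
  } else if (n <= exact_n && length(ties) == 0L) {
    tab <- mk_exact_cdf(n)
    p <- min(1, 2 * sum(tab$p[tab$s >= abs(S)]))
    method <- "exact permutation null"
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  structure(
    list(n = n, S = S, var_S = var_S, Z = Z, p_value = p,
         tau = S / (n * (n - 1) / 2), method = method),
    class = "mann_kendall"
  )
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat("Mann-Kendall trend test (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, S = %d, var(S) = %.3f, Z = %.4f, tau = %.3f\n",
              x$n, x$S, x$var_S, x$Z, x$tau))
  cat(sprintf("  two-sided p = %.4g\n", x$p_value))
  invisible(x)
}

#' Sen's slope estimator
#'
#' Median of all pairwise slopes `(x_j - x_i)/(d_j - d_i)` over pairs with
#' distinct days; robust to outliers and missing values.
#'
#' @param value series values; `NA`s dropped.
#' @param day day coordinates (defaults to `1:n`).
#' @return slope in value units per day.
#' @export
sens_slope <- function(value, day = seq_along(value)) {
  keep <- !is.na(value) & !is.na(day)
  x <- value[keep]; d <- day[keep]
  n <- length(x)
  if (n < 2L) stop("Sen's slope needs at least 2 non-missing values",
                   call. = FALSE)
  dx <- outer(x, x, "-")
  dd <- outer(d, d, "-")
  lt <- lower.tri(dd)
  ok <- lt & dd != 0
  if (!any(ok)) stop("no pair of points with distinct days", call. = FALSE)
  stats::median(dx[ok] / dd[ok])
}

#' Per-stage trend table for a performance series
#'
#' Runs [mann_kendall()] and [sens_slope()] on the whole series and on each
#' successional stage separately.
#'
#' @param day,value the series (e.g. the smoothed N2/npNO3- ratio).
#' @param stages integer stage label per point.
#' @return data frame with one row per stage plus a `"all"` row: `stage`,
#'   `n`, `S`, `Z`, `p_value`, `sen_slope`.
#' @export
trend_by_stage <- function(day, value, stages) {
  stopifnot(length(day) == length(value), length(day) == length(stages))
  one <- function(d, v, label) {
    ok <- !is.na(v)
    if (sum(ok) < 3L)
      return(data.frame(stage = label, n = sum(ok), S = NA_real_,
                        Z = NA_real_, p_value = NA_real_,
                        sen_slope = NA_real_))
    mk <- mann_kendall(v[ok], d[ok])
    data.frame(stage = label, n = mk$n, S = mk$S, Z = mk$Z,
               p_value = mk$p_value, sen_slope = sens_slope(v[ok], d[ok]))
  }
  res <- lapply(sort(unique(stages)), function(s) {
    sel <- stages == s
    one(day[sel], value[sel], as.character(s))
  })
  rbind(do.call(rbind, res), one(day, value, "all"))
}
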