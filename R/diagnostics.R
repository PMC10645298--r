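#' Scaled total-time-on-test (TTT) transform
#'
#' With order statistics \eqn{x_{(1)} \le \dots \le x_{(n)}}, the scaled
#' TTT values are
#' \deqn{T_i = \frac{\sum_{j \le i} x_{(j)} + (n - i)\,x_{(i)}}
#'   {\sum_j x_{(j)}}, \qquad T_0 = 0,}
#' plotted against \eqn{u_i = i/n}.  A concave curve above the diagonal
#' indicates an increasing failure rate, the diagonal a constant rate, and
#' an S-shape a bathtub-type rate; the curve always runs from (0, 0) to
#' (1, 1) and is nondecreasing.
#'
#' @param x numeric vector of at least 2 nonnegative values, not all zero.
#' @return An object of class `"ttt_curve"`: a `data.frame` with columns
#'   `u` (\eqn{i/n}, \eqn{i = 0 \dots n}) and `ttt`.
#' @examples
#' ttt_curve(c(1, 2, 3))
#' ttt_curve(load_dataset("bearings23")$values)
#' @export
ttt_curve <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(x < 0)) stop("TTT is defined for nonnegative data", call. = FALSE)
  total <- sum(x)
  if (total == 0) stop("degenerate all-zero sample", call. = FALSE)
  xs <- sort(x)
  i <- seq_len(n)
  ttt <- (cumsum(xs) + (n - i) * xs) / total
  structure(data.frame(u = c(0, i / n), ttt = c(0, ttt)),
            class = c("ttt_curve", "data.frame"))
}

#' Probability-probability and quantile-quantile series for a fitted model
#'
#' `pp_points()` pairs the empirical cdf \eqn{i/n} at each order statistic
#' with the fitted-model cdf there.  `qq_points()` pairs the fitted-model
#' quantile at plotting position \eqn{p_i = (i - 0.5)/n} with the order
#' statistic \eqn{x_{(i)}}.  Both are the numeric series behind the usual
#' goodness-of-fit panels; points near the unit diagonal (P-P) or the
#' identity line (Q-Q) indicate agreement.
#'
#' @param fit an `"hltexp_fit"` from [fit_hltexp()].
#' @param x the data the model was fitted to (or any sample on its
#'   support).
#' @return A `data.frame`: `pp_points()` with columns `empirical` and
#'   `theoretical` (both probabilities); `qq_points()` with columns
#'   `theoretical` (model quantiles) and `sample` (order statistics).
#' @examples
#' d <- load_dataset("kevlar76")$values
#' f <- fit_hltexp(d)
#' head(pp_points(f, d))
#' head(qq_points(f, d))
#' @export
pp_points <- function(fit, x) {
  stopifnot(inherits(fit, "hltexp_fit"))
  est <- fit$estimates
  xs <- sort(as.numeric(x))
  n <- length(xs)
  data.frame(empirical = seq_len(n) / n,
             theoretical = phltexp(xs, a = est[["a"]],
                                   theta = est[["theta"]]))
}

#' @rdname pp_points
#' @export
qq_points <- function(fit, x) {
  stopifnot(inherits(fit, "hltexp_fit"))
  est <- fit$estimates
  xs <- sort(as.numeric(x))
  n <- length(xs)
  p <- (seq_len(n) - 0.5) / n
  data.frame(theoretical = qhltexp(p, a = est[["a"]],
                                   theta = est[["theta"]]),
             sample = xs)
}

#' Empirical cdf as a plottable series
#'
#' The standard right-continuous empirical distribution function evaluated
#' at the sorted sample points, returned as a two-column series for overlay
#' against a fitted cdf.
#'
#' @param x numeric sample.
#' @return A `data.frame` with columns `x` (sorted unique values) and
#'   `ecdf` (\eqn{P(X \le x)}).
#' @examples
#' ecdf_series(c(1, 2, 3))
#' @export
ecdf_series <- function(x) {
  x <- as.numeric(x)
  xs <- sort(unique(x))
  data.frame(x = xs, ecdf = ecdf(x)(xs))
}
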