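#' Truncated-family composition
#'
#' A new lifetime law can be built by feeding the cumulative hazard of a
#' left-truncated base distribution through the cdf of a nonnegative
#' "generator" distribution.  If the base has conditional cdf
#' \eqn{F(x \mid x > \tau)} and the generator has cdf \eqn{R} and pdf
#' \eqn{r} on \eqn{[0, \infty)}, the composed law has
#' \deqn{G(x) = R\{H(x)\}, \qquad g(x) = r\{H(x)\}\, \frac{f(x)}{1 - F(x)},}
#' where \eqn{H(x) = -\log\{1 - F(x \mid x > \tau)\}} is the cumulative
#' hazard of the base.  The half logistic-truncated exponential distribution
#' is the special case of a half-logistic generator and a left-truncated
#' exponential base; see [dhltexp()].
#'
#' `truncated_exponential_base()` builds the left-truncated exponential base
#' with rate `theta` and threshold `a` (conditional cdf
#' \eqn{1 - e^{-\theta(x-a)}}).  `half_logistic_generator()` builds the
#' standard half-logistic generator (pdf \eqn{2e^{-t}/(1+e^{-t})^2}), and
#' `exponential_generator()` the unit-exponential generator, for which the
#' composition is the identity map back to the base distribution.
#'
#' @param theta positive rate of the exponential base.
#' @param a truncation threshold (lower support bound), in data units.
#'
#' @return `truncated_exponential_base()` returns an object of class
#'   `"tx_base"`: a list with the threshold `tau` and conditional `cdf` and
#'   `pdf` evaluators.  The generator constructors return objects of class
#'   `"tx_generator"`: a list with `pdf` and `cdf` evaluators on
#'   \eqn{[0, \infty)}.
#'
#' @seealso [cumulative_hazard()], [composed_cdf()], [composed_pdf()],
#'   [compose_with_exponential()]
#' @examples
#' base <- truncated_exponential_base(theta = 0.5, a = 2)
#' gen  <- half_logistic_generator()
#' composed_cdf(gen, base, 4)
#' phltexp(4, a = 2, theta = 0.5)  # identical closed form
#' @export
truncated_exponential_base <- function(theta, a = 0) {
  check_theta(theta)
  check_a(a)
  structure(
    list(
      tau = a,
      cdf = function(x) ifelse(x < a, 0, -expm1(-theta * (x - a))),
      pdf = function(x) ifelse(x < a, 0, theta * exp(-theta * (x - a)))
    ),
    class = "tx_base"
  )
}

#' @rdname truncated_exponential_base
#' @export
half_logistic_generator <- function() {
  structure(
    list(
      pdf = function(t) {
        e <- exp(-t)
        ifelse(t < 0, 0, 2 * e / (1 + e)^2)
      },
      cdf = function(t) {
        e <- exp(-t)
        ifelse(t < 0, 0, (1 - e) / (1 + e))
      }
    ),
    class = "tx_generator"
  )
}

#' @rdname truncated_exponential_base
#' @export
exponential_generator <- function() {
  structure(
    list(
      pdf = function(t) ifelse(t < 0, 0, exp(-t)),
      cdf = function(t) ifelse(t < 0, 0, -expm1(-t))
    ),
    class = "tx_generator"
  )
}

#' Cumulative hazard of a truncated base distribution
#'
#' Evaluates \eqn{H(x) = -\log\{1 - F(x \mid x > \tau)\}}, the quantity at
#' which the generator cdf is evaluated in the truncated-family composition.
#'
#' @param base a `"tx_base"` object, see [truncated_exponential_base()].
#' @param x numeric vector of evaluation points, all `>= base$tau`.
#' @return Nonnegative cumulative-hazard values; `Inf` where the base cdf
#'   has reached 1.
#' @examples
#' b <- truncated_exponential_base(theta = 0.5, a = 2)
#' cumulative_hazard(b, 4)  # 0.5 * (4 - 2) = 1
#' @export
cumulative_hazard <- function(base, x) {
  stopifnot(inherits(base, "tx_base"))
  if (any(x < base$tau))
    stop("'x' must be >= the truncation threshold tau", call. = FALSE)
  Fx <- base$cdf(x)
  ifelse(Fx >= 1, Inf, -log1p(-Fx))
}

#' Composed cdf and pdf of a truncated-family distribution
#'
#' `composed_cdf()` evaluates \eqn{R\{H(x)\}} and `composed_pdf()` evaluates
#' \eqn{r\{H(x)\} f(x) / \{1 - F(x)\}} for a generator/base pair.  Where the
#' base cdf is within `1e-15` of 1 the density is returned as 0 (its correct
#' limit) rather than evaluating an indeterminate ratio.
#'
#' @param gen a `"tx_generator"` object.
#' @inheritParams cumulative_hazard
#' @return Probabilities (`composed_cdf`) or densities (`composed_pdf`).
#' @examples
#' b <- truncated_exponential_base(1, 0)
#' g <- half_logistic_generator()
#' composed_pdf(g, b, 0)  # theta/2 = 0.5 at the threshold
#' @export
composed_cdf <- function(gen, base, x) {
  stopifnot(inherits(gen, "tx_generator"))
  gen$cdf(cumulative_hazard(base, x))
}

#' @rdname composed_cdf
#' @export
composed_pdf <- function(gen, base, x) {
  stopifnot(inherits(gen, "tx_generator"))
  H <- cumulative_hazard(base, x)
  Fx <- base$cdf(x)
  out <- numeric(length(H))
  ok <- Fx < 1 - 1e-15
  out[ok] <- gen$pdf(H[ok]) * base$pdf(x[ok]) / (1 - Fx[ok])
  out
}

#' Composition with an exponential base in closed scale-location form
#'
#' For an exponential base the composed density collapses to
#' \eqn{g(x) = \theta\, r\{\theta (x - a)\}}: the generator density rescaled
#' by the rate and shifted to the threshold.  Returns that density as a
#' function of `x`, valid for `x >= a`.
#'
#' @inheritParams composed_cdf
#' @inheritParams truncated_exponential_base
#' @return A vectorised density function of one argument.
#' @examples
#' f <- compose_with_exponential(half_logistic_generator(), theta = 1, a = 0)
#' f(0)  # 1/2
#' @export
compose_with_exponential <- function(gen, theta, a = 0) {
  stopifnot(inherits(gen, "tx_generator"))
  check_theta(theta)
  check_a(a)
  function(x) ifelse(x < a, 0, theta * gen$pdf(theta * (x - a)))
}
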