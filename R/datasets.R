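# The three classical lifetime datasets, stored to full printed precision.

.kevlar76 <- c(
  0.0251, 0.0891, 0.0886, 0.3113, 0.8425, 0.2501, 0.4763, 0.5650, 0.5671,
  0.3451, 0.8645, 0.6566, 0.6751, 0.6748, 0.8375, 0.7696, 0.6753, 0.8391,
  0.9836, 0.8851, 0.9120, 0.9113, 1.0483, 1.0773, 1.1733, 1.0596, 1.5733,
  1.7083, 1.2570, 1.7263, 1.2766, 1.2985, 1.7630, 1.3211, 1.3503, 1.9316,
  1.3551, 1.4595, 1.8808, 1.4880, 1.5728, 1.8881, 1.7460, 1.8275, 1.8375,
  1.7746, 1.8503, 1.8878, 1.9558, 2.2100, 2.0408, 2.0903, 2.1093, 2.1330,
  2.2460, 2.0048, 2.2878, 2.3203, 2.3513, 2.4951, 2.3470, 2.9911, 2.5260,
  3.0256, 3.2678, 3.4045, 3.4846, 3.7433, 3.9143, 3.7455, 4.8073, 5.5295,
  5.4005, 6.5541, 5.4435, 9.0960)

.guinea72 <- c(
  0.1, 0.96, 0.56, 0.72, 0.44, 0.77, 0.93, 0.33, 0.59, 0.92, 1.00, 1.02,
  1.00, 1.07, 0.70, 0.08, 1.08, 1.05, 1.08, 1.12, 1.09, 1.13, 0.74, 1.15,
  1.16, 1.20, 1.21, 1.22, 1.22, 1.24, 1.3, 1.34, 1.36, 1.39, 1.44, 1.97,
  1.46, 1.59, 1.72, 1.60, 1.68, 1.63, 1.71, 1.63, 1.76, 1.96, 1.83, 1.53,
  1.95, 2.02, 2.15, 2.93, 2.16, 2.30, 2.53, 2.31, 2.40, 2.51, 2.22, 2.54,
  2.45, 2.54, 2.78, 2.13, 3.61, 3.27, 3.47, 3.42, 4.02, 4.58, 4.32, 5.55)

.bearings23 <- c(
  17.88, 41.52, 33.00, 42.12, 28.92, 48.80, 51.84, 45.60, 54.12, 67.80,
  51.96, 68.64, 55.56, 68.88, 93.12, 68.64, 98.64, 84.12, 128.04, 105.12,
  127.92, 105.84, 173.40)

.datasets <- list(
  kevlar76 = list(
    values = .kevlar76, units = "lifetime (stress cycles, scaled)",
    note = paste("Fatigue-fracture lifetimes of 76 Kevlar 373/epoxy",
                 "specimens under constant 90% stress until all failed")),
  guinea72 = list(
    values = .guinea72, units = "survival time (days, scaled)",
    note = paste("Survival times of 72 guinea pigs infected with",
                 "virulent tubercle bacilli")),
  bearings23 = list(
    values = .bearings23, units = "millions of revolutions",
    note = "Revolutions to failure of 23 ball bearings in a life test")
)

#' Bundled classical lifetime datasets
#'
#' Three small, widely reanalysed reliability/survival samples, stored to
#' full printed precision: `"kevlar76"` (76 fatigue-fracture lifetimes of
#' Kevlar 373/epoxy specimens), `"guinea72"` (72 survival times of guinea
#' pigs infected with tubercle bacilli) and `"bearings23"` (millions of
#' revolutions to failure of 23 ball bearings).
#'
#' @param name one of `"kevlar76"`, `"guinea72"`, `"bearings23"`.
#' @return An object of class `"lifetime_dataset"`: a list with `name`,
#'   `values` (numeric vector, in listed order), `units` and `note`.
#' @examples
#' d <- load_dataset("bearings23")
#' length(d$values)
#' @export
load_dataset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.datasets))
    stop("unknown dataset; choose one of: ",
         paste(names(.datasets), collapse = ", "), call. = FALSE)
  d <- .datasets[[name]]
  structure(list(name = name, values = d$values, units = d$units,
                 note = d$note),
            class = "lifetime_dataset")
}

#' @export
print.lifetime_dataset <- function(x, ...) {
  cat(sprintf("%s: %d observations [%s]\n%s\n", x$name, length(x$values),
              x$units, x$note))
  invisible(x)
}

#' Descriptive statistics for a lifetime sample
#'
#' Summarises a sample with the quantities customarily tabulated for
#' lifetime data: minimum, quartiles (linear interpolation of order
#' statistics at plotting positions \eqn{(k-1)/(n-1)}, i.e. R's default
#' type-7 quantiles), mean, maximum, standard deviation (\eqn{n-1}
#' denominator), and moment-ratio skewness \eqn{m_3/m_2^{3/2}} and
#' (non-excess) kurtosis \eqn{m_4/m_2^2} with central sample moments
#' \eqn{m_k = n^{-1}\sum(x_i - \bar x)^k}.
#'
#' @param x numeric vector of at least 4 observations.
#' @return A one-row `data.frame` with columns `min`, `q1`, `median`,
#'   `mean`, `q3`, `max`, `sd`, `skewness`, `kurtosis`.
#' @examples
#' describe_sample(load_dataset("kevlar76")$values)
#' @export
describe_sample <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L)
    stop("need at least 4 observations to summarise", call. = FALSE)
  m <- mean(x)
  mk <- function(k) mean((x - m)^k)
  data.frame(
    min = min(x),
    q1 = unname(quantile(x, 0.25)),
    median = median(x),
    mean = m,
    q3 = unname(quantile(x, 0.75)),
    max = max(x),
    sd = sd(x),
    skewness = mk(3) / mk(2)^1.5,
    kurtosis = mk(4) / mk(2)^2
  )
}
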