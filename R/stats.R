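#' Bartlett test statistic from variance summaries
#'
#' Bartlett's homogeneity-of-variance statistic computed directly from
#' per-group sample variances and sizes:
#' \deqn{T = \frac{(N-k)\ln s_p^2 - \sum_i (n_i-1)\ln s_i^2}{C}, \quad
#'   C = 1 + \frac{\sum_i 1/(n_i-1) - 1/(N-k)}{3(k-1)},}
#' with \eqn{s_p^2} the pooled variance, \eqn{N} the total observation
#' count and \eqn{k} the number of groups. Under equal variances \eqn{T}
#' is approximately chi-square with \eqn{k-1} degrees of freedom.
#'
#' @param variances per-group sample variances, all > 0.
#' @param n per-group sizes (recycled if scalar), all >= 2.
#' @return A list: \code{statistic} (corrected \eqn{T}),
#'   \code{uncorrected} (numerator, exposed for diagnostics),
#'   \code{correction} (\eqn{C}), \code{df}, \code{pooled_variance},
#'   \code{p} (upper-tail chi-square probability).
#' @examples
#' bartlett_statistic(c(28.07, 31.36), n = 7)$statistic  # ~0.018, << 3.84
#' @export
bartlett_statistic <- function(variances, n) {
  k <- length(variances)
  if (k < 2) stop("need at least two variance samples", call. = FALSE)
  n <- rep_len(n, k)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(variances <= 0))
    stop("all variances must be positive", call. = FALSE)
  N <- sum(n)
  sp2 <- sum((n - 1) * variances) / (N - k)
  num <- (N - k) * log(sp2) - sum((n - 1) * log(variances))
  C <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  Tstat <- num / C
  list(statistic = Tstat, uncorrected = num, correction = C, df = k - 1,
       pooled_variance = sp2,
       p = stats::pchisq(Tstat, df = k - 1, lower.tail = FALSE))
}

#' Chi-square quantile
#'
#' Critical value of the chi-square distribution, e.g. 3.84 at the 0.95
#' quantile with 1 degree of freedom.
#'
#' @param p probability in (0, 1).
#' @param df degrees of freedom, >= 1.
#' @return The inverse chi-square CDF at \code{p}.
#' @export
chi2_quantile <- function(p, df) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stats::qchisq(p, df)
}

#' Combine independent standard deviations
#'
#' Root-sum-of-squares combination, used to propagate the chemoreflex-fit
#' residual SD into the group SD of the final augmentation.
#'
#' @param sds numeric vector of SDs, all >= 0.
#' @return \eqn{\sqrt{\sum \mathrm{sd}_i^2}}.
#' @examples
#' combine_sd(c(6.32, 1.73))  # 6.55
#' @export
combine_sd <- function(sds) {
  if (any(sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  sqrt(sum(sds^2))
}

#' Standard error of a mean
#'
#' @param sd standard deviation, >= 0.
#' @param n sample size, >= 1.
#' @return \code{sd / sqrt(n)}.
#' @examples
#' standard_error(6.55, 7)  # 2.48
#' @export
standard_error <- function(sd, n) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  sd / sqrt(n)
}

#' Paired t test
#'
#' Standard paired t on the elementwise differences, \eqn{df = n - 1}.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return A list: \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_diff}.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2", call. = FALSE)
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0)
    stop("zero variance of differences: t statistic undefined",
         call. = FALSE)
  n <- length(d)
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = n - 1,
       p = 2 * stats::pt(-abs(tval), df = n - 1),
       mean_diff = mean(d))
}
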