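#' Subject-level median beta over channels
#'
#' @param per_channel_betas numeric vector, one beta per channel
#' @param excluded_channels integer indices to drop before the median
#' @return the median beta (Molar)
#' @export
subject_median <- function(per_channel_betas, excluded_channels = integer(0)) {
  keep <- setdiff(seq_along(per_channel_betas), excluded_channels)
  if (!length(keep)) stop("all channels excluded")
  stats::median(per_channel_betas[keep])
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and p-value (`stats::shapiro.test`), restricted to
#' the small-sample range the test is recommended for.
#'
#' @param values numeric vector, 3 <= n <= 50
#' @return list with `W` and `p`
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 50) stop("shapiro_wilk needs 3 <= n <= 50")
  if (stats::sd(values) == 0) stop("degenerate (constant) input")
  s <- stats::shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value)
}

#' IQR fence outlier flags
#'
#' Flags values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`. Quartiles
#' use linear interpolation (type 7, the R default); the fences depend on
#' the quartile convention, hence it is fixed and documented here.
#'
#' @param values numeric vector, n >= 4
#' @return logical vector of flags
#' @export
iqr_outliers <- function(values) {
  if (length(values) < 4) stop("need n >= 4 for quartile fences")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Two-sided one-sample t-test against a reference value
#'
#' @param values numeric vector, n >= 2
#' @param reference null-hypothesis mean (the reference beta, Molar)
#' @return list with `t`, `p`, `df`
#' @export
one_sample_t <- function(values, reference) {
  if (length(values) < 2) stop("need n >= 2")
  if (stats::sd(values) == 0) stop("zero variance; t undefined")
  tt <- stats::t.test(values, mu = reference)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Two-sided paired t-test
#'
#' One-sample t-test on the differences. When the pairs are numerically
#' identical (as when the same linear filter was applied in OD versus
#' concentration space), the comparison is degenerate and is reported as
#' `no_difference` instead of a statistic.
#'
#' @param a,b numeric vectors of equal length
#' @param tol differences below `tol * max(|a|)` count as zero
#' @return list with `t`, `p`, `df`, or `list(no_difference = TRUE)` when
#'   all differences vanish
#' @export
paired_t <- function(a, b, tol = 1e-12) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  scale <- max(abs(c(a, b)), 1e-300)
  if (all(abs(d) <= tol * scale))
    return(list(no_difference = TRUE, t = NA_real_, p = NA_real_,
                df = length(a) - 1))
  if (stats::sd(d) == 0) stop("constant nonzero differences; t undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       no_difference = FALSE)
}

#' Group-level result for one sweep cell
#'
#' Aggregates subject median betas: Shapiro-Wilk normality, IQR outlier
#' flags (reported, not removed), and the one-sample t-test against the
#' reference beta at alpha = 0.05.
#'
#' @param subject_medians numeric vector of per-subject median betas
#' @param reference_beta the generating amplitude (Molar)
#' @param remove_outliers drop IQR-flagged subjects before the t-test
#' @return a `group_result`
#' @export
group_result <- function(subject_medians, reference_beta,
                         remove_outliers = FALSE) {
  sw <- shapiro_wilk(subject_medians)
  fl <- iqr_outliers(subject_medians)
  vals <- if (remove_outliers) subject_medians[!fl] else subject_medians
  tt <- one_sample_t(vals, reference_beta)
  structure(
    list(subject_medians = subject_medians, shapiro_w = sw$W,
         shapiro_p = sw$p, outlier_flags = fl, t_stat = tt$t, t_p = tt$p,
         df = tt$df, reference_beta = reference_beta,
         mean_beta = mean(vals), bias = mean(vals) - reference_beta,
         alpha = 0.05),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "<group_result> n=%d  mean beta=%.3g  ref=%.3g  t(%d)=%.3f  p=%.3g  W=%.3f  outliers=%d\n",
    length(x$subject_medians), x$mean_beta, x$reference_beta, x$df,
    x$t_stat, x$t_p, x$shapiro_w, sum(x$outlier_flags)))
  invisible(x)
}
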