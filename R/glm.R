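#' GLM design matrix for the block protocol
#'
#' Two columns: the unit-peak task regressor (boxcar convolved with the
#' HRF, the same construction as the injected task component) and a
#' constant. Because the regressor has unit peak, the fitted task beta is
#' directly comparable to the generating amplitude in Molar.
#'
#' @param protocol a [protocol_spec()]
#' @param hrf an [hrf_spec()]
#' @param fs sampling rate, Hz
#' @param n_samples expected number of rows (checked against the protocol)
#' @return a `design_matrix` with fields `X` (n x 2), `fs`, `n_samples`
#' @export
build_design <- function(protocol, hrf, fs, n_samples = NULL) {
  boxcar <- build_boxcar(protocol, fs)
  if (!is.null(n_samples) && length(boxcar$values) != n_samples)
    stop("n_samples does not match the protocol sampled at fs (",
         length(boxcar$values), " vs ", n_samples, ")")
  task <- make_task_component(boxcar, sample_hrf(hrf, fs), 1)$values
  X <- cbind(task = task, constant = 1)
  if (qr(X)$rank < 2L) stop("design matrix is rank deficient")
  structure(list(X = X, fs = fs, n_samples = nrow(X)),
            class = "design_matrix")
}

#' Ordinary least-squares GLM fit
#'
#' Exact least-squares solution (QR via `stats::lm.fit`); residual degrees
#' of freedom `n - 2`.
#'
#' @param y a [channel_series()] or numeric vector
#' @param X a `design_matrix` from [build_design()]
#' @param correction label recorded on the fit (`"none"`, `"downsample"`,
#'   `"precolor"`)
#' @return a `glm_fit` with `beta_task`, `beta_const`, `residuals`, `dof`,
#'   `correction`
#' @export
fit_ols <- function(y, X, correction = "none") {
  stopifnot(inherits(X, "design_matrix"))
  yv <- as_series_values(y)
  if (anyNA(yv) || any(!is.finite(yv))) stop("non-finite samples in y")
  if (length(yv) != X$n_samples)
    stop("length(y) != design rows (", length(yv), " vs ", X$n_samples, ")")
  fit <- stats::lm.fit(X$X, yv)
  structure(
    list(beta_task = unname(fit$coefficients["task"]),
         beta_const = unname(fit$coefficients["constant"]),
         residuals = fit$residuals, dof = length(yv) - 2L,
         correction = correction),
    class = "glm_fit"
  )
}

#' Precoloring: smooth data and design with an HRF-shaped kernel
#'
#' Convolves both the data and every design column with the HRF kernel
#' normalized to unit sum (so the constant column is preserved), using
#' same-length output with odd reflection padding. Imposing this known
#' smooth autocorrelation dominates the intrinsic serial correlation of the
#' data, the classical precoloring treatment.
#'
#' @param y a [channel_series()] or numeric vector
#' @param X a `design_matrix`
#' @param hrf_kernel sampled HRF kernel at the data rate
#' @return list with smoothed `y` (numeric) and `X` (`design_matrix`)
#' @export
precolor <- function(y, X, hrf_kernel) {
  stopifnot(inherits(X, "design_matrix"))
  k <- hrf_kernel / sum(hrf_kernel)
  ys <- smooth_same(as_series_values(y), k)
  Xs <- apply(X$X, 2, smooth_same, kernel = k)
  colnames(Xs) <- colnames(X$X)
  X2 <- X
  X2$X <- Xs
  list(y = ys, X = X2)
}

# same-length convolution with odd reflection padding; output aligned so a
# symmetric kernel introduces no shift and a unit-sum kernel preserves
# constants exactly
smooth_same <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  pad <- reflect_pad(x, m)
  full <- stats::convolve(pad$x, rev(kernel), type = "open")
  # centre of the kernel mass for alignment: use (m-1)/2 (causal kernels
  # shift; the same shift is applied to y and X so betas are unaffected)
  off <- pad$p + 1L
  full[off:(off + n - 1L)]
}

#' Down-sample a series with cubic spline interpolation
#'
#' Evaluates a cubic spline through the original samples on the new
#' uniform grid spanning the same record.
#'
#' @param y a [channel_series()] or numeric vector
#' @param fs original rate (taken from the series if not given)
#' @param fs_new new rate, Hz (must be < fs)
#' @return a [channel_series()] at `fs_new` (or numeric vector for plain
#'   numeric input)
#' @export
downsample_spline <- function(y, fs = NULL, fs_new = 1) {
  x <- as_series_values(y)
  if (is.null(fs)) {
    if (!inherits(y, "channel_series")) stop("fs required for numeric input")
    fs <- y$fs
  }
  if (fs_new >= fs) stop("fs_new must be smaller than fs")
  t_old <- (seq_along(x) - 1) / fs
  t_new <- seq(0, t_old[length(t_old)], by = 1 / fs_new)
  sf <- stats::splinefun(t_old, x, method = "fmm")
  out <- sf(t_new)
  if (inherits(y, "channel_series")) {
    y$values <- out
    y$fs <- fs_new
    y
  } else out
}

#' Fit the GLM under one of the three serial-correlation treatments
#'
#' `"none"`: plain OLS at the acquisition rate. `"downsample"`: data
#' spline-down-sampled to 1 Hz, design rebuilt at 1 Hz. `"precolor"`:
#' data and design smoothed with the unit-sum HRF kernel before OLS.
#'
#' @param y a [channel_series()]
#' @param protocol a [protocol_spec()]
#' @param hrf an [hrf_spec()]
#' @param correction one of `"none"`, `"downsample"`, `"precolor"`
#' @param fs_new down-sampling target rate, Hz
#' @return a `glm_fit`
#' @export
fit_glm_corrected <- function(y, protocol, hrf,
                              correction = c("none", "downsample", "precolor"),
                              fs_new = 1) {
  correction <- match.arg(correction)
  stopifnot(inherits(y, "channel_series"))
  fs <- y$fs
  if (correction == "none") {
    X <- build_design(protocol, hrf, fs)
    fit_ols(y, X, "none")
  } else if (correction == "downsample") {
    yd <- downsample_spline(y, fs_new = fs_new)
    X <- build_design(protocol, hrf, fs)
    # the design columns go through the same spline operator as the data:
    # spline evaluation is linear, so noise-free recovery stays exact
    Xd <- X
    Xd$X <- apply(X$X, 2, downsample_spline, fs = fs, fs_new = fs_new)
    colnames(Xd$X) <- colnames(X$X)
    Xd$fs <- fs_new
    Xd$n_samples <- nrow(Xd$X)
    fit_ols(yd$values, Xd, "downsample")
  } else {
    X <- build_design(protocol, hrf, fs)
    pc <- precolor(y, X, sample_hrf(hrf, fs))
    fit_ols(pc$y, pc$X, "precolor")
  }
}
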