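#' Motion-artifact detection / correction parameters
#'
#' Semantics follow the targeted-PCA correction as parameterized in Homer2:
#' `t_motion` is the sliding detection window, `t_mask` the dilation added
#' around each detection, `std_thresh` the threshold in multiples of the
#' channel's first-difference SD (robust to slow drifts), `amp_thresh` an
#' absolute amplitude-change threshold in signal units, `n_sv` the fraction
#' of segment variance removed by PCA, `max_iter` the recursion cap.
#'
#' @param t_motion detection window, seconds
#' @param t_mask mask dilation, seconds
#' @param std_thresh SD multiples
#' @param amp_thresh absolute threshold, signal units
#' @param n_sv fraction of variance to remove, in (0, 1]
#' @param max_iter maximum detect-correct iterations
#' @return a `motion_params`
#' @export
motion_params <- function(t_motion = 0.5, t_mask = 1, std_thresh = 10,
                          amp_thresh = 5, n_sv = 0.97, max_iter = 5) {
  vals <- c(t_motion, t_mask, std_thresh, amp_thresh, n_sv, max_iter)
  if (any(vals <= 0)) stop("all motion parameters must be positive")
  if (n_sv > 1) stop("n_sv must be in (0, 1]")
  structure(list(t_motion = t_motion, t_mask = t_mask,
                 std_thresh = std_thresh, amp_thresh = amp_thresh,
                 n_sv = n_sv, max_iter = as.integer(max_iter)),
            class = "motion_params")
}

# contiguous TRUE runs -> matrix of (start, end) sample indices
mask_segments <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect motion-artifact samples across channels
#'
#' A sample is flagged when, within any window of length `t_motion`
#' containing it, the signal excursion (max - min) exceeds
#' `std_thresh * SD(diff(channel))` or `amp_thresh`. Flags are dilated by
#' `t_mask` on each side and the mask is the union over channels.
#'
#' @param od_channels list of OD [channel_series()] (or numeric vectors)
#' @param params a [motion_params()]
#' @param fs sampling rate (taken from the first series if not given)
#' @return an `artifact_mask` with per-sample `flag`, `segments`
#'   (start_s / end_s), `fs`
#' @export
detect_motion <- function(od_channels, params, fs = NULL) {
  stopifnot(inherits(params, "motion_params"))
  if (is.null(fs)) fs <- od_channels[[1]]$fs
  n <- length(as_series_values(od_channels[[1]]))
  w <- max(2L, seconds_to_samples(params$t_motion, fs))
  if (n < 2L * w) stop("record too short for the detection window")
  flag <- rep(FALSE, n)
  for (ch in od_channels) {
    x <- as_series_values(ch)
    sd_d <- stats::sd(diff(x))
    thr <- min(params$std_thresh * sd_d, params$amp_thresh)
    # rolling max - rolling min over windows of length w
    exc <- roll_range(x, w)
    hit <- exc > thr
    # a window hit flags all samples it contains
    chflag <- rep(FALSE, n)
    for (i in which(hit)) chflag[i:(i + w - 1L)] <- TRUE
    flag <- flag | chflag
  }
  dil <- seconds_to_samples(params$t_mask, fs)
  if (any(flag) && dil > 0L) {
    seg <- mask_segments(flag)
    for (k in seq_len(nrow(seg))) {
      i0 <- max(1L, seg[k, 1] - dil)
      i1 <- min(n, seg[k, 2] + dil)
      flag[i0:i1] <- TRUE
    }
  }
  seg <- mask_segments(flag)
  structure(
    list(flag = flag,
         segments = data.frame(start_s = (seg[, 1] - 1) / fs,
                               end_s = (seg[, 2] - 1) / fs),
         fs = fs),
    class = "artifact_mask"
  )
}

# excursion (max - min) of each length-w window; returns length n-w+1
roll_range <- function(x, w) {
  n <- length(x)
  ix <- seq_len(n - w + 1L)
  mx <- x[ix]; mn <- x[ix]
  for (k in 1L:(w - 1L)) {
    mx <- pmax(mx, x[ix + k])
    mn <- pmin(mn, x[ix + k])
  }
  mx - mn
}

#' Targeted PCA motion correction
#'
#' Within flagged segments only, the multi-channel segment data are
#' decomposed by PCA and the leading components removed until the
#' cumulative explained variance reaches `n_sv`; each corrected segment is
#' then re-anchored with a per-channel constant so its left edge continues
#' from the preceding sample. Detection and correction are repeated until
#' the mask is empty or `max_iter` is reached. Samples outside the mask
#' are returned bit-identical.
#'
#' @param od_channels list of OD [channel_series()]
#' @param mask an `artifact_mask` from [detect_motion()] (re-computed on
#'   later iterations)
#' @param params a [motion_params()]
#' @return list with `channels` (corrected list), `n_iter`, `final_mask`
#' @export
tpca_correct <- function(od_channels, mask = NULL, params = motion_params()) {
  fs <- od_channels[[1]]$fs
  if (is.null(mask)) mask <- detect_motion(od_channels, params, fs)
  chans <- od_channels
  n_iter <- 0L
  while (any(mask$flag) && n_iter < params$max_iter) {
    chans <- tpca_once(chans, mask, params)
    n_iter <- n_iter + 1L
    mask <- detect_motion(chans, params, fs)
  }
  list(channels = chans, n_iter = n_iter, final_mask = mask)
}

tpca_once <- function(chans, mask, params) {
  seg <- mask_segments(mask$flag)
  vals <- do.call(cbind, lapply(chans, as_series_values))
  for (k in seq_len(nrow(seg))) {
    i0 <- seg[k, 1]; i1 <- seg[k, 2]
    if (i1 - i0 + 1L < 3L) {
      warning("motion segment shorter than 3 samples skipped")
      next
    }
    Y <- vals[i0:i1, , drop = FALSE]
    mu <- colMeans(Y)
    Yc <- sweep(Y, 2, mu)
    sv <- svd(Yc)
    var_frac <- cumsum(sv$d^2) / sum(sv$d^2)
    n_rm <- which(var_frac >= params$n_sv)[1]
    proj <- sv$u[, seq_len(n_rm), drop = FALSE] %*%
      diag(sv$d[seq_len(n_rm)], n_rm) %*%
      t(sv$v[, seq_len(n_rm), drop = FALSE])
    Yclean <- sweep(Yc - proj, 2, mu, `+`)
    # left-edge re-anchoring per channel
    for (j in seq_len(ncol(vals))) {
      ref <- if (i0 > 1L) vals[i0 - 1L, j] else Yclean[1L, j]
      Yclean[, j] <- Yclean[, j] - Yclean[1L, j] + ref
    }
    vals[i0:i1, ] <- Yclean
  }
  lapply(seq_along(chans), function(j)
    series_with_values(chans[[j]], vals[, j]))
}

#' Export an artifact mask as a segments table
#'
#' @param mask an `artifact_mask`
#' @param path output TSV path (columns: start_s, end_s)
#' @export
write_mask_segments <- function(mask, path) {
  utils::write.table(mask$segments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
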