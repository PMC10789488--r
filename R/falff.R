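#' BOLD time-series container
#'
#' Voxel x time matrix with repetition time and optional nuisance series.
#'
#' @param series Numeric matrix, voxels in rows, time points in columns
#'   (>= 16 time points).
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param motion6 Optional time x 6 matrix of rigid-body motion parameters.
#' @param wm_signal,csf_signal Optional mean white-matter / CSF signals
#'   (length = number of time points).
#' @return An object of class `timeseries_set`.
#' @export
timeseries_set <- function(series, tr_seconds, motion6 = NULL,
                           wm_signal = NULL, csf_signal = NULL) {
  series <- as.matrix(series)
  n_t <- ncol(series)
  stopifnot(n_t >= 16L, tr_seconds > 0)
  if (!is.null(motion6)) stopifnot(nrow(motion6) == n_t, ncol(motion6) == 6L)
  if (!is.null(wm_signal)) stopifnot(length(wm_signal) == n_t)
  if (!is.null(csf_signal)) stopifnot(length(csf_signal) == n_t)
  structure(list(series = series, tr_seconds = tr_seconds, motion6 = motion6,
                 wm_signal = wm_signal, csf_signal = csf_signal),
            class = "timeseries_set")
}

#' Friston-24 motion regressor expansion
#'
#' Expands six rigid-body parameters R(t) into the 24-column set
#' \[R(t), R(t-1), R(t)^2, R(t-1)^2\]; the lagged rows at t = 1 are zero.
#'
#' @param motion6 Time x 6 numeric matrix.
#' @return Time x 24 matrix, column blocks in the order above.
#' @export
build_friston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("build_friston24: motion matrix must have 6 columns")
  lag1 <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  out <- cbind(motion6, lag1, motion6^2, lag1^2)
  colnames(out) <- c(paste0("R", 1:6), paste0("R", 1:6, "_lag"),
                     paste0("R", 1:6, "_sq"), paste0("R", 1:6, "_lag_sq"))
  out
}

#' Nuisance regression of voxel time series
#'
#' Per voxel, OLS residuals of the series on intercept + the supplied
#' regressors (typically Friston-24 motion plus mean WM and CSF signals).
#'
#' @param ts A `timeseries_set`.
#' @param regressors Time x k numeric matrix.
#' @return A `timeseries_set` holding the residual series.
#' @export
nuisance_regress_timeseries <- function(ts, regressors) {
  regressors <- as.matrix(regressors)
  n_t <- ncol(ts$series)
  if (nrow(regressors) != n_t)
    stop("nuisance_regress_timeseries: regressor rows != time points")
  X <- cbind(intercept = 1, regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
    stop("nuisance_regress_timeseries: rank-deficient regressors: ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  res <- t(stats::lm.fit(X, t(ts$series))$residuals)
  timeseries_set(res, ts$tr_seconds, ts$motion6, ts$wm_signal, ts$csf_signal)
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' Per voxel: demean (optionally also remove a linear trend), discrete
#' Fourier transform, amplitude at each positive frequency = sqrt of
#' periodogram power; fALFF = sum of amplitudes at in-band frequencies
#' divided by the sum over all positive frequencies. Band edges are
#' inclusive. Voxels with zero total amplitude are returned `NA`.
#'
#' @param ts A `timeseries_set`.
#' @param low_hz,high_hz Frequency band in Hz, default 0.01-0.08; must
#'   satisfy 0 < low < high <= Nyquist = 1/(2 tr).
#' @param detrend Also remove a linear trend before the transform (default
#'   FALSE: the canonical definition demeans only; enable for drifting
#'   acquisitions, at the cost of ramp leakage into the denominator).
#' @param ratio `"amplitude"` (default): ratio of summed amplitudes;
#'   `"rms"`: ratio of root-mean-square amplitudes (band mean vs full mean),
#'   an alternative reading of the fALFF definition.
#' @return Numeric vector of fALFF in \[0, 1\] per voxel (row of `series`).
#' @export
compute_falff <- function(ts, low_hz = 0.01, high_hz = 0.08,
                          detrend = FALSE, ratio = c("amplitude", "rms")) {
  ratio <- match.arg(ratio)
  n_t <- ncol(ts$series)
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) stop("compute_falff: invalid band")
  if (high_hz > nyquist + 1e-12)
    stop("compute_falff: band exceeds Nyquist frequency ", signif(nyquist, 4), " Hz")
  Y <- ts$series
  tt <- seq_len(n_t)
  if (detrend) {
    X <- cbind(1, tt - mean(tt))
    Y <- t(stats::lm.fit(X, t(Y))$residuals)
  } else {
    Y <- Y - rowMeans(Y)
  }
  # positive-frequency amplitudes (exclude DC; Nyquist bin kept if present)
  ft <- stats::mvfft(t(Y))
  pos <- seq(2L, floor(n_t / 2) + 1L)
  freqs <- (pos - 1L) / (n_t * ts$tr_seconds)
  amp <- Mod(ft[pos, , drop = FALSE])
  in_band <- freqs >= low_hz - 1e-12 & freqs <= high_hz + 1e-12
  if (ratio == "amplitude") {
    num <- colSums(amp[in_band, , drop = FALSE])
    den <- colSums(amp)
  } else {
    num <- sqrt(colMeans(amp[in_band, , drop = FALSE]^2))
    den <- sqrt(colMeans(amp^2))
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  unname(out)
}
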