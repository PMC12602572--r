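## Timeseries-level denoising: motion outlier detection, CompCor-style
## nuisance components, confound regression, band-pass filtering.
## The fixed pipeline order is outliers -> confound build -> regression ->
## band-pass; image-space steps (realignment, normalisation, smoothing) are
## out of scope here and assumed done upstream.

#' Framewise displacement
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the six rigid-body parameters, with rotations converted to
#' mm on a sphere of radius `head_radius_mm`. The first frame has FD 0.
#'
#' @param trace Numeric matrix, time x 6: three translations (mm) then three
#'   rotations (radians).
#' @param head_radius_mm Head radius used to convert radians to mm
#'   (default 50, the conventional value).
#' @return Numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2) stop("motion trace needs at least 2 frames")
  if (ncol(trace) != 6) stop("motion trace must have 6 columns (3 trans, 3 rot)")
  if (!all(is.finite(trace))) stop("non-finite motion parameters")
  if (!is.finite(head_radius_mm) || head_radius_mm <= 0)
    stop("'head_radius_mm' must be a positive number")
  d <- abs(diff(trace))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Detect motion / global-signal outlier frames
#'
#' Flags a frame when framewise displacement exceeds `fd_thresh` (strictly
#' above) or when the z-scored frame-to-frame change of the spatial-mean BOLD
#' signal exceeds `gs_thresh` standard deviations in absolute value. The
#' defaults (0.9 mm, 5 SD) are the conservative ART preset.
#'
#' @param fd Per-frame framewise displacement (mm), from
#'   [framewise_displacement()].
#' @param bold Time x ROI (or time x voxel) matrix for the same run.
#' @param fd_thresh FD threshold in mm.
#' @param gs_thresh Global-signal-change threshold in standard deviations.
#' @return A list of class `outlier_mask`: `flags` (logical per frame),
#'   `frames` (flagged indices), `n_fd`, `n_gs` (per-trigger counts; a frame
#'   may trip both).
#' @export
detect_outliers <- function(fd, bold, fd_thresh = 0.9, gs_thresh = 5) {
  bold <- as.matrix(bold)
  if (length(fd) != nrow(bold))
    stop("fd series and BOLD run lengths differ")
  gs <- rowMeans(bold)
  dgs <- c(0, diff(gs))
  s <- stats::sd(dgs)
  if (s == 0) {
    warning("zero-variance global signal; no global-signal flags")
    z <- rep(0, length(dgs))
  } else {
    z <- (dgs - mean(dgs)) / s
  }
  fd_hit <- fd > fd_thresh
  gs_hit <- abs(z) > gs_thresh
  flags <- fd_hit | gs_hit
  structure(list(flags = flags, frames = which(flags),
                 n_fd = sum(fd_hit), n_gs = sum(gs_hit),
                 fd_thresh = fd_thresh, gs_thresh = gs_thresh),
            class = "outlier_mask")
}

#' CompCor nuisance components
#'
#' Estimates noise components from a noise-region (white-matter or CSF)
#' timeseries matrix: the average signal is computed, each voxel series is
#' orthogonalised against it (and the constant), and the top `k` principal
#' components of the residual are returned, unit-normalised, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param noise_ts Time x voxel matrix from a noise region.
#' @param k Number of components (default 5).
#' @return Time x k matrix (columns `CC1..CCk`); fewer columns, with a
#'   warning, if the residual rank is below `k`.
#' @export
compcor <- function(noise_ts, k = 5L) {
  noise_ts <- as.matrix(noise_ts)
  k <- as.integer(k)
  if (k == 0L) return(matrix(numeric(0), nrow(noise_ts), 0))
  if (k >= min(dim(noise_ts)))
    stop("'k' must be smaller than both dimensions of the noise matrix")
  avg <- rowMeans(noise_ts)
  basis <- cbind(1, avg)
  resid <- noise_ts - basis %*% qr.coef(qr(basis), noise_ts)
  sv <- svd(resid)
  pos <- sv$d > max(dim(resid)) * max(sv$d, 0) * 1e-12
  rank <- sum(pos)
  if (rank < k) {
    warning("noise matrix rank (", rank, ") below k = ", k,
            "; returning ", rank, " components")
    k <- rank
  }
  comp <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(comp))) {
    i_max <- which.max(abs(comp[, j]))
    if (comp[i_max, j] < 0) comp[, j] <- -comp[, j]
  }
  colnames(comp) <- paste0("CC", seq_len(ncol(comp)))
  comp
}

#' Assemble a confound matrix
#'
#' Builds the nuisance design used for denoising: 5 white-matter CompCor
#' components, 5 CSF CompCor components, 6 motion parameters and their
#' first-order backward differences (12 factors), one indicator column per
#' flagged outlier frame (spike regression), a linear trend and a constant.
#' Exactly duplicated columns are dropped.
#'
#' @param n_timepoints Run length.
#' @param motion Optional time x 6 motion trace.
#' @param compcor_wm,compcor_csf Optional component matrices from
#'   [compcor()].
#' @param outliers Optional `outlier_mask` (or logical vector).
#' @return Time x regressor matrix with named columns, full column rank.
#' @export
build_confound_matrix <- function(n_timepoints, motion = NULL,
                                  compcor_wm = NULL, compcor_csf = NULL,
                                  outliers = NULL) {
  cols <- list()
  if (!is.null(compcor_wm)) {
    colnames(compcor_wm) <- paste0("wm_", seq_len(ncol(compcor_wm)))
    cols$wm <- compcor_wm
  }
  if (!is.null(compcor_csf)) {
    colnames(compcor_csf) <- paste0("csf_", seq_len(ncol(compcor_csf)))
    cols$csf <- compcor_csf
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    dmotion <- rbind(0, diff(motion))
    colnames(motion) <- paste0("mot_", c("tx", "ty", "tz", "rx", "ry", "rz"))
    colnames(dmotion) <- paste0("d", colnames(motion))
    cols$motion <- cbind(motion, dmotion)
  }
  if (!is.null(outliers)) {
    flags <- if (inherits(outliers, "outlier_mask")) outliers$flags else outliers
    fr <- which(flags)
    if (length(fr)) {
      spikes <- matrix(0, n_timepoints, length(fr))
      spikes[cbind(fr, seq_along(fr))] <- 1
      colnames(spikes) <- paste0("outlier_", fr)
      cols$spikes <- spikes
    }
  }
  trend <- seq_len(n_timepoints) - (n_timepoints + 1) / 2
  cols$trend <- matrix(trend / max(abs(trend)), ncol = 1,
                       dimnames = list(NULL, "trend"))
  cols$const <- matrix(1, n_timepoints, 1, dimnames = list(NULL, "constant"))
  x <- do.call(cbind, cols)
  x <- x[, !duplicated(t(x)), drop = FALSE]
  if (qr(x)$rank < ncol(x))
    warning("confound matrix is rank deficient after duplicate removal")
  x
}

#' Regress confounds out of a timeseries matrix
#'
#' Replaces every column of `y` by its ordinary-least-squares residual
#' against the confound matrix; residuals are orthogonal to every confound
#' column, and the operation is idempotent.
#'
#' @param y Time x series matrix (ROI panel subject or voxel matrix).
#' @param confounds Time x regressor matrix from [build_confound_matrix()].
#' @return Residual matrix of the same shape and dimnames as `y`.
#' @export
regress_confounds <- function(y, confounds) {
  y <- as.matrix(y)
  confounds <- as.matrix(confounds)
  if (nrow(y) != nrow(confounds))
    stop("BOLD run and confound matrix lengths differ")
  if (ncol(confounds) >= nrow(y))
    stop("as many confounds as timepoints: zero residual degrees of freedom")
  qrx <- qr(confounds)
  res <- y - confounds %*% qr.coef(qrx, y)
  res[is.na(res)] <- 0
  dimnames(res) <- dimnames(y)
  res
}

#' Band-pass filter BOLD timeseries
#'
#' Discrete-Fourier ideal (brick-wall) filter: DFT components with frequency
#' inside `[f_lo, f_hi]` are kept, everything else (including the DC term) is
#' zeroed. A Butterworth alternative (4th order, zero-phase via forward and
#' reverse application) is available with `method = "butterworth"`.
#'
#' @param y Numeric vector or time x series matrix.
#' @param tr Repetition time in seconds.
#' @param f_lo,f_hi Passband edges in Hz (defaults 0.008 and 0.09).
#' @param method `"fft"` (default) or `"butterworth"`.
#' @return Filtered data of the same shape.
#' @export
bandpass <- function(y, tr, f_lo = 0.008, f_hi = 0.09, method = c("fft", "butterworth")) {
  method <- match.arg(method)
  vec <- is.null(dim(y))
  y <- as.matrix(y)
  nyq <- 1 / (2 * tr)
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (f_hi >= nyq)
    stop("upper band edge ", f_hi, " Hz is at or above the Nyquist frequency ",
         signif(nyq, 4), " Hz for TR = ", tr, " s")
  n_t <- nrow(y)
  out <- if (method == "fft") {
    freqs <- (seq_len(n_t) - 1) / (n_t * tr)
    folded <- pmin(freqs, 1 / tr - freqs)
    keep <- folded >= f_lo & folded <= f_hi
    Re(stats::mvfft(stats::mvfft(y) * keep, inverse = TRUE)) / n_t
  } else {
    bf <- signal::butter(4, c(f_lo, f_hi) / nyq, type = "pass")
    apply(y, 2, function(x) signal::filtfilt(bf, x - mean(x)))
  }
  out <- matrix(out, nrow = n_t, dimnames = dimnames(y))
  if (vec) drop(out) else out
}

#' Denoise one subject's run
#'
#' Applies the fixed denoising order: outlier detection, confound-matrix
#' assembly, confound regression, band-pass filtering. Any component may be
#' omitted by passing `NULL`.
#'
#' @param bold Time x ROI matrix.
#' @param tr Repetition time (s).
#' @param motion Optional time x 6 motion trace.
#' @param noise_wm,noise_csf Optional noise-region timeseries matrices fed to
#'   [compcor()].
#' @param fd_thresh,gs_thresh Outlier thresholds (see [detect_outliers()]).
#' @param band Passband in Hz.
#' @param filter_method Filter passed to [bandpass()].
#' @return A list: `bold` (denoised matrix), `outliers`, `confounds`,
#'   `log` (character record of the stages applied, in order).
#' @export
preprocess_subject <- function(bold, tr, motion = NULL, noise_wm = NULL,
                               noise_csf = NULL, fd_thresh = 0.9,
                               gs_thresh = 5, band = c(0.008, 0.09),
                               filter_method = "fft") {
  bold <- as.matrix(bold)
  log <- character(0)
  outliers <- NULL
  if (!is.null(motion)) {
    fd <- framewise_displacement(motion)
    outliers <- detect_outliers(fd, bold, fd_thresh, gs_thresh)
    log <- c(log, sprintf("outlier detection: %d frames flagged (%d FD, %d GS)",
                          length(outliers$frames), outliers$n_fd, outliers$n_gs))
  }
  cc_wm <- if (!is.null(noise_wm)) compcor(noise_wm) else NULL
  cc_csf <- if (!is.null(noise_csf)) compcor(noise_csf) else NULL
  confounds <- build_confound_matrix(nrow(bold), motion, cc_wm, cc_csf, outliers)
  log <- c(log, sprintf("confound regression: %d regressors", ncol(confounds)))
  bold <- regress_confounds(bold, confounds)
  bold <- bandpass(bold, tr, band[1], band[2], method = filter_method)
  log <- c(log, sprintf("band-pass %.3f-%.3f Hz (%s)", band[1], band[2],
                        filter_method))
  list(bold = bold, outliers = outliers, confounds = confounds, log = log)
}
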