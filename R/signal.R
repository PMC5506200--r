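#' Extract spherical-ROI mean time series from a 4D volume
#'
#' For each node center, averages the time courses of all voxels whose
#' centers lie within \code{radius_mm} (Euclidean distance in mm space,
#' voxel-center-in-sphere rule). The image's sform/qform affine maps voxel
#' indices to mm.
#'
#' @param image 4D array with an RNifti xform (as from
#'   \code{\link{render_volumes}} or \code{RNifti::readNifti}).
#' @param centers_mm n x 3 matrix of node centers (mm).
#' @param radius_mm sphere radius in mm (default 3).
#' @return region x scan matrix.
#' @export
extract_roi_timeseries <- function(image, centers_mm, radius_mm = 3) {
  stopifnot(radius_mm > 0, all(is.finite(centers_mm)))
  centers_mm <- matrix(centers_mm, ncol = 3)
  aff <- RNifti::xform(image)
  if (abs(det(aff)) < 1e-12) stop("image affine not invertible", call. = FALSE)
  inv <- solve(aff)
  dims <- dim(image)
  stopifnot(length(dims) == 4)
  arr <- as.array(image)
  out <- matrix(NA_real_, nrow(centers_mm), dims[4])
  for (r in seq_len(nrow(centers_mm))) {
    v0 <- (inv %*% c(centers_mm[r, ], 1))[1:3]      # voxel units, 0-based
    ## voxel size along each axis for the candidate bounding box
    vs <- sqrt(colSums(aff[1:3, 1:3]^2))
    rng <- lapply(1:3, function(a) {
      s <- max(0, floor(v0[a] - radius_mm / vs[a]))
      e <- min(dims[a] - 1, ceiling(v0[a] + radius_mm / vs[a]))
      if (s > e) integer(0) else s:e
    })
    vox <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    if (nrow(vox)) {
      mm <- t(aff[1:3, 1:3] %*% t(vox) + aff[1:3, 4])
      keep <- rowSums((mm - matrix(centers_mm[r, ], nrow(vox), 3,
                                   byrow = TRUE))^2) <= radius_mm^2
      vox <- vox[keep, , drop = FALSE]
    }
    if (!nrow(vox))
      stop("empty ROI: no voxel center within ", radius_mm,
           " mm of node ", r, call. = FALSE)
    acc <- 0
    for (q in seq_len(nrow(vox)))
      acc <- acc + arr[vox[q, 1] + 1, vox[q, 2] + 1, vox[q, 3] + 1, ]
    out[r, ] <- acc / nrow(vox)
  }
  rownames(out) <- rownames(centers_mm)
  out
}

# odd-reflection padded zero-phase Butterworth application
.filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 2, 3 * max(length(bf$b), length(bf$a)) * 10)
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]),
          x,
          2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-4 Butterworth, applied forward and backward (zero phase) with
#' odd-reflection edge padding to suppress filter transients. The default
#' band 0.008-0.09 Hz keeps block-cycle frequencies while removing scanner
#' drift and high-frequency noise.
#'
#' @param ts region x scan matrix (a vector is treated as one region).
#' @param tr_s repetition time in seconds.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   0 <= low < high < 1/(2 tr).
#' @param order filter order (default 4).
#' @return filtered matrix of the same shape, approximately zero mean per
#'   region.
#' @export
bandpass <- function(ts, tr_s, low_hz = 0.008, high_hz = 0.09, order = 4) {
  if (is.vector(ts)) ts <- matrix(ts, nrow = 1)
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop("infeasible band: need 0 <= low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  if (ncol(ts) < 16) stop("need at least 16 scans to filter", call. = FALSE)
  bf <- signal::butter(order, c(max(low_hz, 1e-6), high_hz) / nyq,
                       type = "pass")
  ## remove the mean first: DC is outside the passband and demeaning keeps
  ## numerical leakage of large offsets out of the filtered series
  out <- t(apply(ts, 1, function(x) {
    y <- .filtfilt_padded(bf, x - mean(x))
    y - mean(y)          # exact zero mean; DC lies outside the passband
  }))
  dimnames(out) <- dimnames(ts)
  out
}

#' Nuisance regression of confounds from ROI time series
#'
#' Regresses each region's series on an intercept, all confound columns and
#' (optionally) the first temporal derivatives of the WM/CSF columns, and
#' returns the residuals. Motion parameters enter as-is; derivatives are
#' added only for the WM and CSF signals. Confounds should be bandpassed
#' with the same filter as the data before calling, so removed frequencies
#' are not reintroduced.
#'
#' @param ts region x scan matrix.
#' @param confounds scan x k data.frame or matrix.
#' @param add_derivatives add first differences (first value 0) of columns
#'   named in \code{derivative_cols}.
#' @param derivative_cols columns whose derivatives join the design.
#' @return residual matrix, same shape as \code{ts}; residuals are
#'   orthogonal to every design column.
#' @export
regress_nuisance <- function(ts, confounds, add_derivatives = TRUE,
                             derivative_cols = c("wm", "csf")) {
  if (is.vector(ts)) ts <- matrix(ts, nrow = 1)
  X <- as.matrix(confounds)
  stopifnot(ncol(ts) == nrow(X))
  if (add_derivatives) {
    dcols <- intersect(derivative_cols, colnames(X))
    if (length(dcols)) {
      D <- apply(X[, dcols, drop = FALSE], 2, function(v) c(0, diff(v)))
      colnames(D) <- paste0(dcols, "_deriv")
      X <- cbind(X, D)
    }
  }
  X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("confound design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- t(qr.resid(qrX, t(ts)))
  dimnames(res) <- dimnames(ts)
  res
}

#' Denoise a subject: bandpass then nuisance regression
#'
#' Fixed order of operations: the ROI series and the confounds are both
#' bandpassed to the same band, then the confounds (plus WM/CSF derivatives)
#' are regressed out.
#'
#' @param ts a \code{subject_ts}.
#' @param low_hz,high_hz band edges in Hz.
#' @return region x scan matrix of cleaned residuals.
#' @export
denoise_subject <- function(ts, low_hz = 0.008, high_hz = 0.09) {
  stopifnot(inherits(ts, "subject_ts"))
  y <- bandpass(ts$data, ts$tr_s, low_hz, high_hz)
  cf <- bandpass(t(as.matrix(ts$confounds)), ts$tr_s, low_hz, high_hz)
  cf <- t(cf)
  colnames(cf) <- colnames(ts$confounds)
  regress_nuisance(y, cf)
}
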