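#' Coupling model for synthetic multi-subject BOLD data
#'
#' Defines the planted region-correlation structure and nuisance amplitudes
#' of the generator. Correlations are population values of the correlated
#' noise component; task, drift, motion and measurement noise are added on
#' top and shift observed correlations accordingly.
#'
#' @param r_homotopic correlation planted between homotopic homologs, [0, 1).
#' @param r_intra correlation between distinct same-hemisphere regions.
#' @param r_other correlation for all remaining region pairs (cross-
#'   hemisphere non-homotopic, and anything involving a midline region).
#' @param task_gain amplitude of the HRF-convolved task response in units of
#'   the correlated-noise standard deviation (0 disables the task signal).
#' @param noise_sd standard deviation of the correlated noise component.
#' @param drift_amp amplitude of the low-frequency (< 0.008 Hz) drift.
#' @param motion_coupling amplitude with which simulated motion and WM/CSF
#'   traces leak into the region signals.
#' @param measurement_sd standard deviation of i.i.d. white measurement
#'   noise added last; kept small by default so planted correlations are
#'   attenuated by < 1 percent.
#' @return An object of class \code{coupling_model}.
#' @export
coupling_model <- function(r_homotopic = 0.6, r_intra = 0.3, r_other = 0.1,
                           task_gain = 0.5, noise_sd = 1, drift_amp = 1,
                           motion_coupling = 0.4, measurement_sd = 0.05) {
  stopifnot(r_homotopic >= 0, r_homotopic < 1, r_intra >= 0, r_intra < 1,
            r_other >= 0, r_other < 1, task_gain >= 0, noise_sd > 0,
            drift_amp >= 0, motion_coupling >= 0, measurement_sd >= 0)
  structure(list(r_homotopic = r_homotopic, r_intra = r_intra,
                 r_other = r_other, task_gain = task_gain,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 motion_coupling = motion_coupling,
                 measurement_sd = measurement_sd),
            class = "coupling_model")
}

#' Build the planted region-correlation matrix
#'
#' Unit diagonal; \code{r_homotopic} on homotopic pairs, \code{r_intra} on
#' distinct same-hemisphere (L-L or R-R) pairs, \code{r_other} elsewhere.
#' If the result is not positive semi-definite it is repaired by flooring
#' eigenvalues at zero and re-normalising to unit diagonal; the repair is
#' flagged in the \code{"repaired"} attribute and rejected if it moves any
#' entry by more than \code{tol}.
#'
#' @param nodes a \code{nodeset}.
#' @param model a \code{coupling_model}.
#' @param tol maximum tolerated entry change during PSD repair.
#' @return correlation matrix with attribute \code{repaired} (logical).
#' @export
build_covariance <- function(nodes, model, tol = 0.05) {
  stopifnot(inherits(nodes, "nodeset"), inherits(model, "coupling_model"))
  n <- length(nodes$labels)
  hemi <- nodes$hemisphere
  C <- matrix(model$r_other, n, n)
  same <- outer(hemi, hemi, "==") & outer(hemi != "M", hemi != "M", "&")
  C[same] <- model$r_intra
  for (k in seq_len(nrow(nodes$pair_map))) {
    i <- nodes$pair_map[k, 1]; j <- nodes$pair_map[k, 2]
    C[i, j] <- C[j, i] <- model$r_homotopic
  }
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < -1e-10) {
    v <- pmax(ev$values, 0)
    R <- ev$vectors %*% (v * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    if (max(abs(R - C)) > tol)
      stop("coupling model implies a correlation matrix that cannot be ",
           "repaired to positive semi-definite within tolerance",
           call. = FALSE)
    C <- R
    repaired <- TRUE
  }
  attr(C, "repaired") <- repaired
  dimnames(C) <- list(nodes$labels, nodes$labels)
  C
}

# matrix square root via symmetric eigendecomposition (PSD input)
.mat_sqrt <- function(C) {
  ev <- eigen(C, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

# smoothed random walk, zero mean, unit sd
.smooth_walk <- function(n, window = 10) {
  x <- cumsum(stats::rnorm(n))
  x <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  x[is.na(x)] <- 0
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate one subject's ROI time series under the block design
#'
#' The signal of region \eqn{i} at scan \eqn{t} is
#' \deqn{y_{it} = g\,(c_i^{R} x^{R}_t + c_i^{L} x^{L}_t) + \epsilon_{it}
#'   + d_{it} + m\,(M_t \lambda_i + w_i\,\mathrm{WM}_t + v_i\,\mathrm{CSF}_t)
#'   + \eta_{it}}
#' where \eqn{x^{L}, x^{R}} are the HRF-convolved condition regressors
#' (contralaterally weighted: contralateral coefficient 1, ipsilateral 0.4,
#' midline 0.7), \eqn{\epsilon} is Gaussian noise with the planted
#' correlation structure, \eqn{d} is low-frequency drift (< 0.008 Hz
#' sinusoid plus linear trend), \eqn{M} are six smoothed-random-walk motion
#' traces with random per-region loadings, WM/CSF are low-frequency nuisance
#' series, and \eqn{\eta} is white measurement noise. The confound table
#' contains exactly the motion, WM and CSF traces that were injected.
#'
#' @param nodes a \code{nodeset}.
#' @param model a \code{coupling_model}.
#' @param paradigm a \code{task_paradigm} with conditions "left"/"right".
#' @param seed integer seed; identical seeds give identical output.
#' @param subject_id identifier stored with the result.
#' @return An object of class \code{subject_ts}: list with \code{data}
#'   (region x scan matrix), \code{tr_s}, \code{confounds} (scan x 8
#'   data.frame), \code{subject_id}.
#' @export
simulate_subject <- function(nodes, model, paradigm = default_paradigm(),
                             seed = 1, subject_id = "sub-01") {
  stopifnot(inherits(nodes, "nodeset"), inherits(model, "coupling_model"),
            inherits(paradigm, "task_paradigm"))
  set.seed(as.integer(seed))
  n <- length(nodes$labels)
  ns <- n_scans(paradigm)
  tr <- paradigm$tr_s
  tt <- (seq_len(ns) - 1) * tr

  ## correlated noise
  C <- build_covariance(nodes, model)
  S <- .mat_sqrt(C)
  eps <- model$noise_sd * (S %*% matrix(stats::rnorm(n * ns), n, ns))

  ## task response, contralaterally weighted, peak-normalised regressors
  y <- eps
  if (model$task_gain > 0) {
    regs <- lapply(c(left = "left", right = "right"), function(cond) {
      r <- condition_regressor(paradigm, cond)$raw
      r / max(r)
    })
    c_contra <- 1; c_ipsi <- 0.4; c_mid <- 0.7
    for (i in seq_len(n)) {
      cf <- switch(nodes$hemisphere[i],
                   L = c(left = c_ipsi, right = c_contra),
                   R = c(left = c_contra, right = c_ipsi),
                   M = c(left = c_mid, right = c_mid))
      y[i, ] <- y[i, ] + model$noise_sd * model$task_gain *
        (cf["left"] * regs$left + cf["right"] * regs$right)
    }
  }

  ## low-frequency drift: sinusoid below 0.008 Hz plus linear trend
  if (model$drift_amp > 0) {
    for (i in seq_len(n)) {
      f <- stats::runif(1, 0.002, 0.005)
      ph <- stats::runif(1, 0, 2 * pi)
      sl <- stats::rnorm(1, 0, 0.5)
      y[i, ] <- y[i, ] + model$drift_amp *
        (sin(2 * pi * f * tt + ph) + sl * (tt - mean(tt)) / max(tt))
    }
  }

  ## motion (6 rigid-body parameters) and WM/CSF nuisance series
  motion <- vapply(1:6, function(k) .smooth_walk(ns), numeric(ns))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  wm <- .smooth_walk(ns, window = 20)
  csf <- .smooth_walk(ns, window = 20)
  if (model$motion_coupling > 0) {
    lambda <- matrix(stats::rnorm(n * 6, 0, 1 / sqrt(6)), n, 6)
    wv <- stats::rnorm(n, 0, 0.5); cv <- stats::rnorm(n, 0, 0.5)
    y <- y + model$motion_coupling *
      (lambda %*% t(motion) + outer(wv, wm) + outer(cv, csf))
  }

  ## white measurement noise
  if (model$measurement_sd > 0)
    y <- y + matrix(stats::rnorm(n * ns, 0, model$measurement_sd), n, ns)

  rownames(y) <- nodes$labels
  confounds <- data.frame(motion, wm = wm, csf = csf)
  structure(list(data = y, tr_s = tr, confounds = confounds,
                 subject_id = subject_id),
            class = "subject_ts")
}

#' Simulate a multi-subject study
#'
#' @param nodes,model,paradigm as in \code{\link{simulate_subject}}.
#' @param n_subjects number of subjects (default 18).
#' @param seed base seed; subject k uses seed + k.
#' @return list of \code{subject_ts}.
#' @export
simulate_study <- function(nodes, model, paradigm = default_paradigm(),
                           n_subjects = 18, seed = 1) {
  lapply(seq_len(n_subjects), function(k)
    simulate_subject(nodes, model, paradigm, seed = as.integer(seed) + k,
                     subject_id = sprintf("sub-%02d", k)))
}

#' Render ROI time series into a 4D NIfTI-style volume
#'
#' Paints each region's time course into all voxels whose centers lie within
#' \code{radius_mm} of the node center, adds i.i.d. background noise, and
#' attaches an affine mapping voxel indices to MNI mm. Spheres must fit
#' inside the grid and must not overlap.
#'
#' @param ts a \code{subject_ts}.
#' @param nodes the matching \code{nodeset}.
#' @param voxel_mm isotropic voxel size in mm.
#' @param radius_mm sphere radius in mm (default 3, matching ROI extraction).
#' @param margin_mm empty margin around the bounding box of all spheres.
#' @param background_sd standard deviation of background noise.
#' @return An \code{RNifti} image (4D array with xform), voxels in mm space.
#' @export
render_volumes <- function(ts, nodes, voxel_mm = 3, radius_mm = 3,
                           margin_mm = 6, background_sd = 0.1) {
  stopifnot(inherits(ts, "subject_ts"), inherits(nodes, "nodeset"))
  cen <- nodes$centers_mm
  dmat <- as.matrix(stats::dist(cen))
  diag(dmat) <- Inf
  if (min(dmat) <= 2 * radius_mm)
    stop("node spheres overlap at radius ", radius_mm, " mm", call. = FALSE)
  lo <- apply(cen, 2, min) - radius_mm - margin_mm
  hi <- apply(cen, 2, max) + radius_mm + margin_mm
  dim3 <- ceiling((hi - lo) / voxel_mm) + 1
  nt <- ncol(ts$data)
  img <- array(stats::rnorm(prod(dim3) * nt, 0, background_sd),
               dim = c(dim3, nt))
  ## voxel (i,j,k) 0-based -> mm: lo + voxel_mm * index
  for (r in seq_len(nrow(cen))) {
    v0 <- (cen[r, ] - lo) / voxel_mm           # node center, voxel units
    rng <- lapply(1:3, function(a)
      max(0, floor(v0[a] - radius_mm / voxel_mm)):
      min(dim3[a] - 1, ceiling(v0[a] + radius_mm / voxel_mm)))
    for (i in rng[[1]]) for (j in rng[[2]]) for (k in rng[[3]]) {
      if (sum(((c(i, j, k) - v0) * voxel_mm)^2) <= radius_mm^2)
        img[i + 1, j + 1, k + 1, ] <- img[i + 1, j + 1, k + 1, ] + ts$data[r, ]
    }
  }
  aff <- structure(rbind(cbind(diag(voxel_mm, 3), lo), c(0, 0, 0, 1)),
                   code = 2L)
  nii <- RNifti::asNifti(img)
  RNifti::sform(nii) <- aff
  nii
}
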