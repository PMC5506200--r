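#' Block-design task paradigm
#'
#' A paradigm is an ordered set of condition blocks over a fixed acquisition
#' window. Blocks within a condition must not overlap, and every block must
#' fit inside the total duration.
#'
#' @param blocks data.frame with columns \code{onset} (s), \code{duration}
#'   (s) and \code{condition} (character).
#' @param total_duration_s total acquisition length in seconds.
#' @param tr_s repetition time in seconds.
#' @param metadata optional named list carried along (e.g. nominal scanner
#'   run length when it differs from the segment sum).
#' @return An object of class \code{task_paradigm}.
#' @export
task_paradigm <- function(blocks, total_duration_s, tr_s, metadata = list()) {
  stopifnot(is.data.frame(blocks),
            all(c("onset", "duration", "condition") %in% names(blocks)))
  blocks$onset <- as.numeric(blocks$onset)
  blocks$duration <- as.numeric(blocks$duration)
  blocks$condition <- as.character(blocks$condition)
  if (tr_s <= 0) stop("tr_s must be positive", call. = FALSE)
  if (any(blocks$onset < 0)) stop("block onsets must be >= 0", call. = FALSE)
  if (any(blocks$onset + blocks$duration > total_duration_s + 1e-9))
    stop("blocks must end before total_duration_s", call. = FALSE)
  for (cond in unique(blocks$condition)) {
    b <- blocks[blocks$condition == cond, , drop = FALSE]
    b <- b[order(b$onset), , drop = FALSE]
    if (nrow(b) > 1 &&
        any(b$onset[-1] < (b$onset + b$duration)[-nrow(b)] - 1e-9))
      stop("overlapping blocks within condition '", cond, "'", call. = FALSE)
  }
  structure(list(blocks = blocks[order(blocks$onset), , drop = FALSE],
                 total_duration_s = total_duration_s,
                 tr_s = tr_s,
                 metadata = metadata),
            class = "task_paradigm")
}

#' Number of scans covered by a paradigm
#' @param paradigm a \code{task_paradigm}.
#' @return integer scan count, \code{floor(total_duration / tr)}.
#' @export
n_scans <- function(paradigm) {
  as.integer(floor(paradigm$total_duration_s / paradigm$tr_s + 1e-9))
}

#' Default alternating left/right foot-movement paradigm
#'
#' Ten 16 s movement blocks separated by 20 s rests, with a 26 s initial and
#' a 22 s final rest, TR = 2 s. Conditions alternate left/right starting with
#' left. The segment sum (388 s) defines the paradigm duration; the nominal
#' 396 s run length and the 4 s pre-scan lead-in are retained as metadata
#' only, since per-cycle accounting of the longer figure is ambiguous.
#'
#' @param tr_s repetition time in seconds (default 2).
#' @param first_condition condition of the first task block, \code{"left"} or
#'   \code{"right"}; the study counterbalanced this across subjects.
#' @return A \code{task_paradigm} with conditions \code{"left"} and
#'   \code{"right"}.
#' @export
default_paradigm <- function(tr_s = 2, first_condition = c("left", "right")) {
  first_condition <- match.arg(first_condition)
  task_s <- 16; rest_s <- 20; initial_rest_s <- 26; final_rest_s <- 22
  n_blocks <- 10
  onsets <- initial_rest_s + (seq_len(n_blocks) - 1) * (task_s + rest_s)
  conds <- rep(c("left", "right"), length.out = n_blocks)
  if (first_condition == "right") conds <- rev(conds)[seq_len(n_blocks)]
  total <- initial_rest_s + n_blocks * task_s + (n_blocks - 1) * rest_s +
    final_rest_s
  task_paradigm(
    data.frame(onset = onsets, duration = task_s, condition = conds,
               stringsAsFactors = FALSE),
    total_duration_s = total, tr_s = tr_s,
    metadata = list(nominal_run_s = 396, lead_in_s = 4))
}

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-convention double gamma: response gamma with shape 6, undershoot gamma
#' with shape 16 (both rate 1 per second), undershoot ratio 1/6, 32 s
#' support, peak amplitude normalised to 1.
#'
#' @param dt_s sampling step in seconds (0 < dt_s <= 4).
#' @return An object of class \code{hrf_kernel} with fields \code{samples}
#'   and \code{dt_s}.
#' @export
canonical_hrf <- function(dt_s) {
  if (!is.numeric(dt_s) || length(dt_s) != 1 || !is.finite(dt_s) ||
      dt_s <= 0 || dt_s > 4)
    stop("dt_s must be a single value in (0, 4]", call. = FALSE)
  t <- seq(0, 32, by = dt_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  structure(list(samples = h, dt_s = dt_s), class = "hrf_kernel")
}

#' HRF-convolved condition regressor sampled at the TR
#'
#' Builds the condition's boxcar (1 during its blocks) on the HRF's time
#' grid, convolves with the kernel, scales by \code{dt}, and samples at scan
#' onsets. The raw regressor (including the negative undershoot) is returned
#' alongside a non-negative copy with undershoot values clipped to zero,
#' which is the version used as per-scan weights in condition-specific
#' correlation.
#'
#' @param paradigm a \code{task_paradigm}.
#' @param condition condition identifier present in the paradigm.
#' @param hrf an \code{hrf_kernel}; its \code{dt_s} must equal the paradigm
#'   TR or an integer subdivision of it.
#' @return list with \code{raw}, \code{weights} (clipped at 0), both of
#'   length \code{n_scans(paradigm)}, and \code{boxcar} (per-scan 0/1).
#' @export
condition_regressor <- function(paradigm, condition, hrf = canonical_hrf(paradigm$tr_s)) {
  stopifnot(inherits(paradigm, "task_paradigm"), inherits(hrf, "hrf_kernel"))
  if (!condition %in% paradigm$blocks$condition)
    stop("condition '", condition, "' not found in paradigm", call. = FALSE)
  ratio <- paradigm$tr_s / hrf$dt_s
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1 - 1e-9)
    stop("hrf dt_s must be the TR or an integer subdivision of it",
         call. = FALSE)
  ratio <- as.integer(round(ratio))
  ns <- n_scans(paradigm)
  n_fine <- ns * ratio
  t_fine <- (seq_len(n_fine) - 1) * hrf$dt_s
  box <- rep(0, n_fine)
  b <- paradigm$blocks[paradigm$blocks$condition == condition, , drop = FALSE]
  for (k in seq_len(nrow(b)))
    box[t_fine >= b$onset[k] - 1e-9 & t_fine < b$onset[k] + b$duration[k] - 1e-9] <- 1
  conv <- stats::convolve(box, rev(hrf$samples), type = "open")[seq_len(n_fine)] *
    hrf$dt_s
  idx <- seq(1, n_fine, by = ratio)
  raw <- conv[idx]
  list(raw = raw, weights = pmax(raw, 0), boxcar = box[idx])
}

#' Read a paradigm from a TSV event file
#'
#' @param path TSV with columns onset, duration, condition.
#' @param tr_s repetition time in seconds.
#' @param total_duration_s total run length; defaults to the end of the last
#'   block.
#' @return A \code{task_paradigm}.
#' @export
read_paradigm <- function(path, tr_s, total_duration_s = NULL) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(total_duration_s))
    total_duration_s <- max(ev$onset + ev$duration)
  task_paradigm(ev, total_duration_s = total_duration_s, tr_s = tr_s)
}

#' Write a paradigm's event table as TSV
#' @param paradigm a \code{task_paradigm}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_paradigm <- function(paradigm, path) {
  utils::write.table(paradigm$blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
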