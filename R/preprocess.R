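#' Zero-phase temporal band-pass filter
#'
#' Applies a second-order Butterworth band-pass (default 0.01--0.1 Hz, the
#' conventional resting-state band) forward and backward
#' ([signal::filtfilt()]), so no phase lag is introduced -- essential when
#' the filtered series feed instantaneous-phase estimation downstream.
#'
#' @param series Numeric vector, or a matrix filtered column-wise.
#' @param tr_seconds Sampling interval in seconds.
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must be below the Nyquist
#'   frequency `1/(2*tr_seconds)`.
#' @param order Butterworth order (default 2).
#' @return Filtered series with the same shape as the input.
#' @export
bandpass <- function(series, tr_seconds, f_lo = 0.01, f_hi = 0.1, order = 2L) {
  stopifnot_scalar(tr_seconds, "tr_seconds", positive = TRUE)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(f_lo > 0 && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi >= nyquist)
    stop(sprintf("f_hi (%g Hz) must be below Nyquist (%g Hz)", f_hi, nyquist),
         call. = FALSE)
  flt <- signal::butter(order, c(f_lo, f_hi) / nyquist, type = "pass")
  min_len <- 3L * (length(flt$b) - 1L) + 1L
  apply_one <- function(x) {
    if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
    if (length(x) < min_len)
      stop(sprintf("series too short to filter (need >= %d samples)", min_len),
           call. = FALSE)
    signal::filtfilt(flt, x)
  }
  if (is.matrix(series)) {
    out <- apply(series, 2L, apply_one)
    dimnames(out) <- dimnames(series)
    attr(out, "tr_seconds") <- attr(series, "tr_seconds")
    out
  } else {
    apply_one(as.numeric(series))
  }
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Computes the per-frame scalar head-motion summary
#' \deqn{FD(t) = \sum_k |\Delta d_k(t)| + r \sum_k |\Delta \theta_k(t)|,}
#' the sum of absolute frame-to-frame changes in the three translations (mm)
#' plus the three rotations converted to arc length on a sphere of radius
#' `head_radius_mm`. The first frame has FD = 0 by definition.
#'
#' @param motion Frames x 6 numeric matrix: translations (mm) in columns
#'   1--3, rotations in columns 4--6.
#' @param head_radius_mm Sphere radius used to convert rotations to mm
#'   (default 50, the common convention).
#' @param rotations_in_degrees Set `TRUE` when the rotation columns are in
#'   degrees rather than radians.
#' @return An object of class `fd_series`: list with `fd` (per-frame FD,
#'   mm), `mean_fd` and `head_radius_mm`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50,
                                   rotations_in_degrees = FALSE) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion must have 6 columns (3 translations + 3 rotations)",
         call. = FALSE)
  if (nrow(motion) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (!all(is.finite(motion)))
    stop("motion parameters contain non-finite values", call. = FALSE)
  rot <- motion[, 4:6, drop = FALSE]
  if (rotations_in_degrees) rot <- rot * pi / 180
  d_trans <- abs(diff(motion[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot))
  fd <- c(0, rowSums(d_trans) + head_radius_mm * rowSums(d_rot))
  structure(list(fd = fd, mean_fd = mean(fd),
                 head_radius_mm = head_radius_mm),
            class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("fd_series: %d frames, mean FD %.4f mm (max %.4f mm)\n",
              length(x$fd), x$mean_fd, max(x$fd)))
  invisible(x)
}

#' Exclude high-motion subjects
#'
#' Partitions subject records by mean framewise displacement. A subject is
#' excluded when `mean_fd` strictly exceeds the threshold (so a subject at
#' exactly the threshold is retained), mirroring the usual "discard subjects
#' with mean FD larger than 0.5 mm" QC rule.
#'
#' @param records Data frame with at least `mean_fd` (and ideally
#'   `subject_id`).
#' @param threshold_mm Exclusion threshold in mm (default 0.5).
#' @return List with data frames `retained` and `excluded`.
#' @export
exclude_high_motion <- function(records, threshold_mm = 0.5) {
  records <- as.data.frame(records)
  if (!"mean_fd" %in% names(records))
    stop("records must contain a `mean_fd` column", call. = FALSE)
  ids <- if ("subject_id" %in% names(records)) records$subject_id
         else as.character(seq_len(nrow(records)))
  bad <- !is.finite(records$mean_fd)
  if (any(bad))
    stop(sprintf("missing or non-finite mean_fd for subject(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  keep <- records$mean_fd <= threshold_mm
  list(retained = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE])
}
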