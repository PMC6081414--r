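#' Instantaneous phase via the discrete analytic signal
#'
#' Forms the analytic signal (original series plus i times its Hilbert
#' transform) by the standard FFT construction — doubling positive
#' frequencies, zeroing negative ones — and returns its argument, the
#' instantaneous phase, wrapped to (-pi, pi].
#'
#' @param series Numeric vector, length >= 8, not constant.
#' @return Numeric vector of per-frame phases in radians.
#' @export
analytic_phase <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 8L) stop("series too short for phase estimation (need >= 8 samples)",
                   call. = FALSE)
  if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  if (sd(x) == 0)
    stop("constant series: instantaneous phase undefined", call. = FALSE)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  analytic <- fft(fft(x) * h, inverse = TRUE) / n
  Arg(analytic)
}

#' Wrap phase values to (-pi, pi]
#'
#' Maps any finite angle to its principal value under the half-open
#' convention (-pi, pi], so -pi wraps to +pi.
#'
#' @param delta Numeric vector of angles in radians.
#' @return Wrapped angles in (-pi, pi].
#' @export
wrap_phase <- function(delta) {
  if (!all(is.finite(delta)))
    stop("phase values must be finite", call. = FALSE)
  delta - 2 * pi * ceiling((delta - pi) / (2 * pi))
}

# Number of frames trimmed from each end before a phase statistic is
# computed; the discrete analytic signal is unreliable near the series
# boundaries.
trim_count <- function(n, trim) {
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)", call. = FALSE)
  ceiling(trim * n)
}

#' Variance of a wrapped phase-difference series
#'
#' The estimator at the heart of the inter-ICN variability metric: wrap the
#' phase differences to (-pi, pi], drop a fraction of frames at each end
#' (edge effects of the analytic signal), and take the ordinary sample
#' variance. For i.i.d. uniform phase differences the population value is
#' \eqn{(2\pi)^2/12 = \pi^2/3}.
#'
#' The circular alternative `1 - R` (one minus the resultant length) is
#' available for data whose mean difference sits near the +/-pi wrapping
#' boundary, where the ordinary variance is inflated by wrap-around jumps.
#'
#' @param dphi Numeric vector of phase differences in radians (any range;
#'   wrapped internally).
#' @param trim Fraction of frames trimmed from each end (default 0.05).
#' @param denominator `"n-1"` (sample variance, default) or `"n"`.
#' @param estimator `"variance"` (default) or `"circular"` (1 - resultant
#'   length, in [0, 1]).
#' @return Nonnegative scalar.
#' @export
phase_difference_variance <- function(dphi, trim = 0.05,
                                      denominator = c("n-1", "n"),
                                      estimator = c("variance", "circular")) {
  denominator <- match.arg(denominator)
  estimator <- match.arg(estimator)
  w <- wrap_phase(dphi)
  k <- trim_count(length(w), trim)
  if (length(w) - 2L * k < 2L)
    stop("too few frames left after edge trimming", call. = FALSE)
  if (k > 0L) w <- w[(k + 1L):(length(w) - k)]
  if (estimator == "circular")
    return(1 - Mod(mean(exp(1i * w))))
  v <- sum((w - mean(w))^2)
  v / (if (denominator == "n-1") length(w) - 1L else length(w))
}

#' Inter-network variability: variance of the instantaneous phase difference
#'
#' The dynamic-connectivity statistic: (1) take the two time-courses,
#' (2--3) obtain each one's instantaneous phase from the analytic signal,
#' (4) form the per-frame phase difference, (5) wrap it to (-pi, pi], and
#' (6) return its sample variance. Identical inputs give 0; a constant
#' phase offset gives ~0 (up to edge effects); fully desynchronised phases
#' approach the uniform limit pi^2/3. The statistic is symmetric in its
#' arguments and invariant to positive rescaling of either input.
#'
#' @param x,y Equal-length numeric time-courses.
#' @param trim,denominator,estimator Passed to
#'   [phase_difference_variance()].
#' @return Nonnegative scalar.
#' @export
inter_icn_variability <- function(x, y, trim = 0.05,
                                  denominator = c("n-1", "n"),
                                  estimator = c("variance", "circular")) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  dphi <- analytic_phase(x) - analytic_phase(y)
  phase_difference_variance(dphi, trim = trim,
                            denominator = match.arg(denominator),
                            estimator = match.arg(estimator))
}

#' Functional connectivity (Pearson correlation)
#'
#' The conventional static connectivity measure between two time-courses.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return Correlation in [-1, 1].
#' @export
functional_connectivity <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 frames", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("series contain non-finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant series: correlation undefined", call. = FALSE)
  cor(x, y)
}

#' Phase synchrony (phase-locking value)
#'
#' The standard instantaneous-phase synchrony estimator: the modulus of the
#' time-averaged unit phasor of the phase difference,
#' \eqn{PLV = |T^{-1} \sum_t e^{i\Delta\phi(t)}|}. Equals 1 for identical
#' series or any constant phase offset and decays towards 0 (at rate
#' ~ T^{-1/2}) for independent phases.
#'
#' @param x,y Equal-length numeric time-courses.
#' @param trim Fraction of frames trimmed from each end (default 0.05).
#' @return Value in [0, 1].
#' @export
phase_synchrony <- function(x, y, trim = 0.05) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  dphi <- analytic_phase(x) - analytic_phase(y)
  k <- trim_count(length(dphi), trim)
  if (length(dphi) - 2L * k < 2L)
    stop("too few frames left after edge trimming", call. = FALSE)
  if (k > 0L) dphi <- dphi[(k + 1L):(length(dphi) - k)]
  Mod(mean(exp(1i * dphi)))
}

#' Pairwise metric vector over all component pairs
#'
#' Computes one metric value per unordered component pair in canonical
#' row-major upper-triangle order ((1,2), (1,3), ..., (N-1,N)), the order
#' that fixes feature identity for weight reporting. Ten components yield
#' 10 x 9 / 2 = 45 features.
#'
#' @param tc Frames x components matrix (column names label the
#'   components).
#' @param metric `"VAR"` (inter-network variability, default), `"FC"`
#'   (Pearson correlation) or `"PS"` (phase-locking value).
#' @param ... Passed to the underlying metric (e.g. `trim`).
#' @return Named numeric vector of length `N(N-1)/2`; names are
#'   `"<label_i>-<label_j>"`.
#' @export
pairwise_features <- function(tc, metric = c("VAR", "FC", "PS"), ...) {
  metric <- match.arg(metric)
  tc <- as.matrix(tc)
  n <- ncol(tc)
  if (n < 2L) stop("need at least 2 components", call. = FALSE)
  labels <- colnames(tc) %||% default_icn_labels(n)
  idx <- pair_index(n)
  fun <- switch(metric,
                VAR = function(a, b) inter_icn_variability(a, b, ...),
                FC = function(a, b) functional_connectivity(a, b),
                PS = function(a, b) phase_synchrony(a, b, ...))
  vals <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, "i"]; j <- idx[r, "j"]
    tryCatch(fun(tc[, i], tc[, j]),
             error = function(e)
               stop(sprintf("pair (%s, %s): %s", labels[i], labels[j],
                            conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  names(vals) <- paste(labels[idx[, "i"]], labels[idx[, "j"]], sep = "-")
  vals
}

#' Assemble the predictor vector for the diagnostic model
#'
#' Concatenates the pairwise metric values with the subject covariates in
#' the diagnostic-model term order: the 45 pairwise values, then verbal,
#' performance and full IQ, then sex (male = 1, female = 0), age, and mean
#' framewise displacement — 51 predictors for a 10-component metric vector.
#' Ablation flags drop the IQ block, age, or the motion covariate to
#' reproduce reduced model variants.
#'
#' @param pairs Named numeric vector from [pairwise_features()].
#' @param record One-row data frame (or list) with `viq`, `piq`, `fiq`,
#'   `sex`, `age`, `mean_fd`.
#' @param include_iq,include_age,include_motion Ablation switches.
#' @return Named numeric predictor vector.
#' @export
assemble_feature_vector <- function(pairs, record,
                                    include_iq = TRUE,
                                    include_age = TRUE,
                                    include_motion = TRUE) {
  needed <- c(if (include_iq) c("viq", "piq", "fiq"),
              "sex",
              if (include_age) "age",
              if (include_motion) "mean_fd")
  record <- as.list(record)
  for (f in needed) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(as.numeric(v)))
      stop(sprintf("missing or non-finite covariate `%s`", f), call. = FALSE)
  }
  cov_vals <- vapply(needed, function(f) as.numeric(record[[f]]), numeric(1))
  c(pairs, cov_vals)
}

#' Feature matrix and labels for a whole cohort
#'
#' Runs the per-subject feature pipeline over a simulated (or assembled)
#' cohort: optionally band-pass each component time-course (default on,
#' 0.01--0.1 Hz), compute the pairwise metric vector, and append the
#' covariates. Labels are 1 for patients and 0 for controls.
#'
#' @param cohort An `icn_cohort` (see [simulate_cohort()]), or any list
#'   with `phenotypes` and `timecourses` of matching length.
#' @param metric `"VAR"`, `"FC"` or `"PS"`.
#' @param filter_band Band-pass the time-courses before the metric
#'   (default `TRUE`).
#' @param include_iq,include_age,include_motion Ablation switches passed to
#'   [assemble_feature_vector()].
#' @param ... Passed to [pairwise_features()].
#' @return List with `X` (subjects x predictors matrix), `y` (integer 0/1
#'   labels, 1 = patient) and `subject_id`.
#' @export
cohort_features <- function(cohort, metric = c("VAR", "FC", "PS"),
                            filter_band = TRUE,
                            include_iq = TRUE, include_age = TRUE,
                            include_motion = TRUE, ...) {
  metric <- match.arg(metric)
  phen <- cohort$phenotypes
  tcs <- cohort$timecourses
  if (nrow(phen) != length(tcs))
    stop("phenotype rows and time-course list differ in length", call. = FALSE)
  rows <- lapply(seq_len(nrow(phen)), function(s) {
    tc <- tcs[[s]]
    if (filter_band) {
      tr <- attr(tc, "tr_seconds") %||% cohort$config$tr_seconds
      if (is.null(tr)) stop("tr_seconds unknown; cannot band-pass", call. = FALSE)
      tc <- bandpass(tc, tr)
    }
    assemble_feature_vector(pairwise_features(tc, metric, ...),
                            phen[s, , drop = FALSE],
                            include_iq = include_iq,
                            include_age = include_age,
                            include_motion = include_motion)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- phen$subject_id
  list(X = X,
       y = as.integer(phen$group == "patient"),
       subject_id = phen$subject_id)
}
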