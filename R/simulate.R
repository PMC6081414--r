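#' Simulation configuration for a two-group synthetic cohort
#'
#' Builds the configuration object used by all cohort generators. Each
#' component time-course is a noisy oscillator
#' \deqn{x_i(t) = \cos(2\pi f\, t\, TR + \epsilon_i(t)) + \eta(t),}
#' where the per-frame phase jitter \eqn{\epsilon_i(t)} is i.i.d.
#' wrapped-normal with component- and group-specific circular SD
#' \eqn{\sigma_i}, and \eqn{\eta} is additive Gaussian observation noise.
#' In the small-dispersion regime the variance of the wrapped phase
#' difference of a pair \eqn{(i, j)} is governed by
#' \eqn{\sigma_i^2 + \sigma_j^2}, so raising \eqn{\sigma} on a subset of
#' components in one group plants a group difference in the downstream
#' inter-ICN variability of every pair drawn from that subset.
#'
#' By default three pairs among components 1--3 carry the effect: those
#' components have \eqn{\sigma} = `effect_sigma["patient"]` (0.3 rad) in
#' patients and `effect_sigma["control"]` (0.05 rad) in controls, while all
#' remaining components sit at `base_sigma` in both groups. Explicit
#' per-component dispersions can be supplied through `phase_dispersion`.
#'
#' @param n_patients,n_controls Group sizes (default 60 each).
#' @param n_timepoints Frames per subject; default 235 (a 240-volume
#'   acquisition minus 5 discarded initial volumes).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param n_components Number of network components (default 10).
#' @param carrier_freq_hz Shared oscillation frequency in Hz; must lie
#'   strictly inside (0, Nyquist) and defaults to 0.05, the centre of the
#'   0.01--0.1 Hz resting-state band.
#' @param base_sigma Baseline circular SD (radians) of the per-frame phase
#'   jitter for components not carrying the effect (default 0.35, a
#'   moderately desynchronised regime typical of distinct resting-state
#'   networks; it also keeps the planted contrast confined to the
#'   designated pairs in standardised units, since the sampling noise of a
#'   variance estimate scales with its level).
#' @param effect_sigma Named length-2 vector `c(patient=, control=)` of
#'   circular SDs applied to effect components per group.
#' @param effect_pairs List of length-2 integer vectors: the component pairs
#'   that carry the planted group effect.
#' @param obs_noise_sd SD of the additive observation noise (default 0.1).
#' @param null_effect If `TRUE`, both groups use identical generator
#'   parameters (dispersion and phenotypes), producing a null cohort for
#'   calibration checks.
#' @param phase_dispersion Optional list with elements `patient` and
#'   `control`, each a length-`n_components` vector of circular SDs;
#'   overrides `base_sigma`/`effect_sigma`.
#' @param seed Default seed used by generators when no explicit seed is
#'   passed.
#'
#' @return An object of class `sim_config`.
#' @export
make_sim_config <- function(n_patients = 60L,
                            n_controls = 60L,
                            n_timepoints = 235L,
                            tr_seconds = 2,
                            n_components = 10L,
                            carrier_freq_hz = 0.05,
                            base_sigma = 0.35,
                            effect_sigma = c(patient = 0.3, control = 0.05),
                            effect_pairs = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
                            obs_noise_sd = 0.1,
                            null_effect = FALSE,
                            phase_dispersion = NULL,
                            seed = NULL) {
  stopifnot_scalar(tr_seconds, "tr_seconds", positive = TRUE)
  stopifnot_scalar(carrier_freq_hz, "carrier_freq_hz")
  if (n_patients < 1L || n_controls < 1L)
    stop("both groups need at least one subject", call. = FALSE)
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2", call. = FALSE)
  if (n_components < 2L) stop("n_components must be >= 2", call. = FALSE)
  nyquist <- 1 / (2 * tr_seconds)
  if (carrier_freq_hz <= 0 || carrier_freq_hz >= nyquist)
    stop(sprintf("carrier_freq_hz must lie in (0, Nyquist = %g Hz)", nyquist),
         call. = FALSE)
  if (obs_noise_sd < 0) stop("obs_noise_sd must be >= 0", call. = FALSE)

  for (p in effect_pairs) {
    if (length(p) != 2L || anyNA(p) || any(p < 1L) || any(p > n_components) ||
        p[1] == p[2])
      stop("effect_pairs must be valid unordered pairs of distinct component indices",
           call. = FALSE)
  }
  effect_components <- sort(unique(unlist(effect_pairs)))

  if (is.null(phase_dispersion)) {
    sig_pat <- rep(base_sigma, n_components)
    sig_con <- rep(base_sigma, n_components)
    sig_pat[effect_components] <- effect_sigma[["patient"]]
    sig_con[effect_components] <- effect_sigma[["control"]]
    phase_dispersion <- list(patient = sig_pat, control = sig_con)
  } else {
    if (!all(c("patient", "control") %in% names(phase_dispersion)))
      stop("phase_dispersion needs elements 'patient' and 'control'", call. = FALSE)
    phase_dispersion <- phase_dispersion[c("patient", "control")]
    if (any(lengths(phase_dispersion) != n_components))
      stop("phase_dispersion vectors must have length n_components", call. = FALSE)
  }
  if (any(unlist(phase_dispersion) < 0))
    stop("phase dispersions must be >= 0", call. = FALSE)
  if (null_effect) phase_dispersion$patient <- phase_dispersion$control

  structure(list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    n_components = as.integer(n_components),
    carrier_freq_hz = carrier_freq_hz,
    phase_dispersion = phase_dispersion,
    effect_pairs = lapply(effect_pairs, as.integer),
    obs_noise_sd = obs_noise_sd,
    null_effect = isTRUE(null_effect),
    seed = seed
  ), class = "sim_config")
}

# Un-seeded core used by simulate_timecourses() and simulate_cohort().
timecourse_matrix <- function(config, group) {
  tt <- seq_len(config$n_timepoints) - 1L
  base_phase <- 2 * pi * config$carrier_freq_hz * tt * config$tr_seconds
  sigma <- config$phase_dispersion[[group]]
  x <- vapply(seq_len(config$n_components), function(i) {
    eps <- if (sigma[i] > 0) rnorm(config$n_timepoints, 0, sigma[i]) else 0
    cos(base_phase + eps)
  }, numeric(config$n_timepoints))
  if (config$obs_noise_sd > 0)
    x <- x + matrix(rnorm(length(x), 0, config$obs_noise_sd), nrow(x), ncol(x))
  colnames(x) <- default_icn_labels(config$n_components)
  attr(x, "tr_seconds") <- config$tr_seconds
  x
}

#' Simulate network time-courses for one subject
#'
#' Draws a `n_timepoints` x `n_components` matrix of oscillator signals with
#' group-specific per-frame phase jitter (see [make_sim_config()] for the
#' generative model). With all dispersions and the observation noise at zero
#' every component is the identical cosine, so all pairwise phase differences
#' are exactly constant.
#'
#' @param config A `sim_config`.
#' @param group `"patient"` or `"control"`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A numeric matrix (frames x components) with attribute
#'   `tr_seconds`; columns carry component labels.
#' @export
simulate_timecourses <- function(config, group = c("patient", "control"),
                                 seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group)
  with_seed(seed, timecourse_matrix(config, group))
}

#' Simulate compact spatial template maps
#'
#' Places `n_components` spherical Gaussian blobs (unit peak) at well
#' separated lattice positions in a 3D grid, emulating a set of network
#' template maps. The brain mask is the full grid box: the synthetic
#' "brain" fills the volume and the blobs are compact structures within
#' it (a large mask also keeps the mean template value small, which is
#' what limits cross-talk between per-map simple regressions). Centres are
#' deterministic given the grid; `jitter_sd > 0` adds seeded random
#' jitter.
#'
#' @param grid_shape Integer length-3 grid extents (default `c(16,16,16)`).
#' @param n_components Number of maps (default 10).
#' @param blob_sd Gaussian SD of each blob in voxels (default 0.8).
#' @param min_separation Minimum centre-to-centre distance in voxels
#'   (default `4 * blob_sd`, which keeps blobs effectively disjoint).
#' @param jitter_sd SD of random centre jitter in voxels (default 0).
#' @param seed Seed for the jitter.
#' @return An object of class `template_set`: list with `maps` (voxels x
#'   components matrix), `grid_shape`, `mask` (logical 3D array), `labels`
#'   and `centers`.
#' @export
simulate_templates <- function(grid_shape = c(16L, 16L, 16L),
                               n_components = 10L,
                               blob_sd = 0.8,
                               min_separation = 4 * blob_sd,
                               jitter_sd = 0,
                               seed = NULL) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  grid_shape <- as.integer(grid_shape)
  centers <- place_centers(grid_shape, n_components, blob_sd, min_separation)
  with_seed(seed, {
    if (jitter_sd > 0)
      centers <- centers + matrix(rnorm(length(centers), 0, jitter_sd),
                                  nrow(centers), 3L)
    coords <- as.matrix(expand.grid(seq_len(grid_shape[1]),
                                    seq_len(grid_shape[2]),
                                    seq_len(grid_shape[3])))
    maps <- vapply(seq_len(n_components), function(i) {
      d2 <- rowSums(sweep(coords, 2L, centers[i, ])^2)
      exp(-d2 / (2 * blob_sd^2))
    }, numeric(nrow(coords)))
    labels <- default_icn_labels(n_components)
    colnames(maps) <- labels
    structure(list(
      maps = maps,
      grid_shape = grid_shape,
      mask = array(TRUE, dim = grid_shape),
      labels = labels,
      centers = centers
    ), class = "template_set")
  })
}

# Deterministic lattice placement of blob centres with a margin keeping the
# blob support inside the grid. Errors when the grid cannot host n blobs at
# the requested separation.
place_centers <- function(grid_shape, n, blob_sd, min_separation) {
  margin <- 2.5 * blob_sd + 1
  # usable positions run from margin+1 to grid-margin
  span <- grid_shape - 2 * margin - 1
  if (any(span <= 0))
    stop("grid too small for the requested blob size", call. = FALSE)
  max_per_dim <- pmax(1L, floor(span / min_separation) + 1L)
  best <- NULL
  for (k1 in seq_len(max_per_dim[1])) for (k2 in seq_len(max_per_dim[2]))
    for (k3 in seq_len(max_per_dim[3])) {
      if (k1 * k2 * k3 >= n) {
        cand <- c(k1, k2, k3)
        if (is.null(best) || prod(cand) < prod(best)) best <- cand
      }
    }
  if (is.null(best))
    stop(sprintf("cannot place %d components in a %s grid at separation %.1f",
                 n, paste(grid_shape, collapse = "x"), min_separation),
         call. = FALSE)
  axis_pos <- lapply(1:3, function(d) {
    if (best[d] == 1L) (grid_shape[d] + 1) / 2
    else seq(margin + 1, grid_shape[d] - margin, length.out = best[d])
  })
  grid <- as.matrix(expand.grid(axis_pos[[1]], axis_pos[[2]], axis_pos[[3]]))
  # snap to the voxel lattice so each map attains its unit peak exactly
  round(unname(grid[seq_len(n), , drop = FALSE]))
}

#' Mix templates and time-courses into a synthetic 4D volume
#'
#' Each frame is the sum of the template maps weighted by that frame's
#' component activities, plus i.i.d. voxelwise Gaussian noise:
#' `volume[,,,t] = sum_i map_i * x_i(t) + N(0, noise_sd^2)`.
#'
#' @param templates A `template_set`.
#' @param timecourses Frames x components matrix; column count must equal the
#'   number of template maps.
#' @param noise_sd Voxelwise noise SD (default 0).
#' @param seed Seed for the noise.
#' @return A 4D array `(x, y, z, t)` with attribute `tr_seconds` copied from
#'   the time-courses when present.
#' @export
simulate_bold <- function(templates, timecourses, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(templates, "template_set"))
  timecourses <- as.matrix(timecourses)
  if (ncol(timecourses) != ncol(templates$maps))
    stop(sprintf("component mismatch: %d time-courses vs %d templates",
                 ncol(timecourses), ncol(templates$maps)), call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    vox <- templates$maps %*% t(timecourses)  # voxels x T
    if (noise_sd > 0)
      vox <- vox + matrix(rnorm(length(vox), 0, noise_sd), nrow(vox), ncol(vox))
    out <- array(vox, dim = c(templates$grid_shape, ncol(vox)))
    attr(out, "tr_seconds") <- attr(timecourses, "tr_seconds")
    out
  })
}

# Moments of a normal left-truncated at `a`, and the parent parameters whose
# truncated distribution matches target moments. Truncation models the
# cohort's IQ > 80 inclusion criterion while preserving the published group
# means/SDs of the retained sample.
truncated_normal_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 - lambda * (lambda - alpha))
  c(mean = m, sd = sqrt(v))
}

truncated_normal_parent <- function(target_mean, target_sd, a) {
  obj <- function(par) {
    mm <- truncated_normal_moments(par[1], exp(par[2]), a)
    (mm["mean"] - target_mean)^2 + (mm["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm_left <- function(n, mu, sigma, a) {
  out <- rnorm(n, mu, sigma)
  bad <- which(out <= a)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] <= a]
  }
  out
}

# Group-level phenotype parameters: moments of the retained cohort.
phenotype_params <- function() {
  list(
    patient = list(male_fraction = 88 / 100,
                   age = c(12.1, 2.05),
                   viq = c(111.44, 15.57),
                   piq = c(99.03, 13.65),
                   fiq = c(106.36, 13.02),
                   fd_meanlog = log(0.18), fd_sdlog = 0.45),
    control = list(male_fraction = 81 / 140,
                   age = c(11.44, 1.86),
                   viq = c(120.46, 13.3),
                   piq = c(111.29, 14.33),
                   fiq = c(118.02, 12.12),
                   fd_meanlog = log(0.14), fd_sdlog = 0.45)
  )
}

phenotype_draw <- function(n, group, params, iq_floor = 80) {
  p <- params[[group]]
  draw_iq <- function(moments) {
    parent <- truncated_normal_parent(moments[1], moments[2], iq_floor)
    rtruncnorm_left(n, parent["mu"], parent["sigma"], iq_floor)
  }
  data.frame(
    subject_id = sprintf("%s%03d", if (group == "patient") "P" else "C",
                         seq_len(n)),
    group = group,
    sex = rbinom(n, 1L, p$male_fraction),   # 1 = male, 0 = female
    age = rnorm(n, p$age[1], p$age[2]),
    viq = draw_iq(p$viq),
    piq = draw_iq(p$piq),
    fiq = draw_iq(p$fiq),
    mean_fd = rlnorm(n, p$fd_meanlog, p$fd_sdlog),
    stringsAsFactors = FALSE
  )
}

#' Simulate subject phenotypes for both groups
#'
#' Draws demographics and covariates per subject: sex (Bernoulli with
#' group-specific male fraction), age (Gaussian), the three IQ scores
#' (normal left-truncated at 80, emulating an IQ > 80 inclusion criterion;
#' the truncated distribution's mean/SD match the group moments), and mean
#' framewise displacement (log-normal, shifted upwards in patients).
#' With `config$null_effect` the control parameters are used for both
#' groups.
#'
#' @param config A `sim_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return A data frame with columns `subject_id`, `group`, `sex`, `age`,
#'   `viq`, `piq`, `fiq`, `mean_fd`.
#' @export
simulate_phenotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  params <- phenotype_params()
  if (config$null_effect) params$patient <- params$control
  with_seed(seed, {
    rbind(phenotype_draw(config$n_patients, "patient", params),
          phenotype_draw(config$n_controls, "control", params))
  })
}

#' Simulate a rigid-body motion trace
#'
#' Generates a 6-parameter motion trace (3 translations in mm, 3 rotations
#' in radians) as independent Gaussian random walks, with optional
#' translation steps of known size: at each frame in `spike_frames` the
#' x-translation shifts by `spike_mm` and stays shifted, so the framewise
#' displacement at exactly that frame is `spike_mm` (plus random-walk
#' contribution).
#'
#' @param n_timepoints Number of frames.
#' @param step_sd Per-frame random-walk step SD for the translations in mm
#'   (rotations use `step_sd / 50` rad so both contribute comparably to FD
#'   under a 50 mm head radius). `0` gives a constant trace.
#' @param spike_frames Integer frames at which a translation step occurs.
#' @param spike_mm Step size in mm.
#' @param seed Seed.
#' @return A `n_timepoints` x 6 matrix with columns `trans_x`, `trans_y`,
#'   `trans_z`, `rot_x`, `rot_y`, `rot_z`.
#' @export
simulate_motion <- function(n_timepoints, step_sd = 0.02,
                            spike_frames = integer(0), spike_mm = 0,
                            seed = NULL) {
  if (n_timepoints < 2L) stop("need at least 2 frames", call. = FALSE)
  if (length(spike_frames) > 0 &&
      (any(spike_frames < 1L) || any(spike_frames > n_timepoints)))
    stop("spike_frames out of range", call. = FALSE)
  with_seed(seed, {
    walk <- function(sd) {
      if (sd == 0) rep(0, n_timepoints) else cumsum(rnorm(n_timepoints, 0, sd))
    }
    m <- cbind(trans_x = walk(step_sd), trans_y = walk(step_sd),
               trans_z = walk(step_sd),
               rot_x = walk(step_sd / 50), rot_y = walk(step_sd / 50),
               rot_z = walk(step_sd / 50))
    for (f in spike_frames) m[f:n_timepoints, "trans_x"] <-
      m[f:n_timepoints, "trans_x"] + spike_mm
    m
  })
}

#' Simulate a complete two-group cohort
#'
#' Draws phenotypes and per-subject component time-courses in one seeded
#' pass. Subject order matches the phenotype table (patients first).
#'
#' @param config A `sim_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return An object of class `icn_cohort`: list with `phenotypes` (data
#'   frame), `timecourses` (named list of frames x components matrices) and
#'   `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  params <- phenotype_params()
  if (config$null_effect) params$patient <- params$control
  with_seed(seed, {
    phen <- rbind(phenotype_draw(config$n_patients, "patient", params),
                  phenotype_draw(config$n_controls, "control", params))
    tcs <- lapply(seq_len(nrow(phen)), function(s)
      timecourse_matrix(config, phen$group[s]))
    names(tcs) <- phen$subject_id
    structure(list(phenotypes = phen, timecourses = tcs, config = config),
              class = "icn_cohort")
  })
}

#' @export
print.icn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICN cohort: %d patients + %d controls, %d frames x %d components (TR %gs)\n",
              x$config$n_patients, x$config$n_controls,
              x$config$n_timepoints, x$config$n_components,
              x$config$tr_seconds))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d+%d subjects, T=%d, TR=%gs, %d components, carrier %g Hz%s\n",
              x$n_patients, x$n_controls, x$n_timepoints, x$tr_seconds,
              x$n_components, x$carrier_freq_hz,
              if (x$null_effect) " (null effect)" else ""))
  invisible(x)
}
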