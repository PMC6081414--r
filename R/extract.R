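#' Extract one network time-course by spatial regression
#'
#' For each frame of the 4D volume, the frame and the template map are
#' reshaped to vectors over the mask and the frame values are regressed on
#' the map values (simple linear regression with intercept); the slope is
#' that frame's activity estimate ("beta"). Stringing the betas along the
#' timeline yields the network time-course — the spatial-regression step of
#' dual regression applied one map at a time.
#'
#' The intercept absorbs any global per-frame offset, so adding a constant
#' to a frame leaves its beta unchanged, and scaling a frame by `c` scales
#' its beta by `c`.
#'
#' @param volume4d 4D array `(x, y, z, t)`.
#' @param template_map 3D array (or vector) of map values on the same grid.
#' @param mask Logical array on the same grid; `NULL` uses all voxels.
#' @return Numeric vector of length `T` (one beta per frame).
#' @export
extract_timecourse <- function(volume4d, template_map, mask = NULL) {
  dv <- dim(volume4d)
  if (is.null(dv) || length(dv) != 4L)
    stop("volume4d must be a 4D array", call. = FALSE)
  grid <- dv[1:3]
  map <- as.numeric(template_map)
  if (length(map) != prod(grid))
    stop(sprintf("grid mismatch: template has %d voxels, volume frames have %d",
                 length(map), prod(grid)), call. = FALSE)
  if (is.null(mask)) {
    mask_vec <- rep(TRUE, prod(grid))
  } else {
    mask_vec <- as.logical(mask)
    if (length(mask_vec) != prod(grid))
      stop("mask does not match the volume grid", call. = FALSE)
  }
  if (sum(mask_vec) < 2L)
    stop("need at least 2 in-mask voxels", call. = FALSE)
  m <- map[mask_vec]
  mc <- m - mean(m)
  ss <- sum(mc^2)
  if (ss == 0)
    stop("template is constant within the mask; regression slope undefined",
         call. = FALSE)
  vox <- matrix(volume4d, nrow = prod(grid))[mask_vec, , drop = FALSE]
  # slope_t = sum((m - mean(m)) * v_t) / sum((m - mean(m))^2); centring the
  # frame is unnecessary because mc sums to zero.
  as.numeric(crossprod(vox, mc)) / ss
}

#' Extract all network time-courses from a 4D volume
#'
#' Runs [extract_timecourse()] for every template map (default), or fits all
#' maps jointly in a single per-frame multiple regression (`joint = TRUE`),
#' which removes the cross-talk simple regression suffers when maps overlap
#' spatially.
#'
#' @param volume4d 4D array `(x, y, z, t)`.
#' @param templates A `template_set` (see [simulate_templates()]), or a list
#'   with elements `maps` (voxels x components matrix), `grid_shape`, `mask`
#'   and optionally `labels`.
#' @param joint Fit all maps simultaneously per frame (default `FALSE`,
#'   one-map-at-a-time simple regression).
#' @return A frames x components matrix with component labels as column
#'   names and attribute `tr_seconds` copied from the volume when present.
#' @export
extract_all <- function(volume4d, templates, joint = FALSE) {
  if (is.null(templates$maps) || NCOL(templates$maps) == 0L)
    stop("templates is empty: no maps to extract", call. = FALSE)
  maps <- as.matrix(templates$maps)
  n_comp <- ncol(maps)
  labels <- templates$labels %||% colnames(maps) %||% default_icn_labels(n_comp)
  mask <- templates$mask
  if (joint) {
    dv <- dim(volume4d)
    if (is.null(dv) || length(dv) != 4L)
      stop("volume4d must be a 4D array", call. = FALSE)
    mask_vec <- if (is.null(mask)) rep(TRUE, prod(dv[1:3])) else as.logical(mask)
    if (length(mask_vec) != prod(dv[1:3]))
      stop("mask does not match the volume grid", call. = FALSE)
    design <- cbind(intercept = 1, maps[mask_vec, , drop = FALSE])
    if (qr(design)$rank < ncol(design))
      stop("template maps are collinear within the mask; joint regression undefined",
           call. = FALSE)
    vox <- matrix(volume4d, nrow = prod(dv[1:3]))[mask_vec, , drop = FALSE]
    betas <- qr.solve(design, vox)       # (1 + N) x T
    out <- t(betas[-1L, , drop = FALSE])
  } else {
    cols <- lapply(seq_len(n_comp), function(i) {
      tryCatch(extract_timecourse(volume4d, maps[, i], mask),
               error = function(e)
                 stop(sprintf("component %s: %s", labels[i], conditionMessage(e)),
                      call. = FALSE))
    })
    out <- do.call(cbind, cols)
  }
  colnames(out) <- labels
  attr(out, "tr_seconds") <- attr(volume4d, "tr_seconds")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
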