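# File-format interfaces: NIfTI volumes via RNifti, 6-column motion text,
# phenotype CSV, and time-course TSV.

#' Write / read a 4D volume as NIfTI
#'
#' @param volume4d 4D array `(x, y, z, t)`; an attribute `tr_seconds` is
#'   stored in the NIfTI time pixdim.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_bold()` returns `path` invisibly; `read_bold()` returns
#'   the 4D array with `tr_seconds` restored from the header.
#' @export
write_bold <- function(volume4d, path) {
  stopifnot(length(dim(volume4d)) == 4L)
  tr <- attr(volume4d, "tr_seconds") %||% 1
  img <- RNifti::asNifti(unclass_keep_dim(volume4d))
  RNifti::pixdim(img) <- c(1, 1, 1, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  pd <- RNifti::pixdim(img)
  if (length(pd) >= 4L && pd[4] > 0) attr(out, "tr_seconds") <- pd[4]
  out
}

unclass_keep_dim <- function(x) {
  d <- dim(x)
  x <- as.numeric(x)
  dim(x) <- d
  x
}

#' Write / read a template set as a 4D NIfTI stack
#'
#' Maps are stacked along the 4th dimension; the mask is the full grid box
#' (matching [simulate_templates()]). Component labels are not stored in
#' NIfTI and must be re-supplied (defaults used otherwise).
#'
#' @param templates A `template_set`.
#' @param path Output path.
#' @param labels Optional labels on read.
#' @return `write_templates()` returns `path` invisibly; `read_templates()`
#'   a `template_set`.
#' @export
write_templates <- function(templates, path) {
  stopifnot(inherits(templates, "template_set"))
  arr <- array(templates$maps,
               dim = c(templates$grid_shape, ncol(templates$maps)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path, labels = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  maps <- matrix(as.numeric(img), nrow = prod(d[1:3]))
  n <- d[4]
  labels <- labels %||% default_icn_labels(n)
  colnames(maps) <- labels
  structure(list(maps = maps, grid_shape = d[1:3],
                 mask = array(TRUE, dim = d[1:3]),
                 labels = labels, centers = NULL),
            class = "template_set")
}

#' Read / write a 6-column rigid-body motion file
#'
#' Whitespace-delimited text, one row per frame: 3 translations (mm) then
#' 3 rotations (radians unless `rotations_in_degrees`).
#'
#' @param path File path.
#' @param rotations_in_degrees Convert rotation columns from degrees to
#'   radians on read.
#' @return A frames x 6 matrix with standard column names.
#' @export
read_motion <- function(path, rotations_in_degrees = FALSE) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop(sprintf("expected 6 motion columns, found %d in %s", ncol(m), path),
         call. = FALSE)
  if (rotations_in_degrees) m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname read_motion
#' @param motion Frames x 6 matrix.
#' @export
write_motion <- function(motion, path) {
  write.table(as.matrix(motion), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the phenotype table
#'
#' CSV with columns `subject_id`, `group`, `sex`, `age`, `viq`, `piq`,
#' `fiq`, `mean_fd`.
#'
#' @param phenotypes Data frame as produced by [simulate_phenotypes()].
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a time-course matrix as TSV
#'
#' Tab-separated, one row per frame, with a component-label header row.
#'
#' @param tc Frames x components matrix.
#' @param path File path.
#' @param tr_seconds Optional TR restored as an attribute on read.
#' @export
write_timecourses <- function(tc, path) {
  write.table(as.matrix(tc), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path, tr_seconds = NULL) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  if (!is.null(tr_seconds)) attr(m, "tr_seconds") <- tr_seconds
  m
}
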