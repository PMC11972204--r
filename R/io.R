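#' Read and write BIDS-dialect events tables
#'
#' Tab-separated tables with columns onset, duration, trial_type, source
#' (seconds, 0-based onsets); validated on both paths so a malformed table
#' (negative duration, unknown label, overlap) fails loudly.
#'
#' @param events Events table.
#' @param path File path.
#' @return `read_events` returns the validated data frame; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}

#' Read and write generic TSV tables
#' @param x Data frame.
#' @param path File path.
#' @return `read_table_tsv` returns the data frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a simulated run as a NIfTI-1 volume
#'
#' Voxels are laid out on a 1D grid (x axis) by voxel index; the 4th
#' dimension is time with the TR stored in the header (RAS+ identity
#' affine scaled by voxel size).
#'
#' @param Y Matrix volumes x voxels from [simulate_run()].
#' @param path Output path (.nii or .nii.gz).
#' @param tr_s Repetition time (s).
#' @param voxel_mm Voxel size (mm).
#' @return `path`, invisibly.
#' @export
write_volume <- function(Y, path, tr_s = attr(Y, "tr_s") %||% 2, voxel_mm = 0.8) {
  arr <- array(t(Y), dim = c(ncol(Y), 1L, 1L, nrow(Y)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_mm, voxel_mm, voxel_mm, tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @return `read_volume` returns the volumes x voxels matrix with `tr_s`
#'   attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D volume", call. = FALSE)
  Y <- t(matrix(img, prod(d[1:3]), d[4]))
  attr(Y, "tr_s") <- RNifti::pixdim(img)[4]
  Y
}

#' Read and write pipeline configurations as YAML
#'
#' @param config Configuration list (see [pipeline_config()]).
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
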