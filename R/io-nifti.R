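# NIfTI-1 volume I/O (via RNifti) and CSV helpers.

#' Write an array as NIfTI-1
#'
#' @param data 3-D or 4-D numeric/logical array.
#' @param affine 4x4 voxel-to-world transform (mm).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype storage type passed to RNifti (e.g. `"double"`,
#'   `"uint8"`, `"int16"`).
#' @return invisibly, `path`.
#' @export
write_nifti <- function(data, affine, path, datatype = "double") {
  img <- RNifti::asNifti(data * 1)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path input path.
#' @return list with `data` (array) and `affine` (4x4 voxel-to-world).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim(img)), affine = unclass(aff)[1:4, 1:4])
}

#' Write a measurements or table data.frame as CSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
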