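#' BOLD panel container
#'
#' The pipeline's main currency: a cohort of per-subject ROI timeseries
#' matrices (rows = timepoints, columns = ROIs, column names = atlas region
#' names) plus the sampling interval.
#'
#' @param subjects Named list of time x ROI numeric matrices with identical
#'   column names.
#' @param tr Repetition time in seconds.
#' @return A list of class `bold_panel` with elements `subjects` and `tr`.
#' @export
bold_panel <- function(subjects, tr) {
  if (!length(subjects)) stop("a BOLD panel needs at least one subject")
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("sub-%03d", seq_along(subjects))
  cn <- colnames(subjects[[1]])
  if (is.null(cn)) stop("subject matrices must carry ROI names as colnames")
  for (s in seq_along(subjects)) {
    if (!identical(colnames(subjects[[s]]), cn))
      stop("subject ", names(subjects)[s], " has a different ROI set/order")
  }
  if (!is.numeric(tr) || tr <= 0) stop("'tr' must be positive seconds")
  structure(list(subjects = subjects, tr = tr), class = "bold_panel")
}

#' @export
print.bold_panel <- function(x, ...) {
  cat("<bold_panel> ", length(x$subjects), " subjects, ",
      nrow(x$subjects[[1]]), " timepoints x ", ncol(x$subjects[[1]]),
      " ROIs, TR = ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Voxel panel container
#'
#' A single-subject 4-D voxel dataset: the data array (x, y, z, time), the
#' voxel size in mm, and an integer parcellation volume of the same spatial
#' shape (0 = background).
#'
#' @param data 4-D numeric array.
#' @param voxel_size_mm Positive isotropic voxel size (mm).
#' @param parcellation Integer 3-D array matching the spatial shape.
#' @param tr Repetition time in seconds.
#' @return A list of class `voxel_panel`.
#' @export
voxel_panel <- function(data, voxel_size_mm, parcellation, tr) {
  if (length(dim(data)) != 4) stop("'data' must be a 4-D (x, y, z, time) array")
  if (dim(data)[4] < 16) stop("voxel sessions need at least 16 timepoints")
  if (!isTRUE(all(dim(parcellation) == dim(data)[1:3])))
    stop("parcellation shape must match the spatial shape of 'data'")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("'voxel_size_mm' must be positive")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 parcellation = array(as.integer(parcellation),
                                      dim = dim(data)[1:3]),
                 tr = tr),
            class = "voxel_panel")
}

#' @export
print.voxel_panel <- function(x, ...) {
  d <- dim(x$data)
  cat("<voxel_panel> grid ", paste(d[1:3], collapse = "x"), ", ", d[4],
      " timepoints, voxel ", x$voxel_size_mm, " mm, ",
      sum(x$parcellation > 0), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Read / write a voxel panel as NIfTI
#'
#' Stores the 4-D data as `<prefix>_bold.nii.gz` and the parcellation as
#' `<prefix>_parc.nii.gz` (requires the RNifti package).
#'
#' @param panel A `voxel_panel`.
#' @param prefix Path prefix for the two files.
#' @param voxel_size_mm,tr Metadata needed on the read side.
#' @return `write_voxel_panel` returns the paths invisibly;
#'   `read_voxel_panel` returns a `voxel_panel`.
#' @export
write_voxel_panel <- function(panel, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  paths <- c(bold = paste0(prefix, "_bold.nii.gz"),
             parc = paste0(prefix, "_parc.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(panel$data), paths[["bold"]])
  RNifti::writeNifti(RNifti::asNifti(panel$parcellation), paths[["parc"]])
  invisible(paths)
}

#' @rdname write_voxel_panel
#' @export
read_voxel_panel <- function(prefix, voxel_size_mm, tr) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  dat <- as.array(RNifti::readNifti(paste0(prefix, "_bold.nii.gz")))
  parc <- as.array(RNifti::readNifti(paste0(prefix, "_parc.nii.gz")))
  voxel_panel(dat, voxel_size_mm = voxel_size_mm,
              parcellation = round(parc), tr = tr)
}

## time x voxel matrix of the in-mask voxels, plus their mm coordinates
flatten_voxels <- function(panel) {
  dims <- dim(panel$data)[1:3]
  mask <- which(panel$parcellation > 0)
  idx <- arrayInd(mask, dims)
  coords <- (idx - 0.5) * panel$voxel_size_mm
  mat <- matrix(panel$data, nrow = prod(dims))[mask, , drop = FALSE]
  list(ts = t(mat), coords = coords, mask = mask,
       labels = panel$parcellation[mask])
}
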