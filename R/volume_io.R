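# Canonical in-memory data model for CT volumes and NIfTI input/output.
#
# Axis convention everywhere in the package: (slice, row, column), 0-based
# slice indexing in user-facing reports, with the through-plane axis first.
# On disk NIfTI stores (column, row, slice) fastest-first; read/write permute.

#' Construct a CT image volume
#'
#' @param intensities 3D numeric array in (slice, row, column) order.
#' @param spacing Numeric length-3: (through-plane mm, row mm, column mm).
#' @param units `"HU"` for calibrated Hounsfield data, `"zscore"` after
#'   normalisation.
#' @param orientation Opaque affine/orientation metadata carried through I/O.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing = c(1, 1, 1), units = "HU", orientation = NULL) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L) stop("intensities must be a 3D array")
  if (dim(intensities)[1] < 1L) stop("volume must have at least one slice")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(intensities = intensities, spacing = spacing,
                 units = units, orientation = orientation),
            class = "ct_volume")
}

#' Construct a voxel-wise label volume
#'
#' Class 0 is background by convention.
#'
#' @param classes 3D integer array, same (slice, row, column) order as the
#'   image it annotates.
#' @param class_names Character vector naming classes `0..K-1`; names beyond
#'   the observed maximum are allowed.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(classes, class_names = NULL) {
  classes <- as.array(classes)
  if (length(dim(classes)) != 3L) stop("classes must be a 3D array")
  if (any(classes < 0)) stop("label classes must be non-negative")
  if (any(abs(classes - round(classes)) > 1e-6)) {
    stop("label volume contains non-integer values")
  }
  storage.mode(classes) <- "integer"
  if (is.null(class_names)) {
    class_names <- c("background", paste0("class", seq_len(max(classes, 0))))
  }
  if (max(classes) >= length(class_names)) {
    stop("max class id ", max(classes), " exceeds named classes (", length(class_names), ")")
  }
  structure(list(classes = classes, class_names = class_names),
            class = "label_volume")
}

#' Construct a case (image with optional labels)
#'
#' @param image A [ct_volume()].
#' @param labels A [label_volume()] or `NULL` (e.g. at inference).
#' @param id Case identifier string.
#' @return An object of class `ct_case`.
#' @export
ct_case <- function(image, labels = NULL, id = "case") {
  stopifnot(inherits(image, "ct_volume"))
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_volume"))
    if (!identical(dim(image$intensities), dim(labels$classes))) {
      stop("image shape (", paste(dim(image$intensities), collapse = "x"),
           ") and label shape (", paste(dim(labels$classes), collapse = "x"),
           ") differ")
    }
  }
  structure(list(image = image, labels = labels, id = as.character(id)),
            class = "ct_case")
}

#' @export
print.ct_case <- function(x, ...) {
  d <- dim(x$image$intensities)
  cat(sprintf("<ct_case '%s'> %d slices x %dx%d, spacing %.2f/%.2f/%.2f mm, %s\n",
              x$id, d[1], d[2], d[3],
              x$image$spacing[1], x$image$spacing[2], x$image$spacing[3],
              if (is.null(x$labels)) "unlabelled" else
                paste0(length(unique(as.vector(x$labels$classes))), " label classes present")))
  invisible(x)
}

# (slice,row,col) in memory <-> (col,row,slice) on disk
.to_disk <- function(arr) aperm(arr, c(3L, 2L, 1L))
.from_disk <- function(nim) {
  arr <- array(as.numeric(nim), dim = dim(nim))  # strip niftiImage attributes
  aperm(arr, c(3L, 2L, 1L))
}

#' Write a case as NIfTI files
#'
#' Images are written as 32-bit float (HU values survive losslessly), labels
#' as unsigned 8-bit integers. Voxel spacing is embedded in the header with
#' the slice thickness as the through-plane spacing, mirroring the
#' imaging/segmentation pair layout of the KiTS-style challenge datasets.
#'
#' @param case A [ct_case()].
#' @param image_path Output path (`.nii` or `.nii.gz`).
#' @param label_path Optional output path for the label volume.
#' @export
write_case <- function(case, image_path, label_path = NULL) {
  stopifnot(inherits(case, "ct_case"))
  sp <- case$image$spacing
  img <- RNifti::asNifti(.to_disk(case$image$intensities * 1.0))
  RNifti::pixdim(img) <- c(sp[3], sp[2], sp[1])
  RNifti::writeNifti(img, image_path, datatype = "float")
  if (!is.null(label_path)) {
    if (is.null(case$labels)) stop("case has no labels to write")
    lab <- RNifti::asNifti(.to_disk(case$labels$classes + 0L))
    RNifti::pixdim(lab) <- c(sp[3], sp[2], sp[1])
    RNifti::writeNifti(lab, label_path, datatype = "uint8")
  }
  invisible(NULL)
}

#' Read a case from NIfTI files
#'
#' Axes are permuted so the through-plane (slice) axis comes first; spacing is
#' permuted consistently. Label values must be integral to within `1e-6`.
#'
#' @param image_path Path to the image NIfTI.
#' @param label_path Optional path to the aligned segmentation NIfTI.
#' @param id Case identifier; defaults to the image file name.
#' @return A [ct_case()].
#' @export
read_case <- function(image_path, label_path = NULL,
                      id = sub("\\.nii(\\.gz)?$", "", basename(image_path))) {
  nim <- RNifti::readNifti(image_path)
  arr <- .from_disk(nim)
  pd <- RNifti::pixdim(nim)
  spacing <- c(pd[3], pd[2], pd[1])
  image <- ct_volume(arr, spacing = spacing,
                     orientation = RNifti::niftiHeader(nim))
  labels <- NULL
  if (!is.null(label_path)) {
    lab <- .from_disk(RNifti::readNifti(label_path))
    if (!identical(dim(lab), dim(arr))) {
      stop("label shape (", paste(dim(lab), collapse = "x"),
           ") does not match image shape (", paste(dim(arr), collapse = "x"), ")")
    }
    if (any(abs(lab - round(lab)) > 1e-6)) {
      stop("label file contains non-integer values: ", label_path)
    }
    labels <- label_volume(round(lab))
  }
  ct_case(image, labels, id = id)
}
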