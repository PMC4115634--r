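# Volume data model and NIfTI-1 I/O.
#
# A volume couples a 3-D intensity array with a 4x4 voxel-to-world affine
# (0-based voxel indices, world coordinates in mm). Label volumes hold
# non-negative integer labels with 0 = background. All spatial transforms in
# the package act in world space.

#' Construct an intensity volume
#'
#' @param data 3-D numeric array of intensities.
#' @param affine 4x4 voxel-to-world matrix (mm); last row `(0,0,0,1)`.
#'   Voxel indices are 0-based.
#' @param mask optional logical array of the same shape marking the region
#'   of interest; registration and statistics restrict to it when present.
#' @return An object of class `mp_volume`.
#' @export
volume <- function(data, affine = diag(4), mask = NULL) {
  stopifnot(length(dim(data)) == 3)
  check_affine(affine)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(data)))
    mask <- array(as.logical(mask), dim(mask))
  }
  structure(list(data = data, affine = unname(affine), mask = mask),
            class = "mp_volume")
}

#' Construct a label volume
#'
#' @param data 3-D array of non-negative integer labels (0 = background).
#' @inheritParams volume
#' @return An object of class `mp_labels`.
#' @export
label_volume <- function(data, affine = diag(4)) {
  stopifnot(length(dim(data)) == 3)
  check_affine(affine)
  d <- array(as.integer(round(data)), dim(data))
  if (any(d < 0)) stop("labels must be non-negative integers")
  structure(list(data = d, affine = unname(affine)), class = "mp_labels")
}

check_affine <- function(affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine is singular")
  invisible(TRUE)
}

#' @export
print.mp_volume <- function(x, ...) {
  cat("<mp_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(voxel_spacing(x), 4), collapse = "/"),
      " mm", if (!is.null(x$mask)) sprintf(", mask (%d voxels)", sum(x$mask)),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.mp_labels <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$data))), 0L)
  cat("<mp_labels> ", paste(dim(x$data), collapse = " x "),
      " voxels, labels {", paste(labs, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Voxel spacing along each axis (mm)
#' @param v an `mp_volume`, `mp_labels`, or `mp_field`.
#' @return length-3 numeric vector.
#' @export
voxel_spacing <- function(v) {
  a <- v$affine[1:3, 1:3]
  sqrt(colSums(a^2))
}

#' Read a NIfTI-1 volume
#'
#' Integer-typed files (NIfTI datatypes uint8/int16/int32/uint16) load as
#' label volumes; floating-point files load as intensity volumes. Only 3-D
#' images are supported.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as one of `"auto"`, `"volume"`, `"labels"` to override the
#'   datatype-based choice.
#' @return `mp_volume` or `mp_labels`.
#' @export
read_volume <- function(path, as = c("auto", "volume", "labels")) {
  as <- match.arg(as)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3-D volume, got ", length(d), "-D: ", path)
  affine <- unname(structure(RNifti::xform(img), class = NULL))
  hdr <- RNifti::niftiHeader(img)
  integer_types <- c(2L, 4L, 8L, 256L, 512L, 768L)  # NIfTI datatype codes
  is_int <- hdr$datatype %in% integer_types
  arr <- array(as.numeric(img), dim = d)
  if (as == "labels" || (as == "auto" && is_int))
    label_volume(arr, affine)
  else
    volume(arr, affine)
}

#' Write a volume to NIfTI-1
#'
#' Intensity volumes are stored as float64 (lossless for the in-memory
#' representation); label volumes as int32.
#'
#' @param v `mp_volume` or `mp_labels`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, c("mp_volume", "mp_labels")))
  datatype <- if (inherits(v, "mp_labels")) "int32" else "double"
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(v$data, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# World -> voxel (0-based) coordinates for an n x 3 matrix of points.
world_to_voxel <- function(affine, pts) {
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
}

# Voxel (0-based) -> world coordinates.
voxel_to_world <- function(affine, pts) {
  t(affine[1:3, 1:3] %*% t(pts) + affine[1:3, 4])
}

# All voxel centres of a grid in world coordinates (nvox x 3, column-major
# voxel order so the result aligns with as.vector(array)).
grid_world_points <- function(affine, dim) {
  ijk <- as.matrix(expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                               k = 0:(dim[3] - 1)))
  voxel_to_world(affine, ijk)
}

# Sample an intensity volume at world points (trilinear).
# outside = "zero" or "clamp".
sample_volume <- function(v, world_pts, outside = "zero", fill = 0) {
  vox <- world_to_voxel(v$affine, world_pts)
  mode <- if (outside == "clamp") 1L else 0L
  cpp_sample_trilinear(as.numeric(v$data), dim(v$data), vox, mode, fill)
}

# Sample a label volume at world points (nearest neighbour, outside -> 0).
sample_labels <- function(v, world_pts) {
  vox <- world_to_voxel(v$affine, world_pts)
  as.integer(cpp_sample_nearest(as.numeric(v$data), dim(v$data), vox, 0))
}
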