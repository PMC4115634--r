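# Deformation-based-morphometry statistics: per-subject displacement
# fields from the common space, linear-part removal, multi-kernel
# smoothing and Jacobian determinants.

#' Displacement fields of a common-to-subject transform
#'
#' @param common_to_subject transform chain mapping the common space to
#'   one subject.
#' @param grid grid description (typically the common-space average).
#' @return list with `full` (displacement of the composed chain) and
#'   `pure_nlin` (displacement after removing the best-fit linear part),
#'   both `mp_field`s on `grid`.
#' @export
compute_subject_displacement <- function(common_to_subject, grid) {
  full <- chain_to_field(as_chain(common_to_subject), grid)
  pure <- pure_nonlinear_component(as_chain(common_to_subject), grid)
  list(full = full, pure_nlin = pure)
}

#' Smoothed Jacobian-determinant set
#'
#' For each kernel: the displacement field is Gaussian-smoothed first and
#' the Jacobian determinant of the smoothed field is taken (smoothing
#' precedes the determinant).
#'
#' @param field `mp_field`.
#' @param kernels numeric vector of smoothing fwhms in mm (>= 0).
#' @param log_scale return log-determinants.
#' @return list of `mp_volume`, one per kernel.
#' @export
compute_determinant_set <- function(field, kernels, log_scale = FALSE) {
  stopifnot(all(kernels >= 0))
  lapply(kernels, function(k)
    jacobian_determinant(smooth_field(field, k), log_scale = log_scale))
}

#' Default determinant smoothing kernel
#' @param spacing voxel size in mm.
#' @return single kernel, `2 x` the voxel size.
#' @export
default_stats_kernels <- function(spacing) 2 * spacing
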