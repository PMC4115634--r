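# Stage callables: the functions pipeline stages execute. Each reads its
# inputs from disk, runs one atom, and writes its outputs, so stages stay
# serializable (arguments are paths and scalars only) and restartable.

load_masked <- function(path, mask = NULL) {
  v <- read_volume(path, as = "volume")
  if (!is.null(mask) && file.exists(mask)) {
    m <- read_volume(mask)
    v$mask <- m$data > 0
  }
  v
}

#' @rdname stage_callables
#' @name stage_callables
#' @title Stage callables
#' @description Worker functions executed by pipeline stages; exposed so
#'   checkpointed pipelines can resolve them by name. Each takes file
#'   paths and scalars, runs a single atom, and writes its outputs.
#' @param input,output,source,target,like,inputs,init,mask file paths.
#' @param fwhm,reference_mean,dof,level,kernels numeric parameters.
#' @param protocol path to a protocol CSV.
#' @param labels logical: resample nearest-neighbour as labels.
#' @param chain_parts,out_dir,prefix,log_scale,center stats/consensus
#'   stage parameters.
#' @return the primary output path, invisibly.
NULL

#' @rdname stage_callables
#' @export
run_blur_stage <- function(input, output, fwhm) {
  v <- read_volume(input, as = "volume")
  write_volume(gaussian_blur(v, fwhm), output)
}

#' @rdname stage_callables
#' @export
run_linear_register_stage <- function(source, target, output, dof = 12,
                                      protocol = NULL, level = NULL,
                                      init = NULL, mask = NULL) {
  sv <- load_masked(source)
  tv <- load_masked(target, mask)
  prot <- if (!is.null(protocol)) read_protocol(protocol)
  if (!is.null(prot) && !is.null(level)) {
    prot <- prot[prot$level == level, , drop = FALSE]
    prot$blur_fwhm <- NA  # stage inputs are pre-blurred
  }
  init_t <- if (!is.null(init)) read_transform(init)
  a <- linear_register(sv, tv, dof = dof, protocol = prot, init = init_t)
  write_transform(a, output)
}

#' @rdname stage_callables
#' @export
run_nonlinear_register_stage <- function(source, target, output,
                                         protocol = NULL, level = NULL,
                                         init = NULL, mask = NULL) {
  sv <- load_masked(source)
  tv <- load_masked(target, mask)
  prot <- if (!is.null(protocol)) read_protocol(protocol)
  if (!is.null(prot) && !is.null(level)) {
    prot <- prot[prot$level == level, , drop = FALSE]
    prot$blur_fwhm <- NA  # stage inputs are pre-blurred
  }
  init_t <- if (!is.null(init)) read_transform(init)
  f <- nonlinear_register(sv, tv, protocol = prot, init = init_t)
  write_transform(f, output)
}

#' @rdname stage_callables
#' @export
run_resample_stage <- function(input, output, like, init = NULL,
                               labels = FALSE) {
  v <- read_volume(input, as = if (labels) "labels" else "volume")
  lk <- read_volume(like, as = "volume")
  t <- if (!is.null(init)) read_transform(init)
  write_volume(resample_volume(v, t, like = lk), output)
}

#' @rdname stage_callables
#' @export
run_average_stage <- function(inputs, output) {
  vs <- lapply(inputs, read_volume, as = "volume")
  write_volume(average_volumes(vs), output)
}

#' @rdname stage_callables
#' @export
run_normalize_stage <- function(input, output, reference_mean,
                                mask = NULL) {
  v <- load_masked(input, mask)
  write_volume(normalize_intensity(v, reference_mean), output)
}

#' @rdname stage_callables
#' @export
run_vote_stage <- function(inputs, output) {
  ls <- lapply(inputs, read_volume, as = "labels")
  write_volume(voxel_vote(ls), output)
}

#' @rdname stage_callables
#' @export
run_average_xfm_stage <- function(inputs, output, center = c(0, 0, 0),
                                  include_identity = TRUE) {
  affs <- lapply(inputs, read_transform)
  write_transform(average_affines(affs, center = center,
                                  include_identity = include_identity),
                  output)
}

#' @rdname stage_callables
#' @export
run_invert_stage <- function(input, output, like) {
  t <- read_transform(input)
  lk <- read_volume(like, as = "volume")
  composed <- compose_transform(as_chain(t), grid = lk)
  write_transform(invert_transform(composed), output)
}

#' @rdname stage_callables
#' @export
run_stats_stage <- function(chain_parts, like, out_dir, prefix,
                            kernels, mask = NULL) {
  parts <- lapply(chain_parts, read_transform)
  chain <- do.call(transform_chain, parts)
  lk <- load_masked(like, mask)
  disp <- compute_subject_displacement(chain, lk)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_transform(disp$full,
                  file.path(out_dir, paste0(prefix, "_full.field.nii.gz")))
  for (k in kernels) {
    ktag <- gsub("[^0-9.]", "", format(k))
    det <- compute_determinant_set(disp$full, k)[[1]]
    write_volume(det, file.path(out_dir,
                                paste0(prefix, "_det_fwhm", ktag,
                                       ".nii.gz")))
    write_volume(volume(log(det$data), det$affine),
                 file.path(out_dir, paste0(prefix, "_log_det_fwhm", ktag,
                                           ".nii.gz")))
    rel <- compute_determinant_set(disp$pure_nlin, k)[[1]]
    write_volume(rel, file.path(out_dir,
                                paste0(prefix, "_rel_det_fwhm", ktag,
                                       ".nii.gz")))
  }
  invisible(out_dir)
}
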