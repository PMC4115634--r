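# Application builders: LSQ6, pairwise LSQ12, iterative NLIN, and the
# full group-wise model-building (MBM) pipeline. Each builder only adds
# stages to a pipeline (no image work happens here); run the result with
# execute(). Builders record their key output artifacts in
# p$artifacts$<name>.
#
# Transform direction convention throughout: every stored transform maps
# TARGET/common space into SOURCE/subject space (the pull-back used for
# resampling), so chains from the final common space to each subject are
# plain concatenations of the recorded transforms.

builder_pipeline <- function(p) {
  if (is.null(p)) p <- pipeline()
  if (is.null(p$artifacts)) p$artifacts <- list()
  p
}

# Bootstrap target: either a given path or the voxel-wise average of the
# raw inputs.
initial_target_stage <- function(p, cohort, output_dir, name) {
  if (identical(cohort$initial_target, "average")) {
    out <- norm_artifact(file.path(output_dir, paste0(name, ".nii.gz")))
    add_stage(p, callable_stage("run_average_stage",
                                args = list(inputs = cohort$inputs,
                                            output = out),
                                inputs = cohort$inputs, outputs = out))
    out
  } else norm_artifact(cohort$initial_target)
}

#' Build an LSQ6 (rigid) alignment pipeline
#'
#' Per input: a blur series, a 6-dof registration per protocol level
#' (each consuming the previous level's transform), and one resample
#' into target space. Target blurs are shared across inputs.
#'
#' @param cohort a [cohort_spec()]. `initial_target` may be an input
#'   path, an initial-model path, or `"average"` to bootstrap a target by
#'   averaging the inputs.
#' @param protocol linear protocol (default at the input voxel size).
#' @param output_dir output root.
#' @param p pipeline to extend (default: a new one).
#' @return the pipeline, with `p$artifacts$lsq6` holding `target`,
#'   `xfms`, `resampled` and the per-input handlers.
#' @export
build_lsq6 <- function(cohort, protocol = NULL, output_dir, p = NULL) {
  p <- builder_pipeline(p)
  if (is.null(protocol)) {
    sp <- min(voxel_spacing(read_volume(cohort$inputs[1])))
    protocol <- default_linear_protocol(sp)
  }
  ppath <- materialize_protocol(protocol, output_dir, "lsq6")
  target <- initial_target_stage(p, cohort, output_dir, "lsq6_target")
  target_h <- file_handler(target, output_dir)
  handlers <- list(); xfms <- character(); res <- character()
  for (i in seq_along(cohort$inputs)) {
    h <- file_handler(cohort$inputs[i], output_dir,
                      mask = mask_for(cohort, cohort$inputs[i]))
    xfm <- hierarchical_stages(p, h, target_h, protocol, ppath,
                               kind = "lsq6")
    res[i] <- resample_stage(p, h, xfm, target, tag = "lsq6")
    xfms[i] <- xfm
    handlers[[i]] <- h
  }
  p$artifacts$lsq6 <- list(target = target, xfms = xfms, resampled = res,
                           handlers = handlers)
  p
}

#' Build a pairwise LSQ12 (full affine) consensus pipeline
#'
#' Registers every ordered pair of inputs with 12 dof, averages each
#' subject's n-1 pair transforms together with its own identity
#' transform in parameter space (the self-term centres the consensus
#' space; without it each subject's deviation is amplified by
#' `n/(n-1)`), resamples each subject once with its averaged transform,
#' and averages the results into the LSQ12-space model.
#'
#' @param inputs paths of rigidly aligned volumes (a common LSQ6 space).
#' @param protocol linear protocol.
#' @param output_dir output root.
#' @param p pipeline to extend.
#' @return pipeline with `p$artifacts$lsq12`: `xfms` (per-subject
#'   averaged affines), `resampled`, `average`.
#' @export
build_lsq12_pairwise <- function(inputs, protocol = NULL, output_dir,
                                 p = NULL) {
  p <- builder_pipeline(p)
  inputs <- norm_artifact(inputs)
  n <- length(inputs)
  if (is.null(protocol)) {
    sp <- min(voxel_spacing(read_volume(inputs[1])))
    protocol <- default_linear_protocol(sp)
  }
  ppath <- materialize_protocol(protocol, output_dir, "lsq12")
  handlers <- lapply(inputs, file_handler, output_dir = output_dir)
  pair_xfms <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      out <- registration_output_name(handlers[[i]], handlers[[j]],
                                      tag = "lsq12", ext = ".aff.txt")
      add_stage(p, callable_stage(
        "run_linear_register_stage",
        args = list(source = inputs[i], target = inputs[j], output = out,
                    dof = 12, protocol = ppath),
        inputs = c(inputs[i], inputs[j]), outputs = out))
      add_xfm(handlers[[i]], handlers[[j]], out)
      # transform j-space -> i-space: it belongs to subject i's consensus
      pair_xfms[[i]] <- c(pair_xfms[[i]], out)
    }
  }
  avg_xfms <- character(n); res <- character(n)
  for (i in seq_len(n)) {
    axfm <- norm_artifact(file.path(handlers[[i]]$group_dir, "transforms",
                                    paste0(handlers[[i]]$stem,
                                           "_lsq12_consensus.aff.txt")))
    add_stage(p, callable_stage("run_average_xfm_stage",
                                args = list(inputs = pair_xfms[[i]],
                                            output = axfm),
                                inputs = pair_xfms[[i]], outputs = axfm))
    avg_xfms[i] <- axfm
    res[i] <- resample_stage(p, handlers[[i]], axfm, inputs[i],
                             tag = "lsq12")
  }
  avg <- norm_artifact(file.path(output_dir, "lsq12_average.nii.gz"))
  add_stage(p, callable_stage("run_average_stage",
                              args = list(inputs = res, output = avg),
                              inputs = res, outputs = avg))
  p$artifacts$lsq12 <- list(xfms = avg_xfms, resampled = res,
                            average = avg)
  p
}

#' Build an iterative nonlinear (NLIN) model-building pipeline
#'
#' Per generation: blur the evolving average and the inputs, register
#' each input nonlinearly to the current average (carrying its previous
#' transform as initialization), resample, and re-average. The final
#' average and each input's final transform are recorded.
#'
#' @param inputs paths of linearly aligned volumes.
#' @param protocol nonlinear protocol.
#' @param generations number of NLIN generations (>= 1).
#' @param output_dir output root.
#' @param p pipeline to extend.
#' @param initial_average optional path of the starting template
#'   (default: average the inputs).
#' @param name stem used for the per-generation average files (lets
#'   several NLIN modules coexist under one output root).
#' @return pipeline with `p$artifacts$nlin`: `average` (final),
#'   `averages` (per generation), `xfms` (per-input final field),
#'   `resampled`.
#' @export
build_nlin <- function(inputs, protocol = NULL, generations = 1,
                       output_dir, p = NULL, initial_average = NULL,
                       name = "nlin") {
  p <- builder_pipeline(p)
  inputs <- norm_artifact(inputs)
  stopifnot(generations >= 1)
  if (is.null(protocol)) {
    sp <- min(voxel_spacing(read_volume(inputs[1])))
    protocol <- default_nonlinear_protocol(sp)
  }
  ppath <- materialize_protocol(protocol, output_dir, name)
  handlers <- lapply(inputs, file_handler, output_dir = output_dir)
  if (is.null(initial_average)) {
    avg <- norm_artifact(file.path(output_dir,
                                   paste0(name, "_gen0.nii.gz")))
    add_stage(p, callable_stage("run_average_stage",
                                args = list(inputs = inputs,
                                            output = avg),
                                inputs = inputs, outputs = avg))
  } else avg <- norm_artifact(initial_average)
  averages <- character(); xfms <- character(length(inputs))
  res <- character(length(inputs))
  last <- rep(list(NULL), length(inputs))
  for (g in seq_len(generations)) {
    target_h <- file_handler(avg, output_dir)
    for (i in seq_along(inputs)) {
      xfm <- hierarchical_stages(p, handlers[[i]], target_h, protocol,
                                 ppath, kind = "nlin",
                                 init = last[[i]])
      res[i] <- resample_stage(p, handlers[[i]], xfm, avg,
                               tag = sprintf("%s_gen%d", name, g))
      xfms[i] <- xfm
      last[[i]] <- xfm
    }
    avg_next <- norm_artifact(file.path(output_dir,
                                        sprintf("%s_gen%d.nii.gz",
                                                name, g)))
    add_stage(p, callable_stage("run_average_stage",
                                args = list(inputs = res,
                                            output = avg_next),
                                inputs = res, outputs = avg_next))
    averages[g] <- avg_next
    avg <- avg_next
  }
  p$artifacts$nlin <- list(average = avg, averages = averages,
                           xfms = xfms, resampled = res)
  p
}

#' Build the full iterative group-wise (MBM) pipeline
#'
#' LSQ6 rigid alignment, intensity normalization, pairwise LSQ12,
#' iterative NLIN, and per-subject DBM statistics from the final common
#' space. The common-to-subject chain for subject i concatenates its
#' final NLIN field, its LSQ12 consensus affine, and its LSQ6 affine.
#'
#' @param cohort a [cohort_spec()].
#' @param output_dir output root.
#' @param lsq6_protocol,lsq12_protocol,nlin_protocol protocols (defaults
#'   at the input voxel size).
#' @param generations NLIN generations.
#' @param stats_kernels fwhms (mm) for determinant smoothing; default
#'   `2 x` voxel size.
#' @param calc_stats add the statistics stages (default `TRUE`).
#' @param p pipeline to extend.
#' @return pipeline with `p$artifacts` from every module plus
#'   `p$artifacts$stats` (`dirs`, per-subject chain part lists).
#' @export
build_mbm <- function(cohort, output_dir, lsq6_protocol = NULL,
                      lsq12_protocol = NULL, nlin_protocol = NULL,
                      generations = 1, stats_kernels = NULL,
                      calc_stats = TRUE, p = NULL) {
  p <- builder_pipeline(p)
  sp <- min(voxel_spacing(read_volume(cohort$inputs[1])))
  # derive every default protocol from the raw inputs: later modules
  # consume artifacts that only exist once the pipeline runs
  if (is.null(lsq6_protocol)) lsq6_protocol <- default_linear_protocol(sp)
  if (is.null(lsq12_protocol)) lsq12_protocol <- default_linear_protocol(sp)
  if (is.null(nlin_protocol))
    nlin_protocol <- default_nonlinear_protocol(sp)
  p <- build_lsq6(cohort, protocol = lsq6_protocol,
                  output_dir = output_dir, p = p)
  lsq6 <- p$artifacts$lsq6
  # intensity normalization between the rigid and affine modules
  normed <- character(length(lsq6$resampled))
  for (i in seq_along(lsq6$resampled)) {
    out <- sub("\\.nii\\.gz$", "_norm.nii.gz", lsq6$resampled[i])
    add_stage(p, callable_stage("run_normalize_stage",
                                args = list(input = lsq6$resampled[i],
                                            output = out,
                                            reference_mean = 1),
                                inputs = lsq6$resampled[i],
                                outputs = out))
    normed[i] <- out
  }
  p <- build_lsq12_pairwise(normed, protocol = lsq12_protocol,
                            output_dir = output_dir, p = p)
  lsq12 <- p$artifacts$lsq12
  p <- build_nlin(lsq12$resampled, protocol = nlin_protocol,
                  generations = generations, output_dir = output_dir,
                  p = p, initial_average = lsq12$average)
  nlin <- p$artifacts$nlin
  if (calc_stats) {
    if (is.null(stats_kernels)) stats_kernels <- default_stats_kernels(sp)
    stats_dir <- file.path(output_dir, "stats")
    chains <- list()
    for (i in seq_along(cohort$inputs)) {
      stem <- sanitize_stem(cohort$inputs[i])
      parts <- list(nlin$xfms[i], lsq12$xfms[i], lsq6$xfms[i])
      chains[[stem]] <- parts
      add_stage(p, callable_stage(
        "run_stats_stage",
        args = list(chain_parts = parts, like = nlin$average,
                    out_dir = norm_artifact(stats_dir), prefix = stem,
                    kernels = stats_kernels),
        inputs = c(unlist(parts), nlin$average),
        outputs = norm_artifact(
          file.path(stats_dir, paste0(stem, "_full.field.nii.gz")))))
    }
    p$artifacts$stats <- list(dir = norm_artifact(stats_dir),
                              chains = chains,
                              kernels = stats_kernels)
  }
  p
}
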