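# Reusable pipeline modules: cohort specification and the hierarchical
# (multi-blur) registration builder that the applications share. Modules
# emit stages through file handlers, so repeated blurs of a shared target
# are constructed once (duplicate elimination in the pipeline removes the
# rest).

#' Cohort specification
#'
#' @param inputs character vector of input volume paths (>= 2).
#' @param subject_of optional character/integer vector mapping each input
#'   to a subject id (longitudinal designs).
#' @param timepoint_of optional integer vector of timepoints, strictly
#'   increasing within each subject.
#' @param initial_target `"average"` (bootstrap a target by averaging the
#'   inputs) or a path to a target / initial-model volume.
#' @param mask_dir optional directory of masks; a mask is matched to each
#'   input by file name.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(inputs, subject_of = NULL, timepoint_of = NULL,
                        initial_target = "average", mask_dir = NULL) {
  if (length(inputs) < 2) stop("a cohort needs at least two inputs")
  if (!is.null(timepoint_of)) {
    stopifnot(!is.null(subject_of), length(timepoint_of) == length(inputs))
    for (s in unique(subject_of)) {
      tp <- timepoint_of[subject_of == s]
      if (any(diff(tp) <= 0))
        stop("timepoints must be strictly increasing within subject ", s)
    }
  }
  structure(list(inputs = norm_artifact(inputs),
                 subject_of = subject_of, timepoint_of = timepoint_of,
                 initial_target = initial_target, mask_dir = mask_dir),
            class = "cohort_spec")
}

#' Read a cohort table (`file,subject,timepoint` CSV)
#' @param path CSV path.
#' @param ... passed on to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
read_cohort_csv <- function(path, ...) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "subject", "timepoint")
  if (!all(need %in% names(df)))
    stop("cohort CSV needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$subject, df$timepoint), ]
  cohort_spec(df$file, subject_of = df$subject,
              timepoint_of = df$timepoint, ...)
}

mask_for <- function(cohort, input) {
  if (is.null(cohort$mask_dir)) return(NULL)
  cand <- file.path(cohort$mask_dir, basename(input))
  if (file.exists(cand)) norm_artifact(cand) else NULL
}

# Write a protocol into the output tree once and reuse the path (stage
# arguments stay scalars; identical protocols fingerprint identically).
materialize_protocol <- function(protocol, output_dir, name) {
  path <- norm_artifact(file.path(output_dir, "protocols",
                                  paste0(name, ".csv")))
  if (!file.exists(path)) write_protocol(protocol, path)
  path
}

#' Emit hierarchical registration stages for one input/target pair
#'
#' For each protocol row: blur the input, blur the target (shared across
#' inputs via the target's handler cache and pipeline-level duplicate
#' elimination), and register the blurred pair, consuming the previous
#' level's transform (the handler's last transform between the pair, or
#' the identity/centroid default when none exists). Stage count per
#' input, for an L-row protocol: L input blurs + L registrations (+ L
#' shared target blurs emitted once overall).
#'
#' @param p the `pp_pipeline` receiving stages.
#' @param input_h,target_h source and target `reg_handler`s.
#' @param protocol nonlinear (or linear) protocol data.frame.
#' @param protocol_path materialized protocol CSV (see
#'   [materialize_protocol()]).
#' @param kind `"nlin"` (demons levels), `"lsq6"` or `"lsq12"` (linear
#'   levels).
#' @param init optional explicit initial transform artifact (overrides
#'   the handler history for the first level).
#' @return artifact identifier of the final (finest-level) transform.
#' @export
hierarchical_stages <- function(p, input_h, target_h, protocol,
                                protocol_path, kind = "nlin",
                                init = NULL) {
  stopifnot(inherits(p, "pp_pipeline"))
  linear <- kind %in% c("lsq6", "lsq12")
  dof <- if (kind == "lsq6") 6 else 12
  last <- init %||% get_last_xfm(input_h, target_h)
  for (row in seq_len(nrow(protocol))) {
    pr <- protocol[row, ]
    fw <- if (is.na(pr$blur_fwhm)) "none" else pr$blur_fwhm
    sb <- get_blur(input_h, p, fw)
    tb <- get_blur(target_h, p, fw)
    ext <- if (linear) ".aff.txt" else ".field.nii.gz"
    out <- registration_output_name(input_h, target_h,
                                    tag = paste0(kind, "_l", pr$level),
                                    ext = ext)
    args <- list(source = sb, target = tb, output = out,
                 protocol = protocol_path, level = pr$level,
                 init = last, mask = target_h$mask)
    fun <- if (linear) "run_linear_register_stage"
           else "run_nonlinear_register_stage"
    if (linear) args$dof <- dof
    ins <- c(sb, tb, if (!is.null(last)) last)
    add_stage(p, callable_stage(fun, args = args, inputs = ins,
                                outputs = out))
    add_xfm(input_h, target_h, out)
    last <- out
  }
  last
}

#' Emit a resample stage for a handler's base volume
#'
#' Resamples the handler's original input through a transform onto the
#' target grid and records the result as the handler's latest resampled
#' state.
#'
#' @param p pipeline.
#' @param input_h handler whose base volume is resampled.
#' @param xfm transform artifact (maps target space to input space).
#' @param like target-grid volume artifact.
#' @param tag name tag for the output file.
#' @return the resampled artifact identifier.
#' @export
resample_stage <- function(p, input_h, xfm, like, tag = "res") {
  out <- norm_artifact(file.path(input_h$group_dir, "resampled",
                                 paste0(input_h$stem, "_", tag,
                                        ".nii.gz")))
  add_stage(p, callable_stage("run_resample_stage",
                              args = list(input = input_h$base_volume,
                                          output = out, like = like,
                                          init = xfm),
                              inputs = c(input_h$base_volume, like, xfm),
                              outputs = out))
  set_last_resampled(input_h, out)
  out
}
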