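# Registration file handlers: per-input bookkeeping of blurred versions,
# transform history per target, and resampled-state lineage, plus the
# deterministic output-naming grammar.
#
# Handlers are pure bookkeeping over artifact identifiers: they hold no
# image data, and all stages they emit go through the pipeline (so
# duplicate blur stages are eliminated there). The original input is
# never mutated — it may be needed again at any later point.

#' Create a registration file handler
#'
#' @param base_volume path to the input volume (NIfTI).
#' @param output_dir root output directory; a subdirectory named after
#'   the input's stem is created for this handler.
#' @param mask optional path to a mask volume associated with the input.
#' @return a `reg_handler` environment.
#' @export
file_handler <- function(base_volume, output_dir, mask = NULL) {
  h <- new.env(parent = emptyenv())
  h$base_volume <- norm_artifact(base_volume)
  h$stem <- sanitize_stem(base_volume)
  h$group_dir <- file.path(normalizePath(output_dir, mustWork = FALSE),
                           h$stem)
  h$blur_cache <- new.env(parent = emptyenv())
  h$xfm_history <- new.env(parent = emptyenv())
  h$last_resampled <- NULL
  h$mask <- if (!is.null(mask)) norm_artifact(mask)
  class(h) <- "reg_handler"
  h
}

sanitize_stem <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
  gsub("[^A-Za-z0-9_.-]", "_", stem)
}

#' @export
print.reg_handler <- function(x, ...) {
  cat("<reg_handler> ", x$stem, "\n  base: ", x$base_volume,
      "\n  blurs cached: ", length(ls(x$blur_cache)),
      ", targets seen: ", length(ls(x$xfm_history)), "\n", sep = "")
  invisible(x)
}

# The volume the handler currently points at: latest resampled state if
# any, else the original input.
current_volume <- function(h) {
  h$last_resampled %||% h$base_volume
}

#' Blurred version of a handler's current volume
#'
#' Returns the cached artifact for this fwhm; on a cache miss, emits
#' exactly one blur stage into the pipeline and caches the output path.
#' `fwhm = "none"` (or 0) returns the current volume itself with no
#' stage.
#'
#' @param h a `reg_handler`.
#' @param p the `pp_pipeline` receiving any new stage.
#' @param fwhm blur fwhm in mm, or `"none"`.
#' @return artifact identifier of the blurred volume.
#' @export
get_blur <- function(h, p, fwhm) {
  if (identical(fwhm, "none") || (is.numeric(fwhm) && fwhm == 0))
    return(current_volume(h))
  stopifnot(is.numeric(fwhm), fwhm > 0)
  key <- format(fwhm, digits = 10)
  hit <- h$blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  src <- current_volume(h)
  out <- file.path(h$group_dir, "blurred",
                   paste0(sanitize_stem(src), "_fwhm",
                          gsub("[^0-9a-zA-Z.]", "", key), ".nii.gz"))
  out <- norm_artifact(out)
  add_stage(p, callable_stage("run_blur_stage",
                              args = list(input = src, output = out,
                                          fwhm = fwhm),
                              inputs = src, outputs = out))
  h$blur_cache[[key]] <- out
  out
}

#' Most recent transform between a handler and a target
#'
#' @param h a `reg_handler`.
#' @param target the target `reg_handler` (or its stem).
#' @return artifact identifier of the last transform, or `NULL` if no
#'   transform between the pair exists yet (callers then fall back to an
#'   identity / default initialization).
#' @export
get_last_xfm <- function(h, target) {
  hist <- h$xfm_history[[target_key(target)]]
  if (is.null(hist) || length(hist) == 0) NULL else hist[[length(hist)]]
}

#' Full transform history between a handler and a target
#' @inheritParams get_last_xfm
#' @return character vector of transform artifacts, oldest first.
#' @export
get_xfm_history <- function(h, target) {
  h$xfm_history[[target_key(target)]] %||% character()
}

#' Append a transform to a handler's history for a target
#'
#' The appended transform becomes the most recent one; earlier transforms
#' remain retrievable by index.
#'
#' @inheritParams get_last_xfm
#' @param xfm_id artifact identifier of the transform.
#' @return `xfm_id`, invisibly.
#' @export
add_xfm <- function(h, target, xfm_id) {
  key <- target_key(target)
  h$xfm_history[[key]] <- c(h$xfm_history[[key]], xfm_id)
  invisible(xfm_id)
}

target_key <- function(target) {
  if (inherits(target, "reg_handler")) target$stem else as.character(target)
}

#' Deterministic output name for a registration
#'
#' Encodes the source stem, target stem, a tag, and the sequence number
#' of transforms already recorded between the pair, so repeat
#' registrations and the two directions of a pair never collide.
#'
#' @param h source `reg_handler`.
#' @param target target `reg_handler` (or stem).
#' @param tag short tag for the registration kind (e.g. `"lsq6"`,
#'   `"lsq12"`, `"nlin"`).
#' @param ext file extension.
#' @return artifact identifier under the handler's transform directory.
#' @export
registration_output_name <- function(h, target, tag = "nlin",
                                     ext = ".chain.json") {
  n_prev <- length(get_xfm_history(h, target))
  norm_artifact(file.path(h$group_dir, "transforms",
                          paste0(h$stem, "_to_", target_key(target), "_",
                                 tag, "_", n_prev, ext)))
}

# Record a resampled state; the base volume itself is never replaced.
set_last_resampled <- function(h, path) {
  h$last_resampled <- norm_artifact(path)
  invisible(h)
}
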