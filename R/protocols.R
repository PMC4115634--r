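# Registration protocols: one row per hierarchical (coarse-to-fine) level.
#
# Columns:
#   level      integer level index (1 = coarsest)
#   blur_fwhm  Gaussian blur fwhm in mm applied to both images at this
#              level ("none"/NA = no blur)
#   step       linear: evaluation-grid sampling step in mm;
#              nonlinear: per-iteration update cap in mm
#   param      linear: simplex scale factor for the optimizer's initial
#              simplex; nonlinear: fwhm (mm) of the Gaussian regularizer
#              applied to each incremental update
#   iterations optimizer iteration cap for the level
#   metric     "ssd" or "ncc"
#
# Defaults scale with the input voxel size, so the same protocol logic
# applies across resolutions.

#' Construct / validate a registration protocol
#'
#' @param df data.frame with columns `level`, `blur_fwhm`, `step`, `param`,
#'   `iterations`, `metric` (see Details in [read_protocol()]).
#' @return validated protocol data.frame.
#' @export
registration_protocol <- function(df) {
  need <- c("level", "blur_fwhm", "step", "param", "iterations", "metric")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("protocol lacks columns: ",
                            paste(missing, collapse = ", "))
  if (nrow(df) < 1) stop("protocol needs at least one row")
  df$blur_fwhm <- suppressWarnings(as.numeric(ifelse(df$blur_fwhm %in%
                                                       c("none", ""),
                                                     NA, df$blur_fwhm)))
  df$metric <- match.arg(tolower(as.character(df$metric)), c("ssd", "ncc"),
                         several.ok = TRUE)
  df[order(df$level), need]
}

#' Default linear-registration protocol
#'
#' Three coarse-to-fine levels with blur fwhm `{8, 4, 2} x` voxel size and
#' evaluation steps `{4, 2, 2} x` voxel size (a 2-voxel step at the
#' finest level recovers parameters as accurately as a dense evaluation
#' at a third of the cost).
#'
#' @param spacing voxel size in mm (scalar; use the smallest axis spacing).
#' @param metric similarity metric, `"ncc"` (default) or `"ssd"`.
#' @return protocol data.frame.
#' @export
default_linear_protocol <- function(spacing, metric = "ncc") {
  registration_protocol(data.frame(
    level = 1:3,
    blur_fwhm = c(8, 4, 2) * spacing,
    step = c(4, 2, 2) * spacing,
    param = 1,
    iterations = 100,
    metric = metric))
}

#' Default nonlinear-registration protocol
#'
#' Two levels with image blur fwhm `{4, 2} x` voxel size, update cap
#' `0.4 x` voxel size, and update regularization fwhm `{6, 3} x` voxel
#' size.
#'
#' @inheritParams default_linear_protocol
#' @param iterations demons iterations per level (cap 100).
#' @return protocol data.frame.
#' @export
default_nonlinear_protocol <- function(spacing, metric = "ncc",
                                       iterations = c(25, 15)) {
  registration_protocol(data.frame(
    level = 1:2,
    blur_fwhm = c(4, 2) * spacing,
    step = 0.4 * spacing,
    param = c(6, 3) * spacing,
    iterations = pmin(iterations, 100),
    metric = metric))
}

#' Read a protocol CSV
#'
#' Header `level,blur_fwhm,step,param,iterations,metric`; the string
#' `"none"` in `blur_fwhm` means no blurring at that level.
#'
#' @param path CSV file path.
#' @return protocol data.frame.
#' @export
read_protocol <- function(path) {
  registration_protocol(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a protocol CSV
#' @param protocol protocol data.frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  out <- protocol
  out$blur_fwhm <- ifelse(is.na(out$blur_fwhm), "none", out$blur_fwhm)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
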