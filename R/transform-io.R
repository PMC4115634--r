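# On-disk transform formats:
#   * affines      -> plain-text 4x4 ("*.aff.txt"), dof tag in a comment
#   * fields       -> 5-D NIfTI vector convention (nx, ny, nz, 1, 3), mm
#   * chains       -> JSON manifest listing member files (relative paths)
# read_transform dispatches on extension.

#' Write a transform to disk
#'
#' @param t `mp_affine`, `mp_field` or `mp_chain`.
#' @param path destination. Conventional extensions: `.aff.txt` (affine),
#'   `.field.nii.gz` (displacement field), `.chain.json` (chain; member
#'   transforms are written next to the manifest).
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (inherits(t, "mp_affine")) {
    lines <- c(paste0("# morphopipe affine v1 dof=", t$dof_tag),
               apply(t$matrix, 1, function(r)
                 paste(formatC(r, format = "g", digits = 17),
                       collapse = " ")))
    writeLines(lines, path)
  } else if (inherits(t, "mp_field")) {
    d <- dim(t$vectors)
    arr <- array(t$vectors, c(d[1:3], 1, 3))
    img <- RNifti::asNifti(arr, datatype = "double")
    # the grid affine applies to the first three (spatial) dimensions
    img <- RNifti::`sform<-`(img, structure(t$affine, code = 2L))
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (inherits(t, "mp_chain")) {
    stem <- sub("\\.chain\\.json$", "", path)
    members <- character(length(t))
    for (i in seq_along(t)) {
      ext <- if (inherits(t[[i]], "mp_affine")) ".aff.txt" else ".field.nii.gz"
      mp <- paste0(stem, "_", i - 1, ext)
      write_transform(t[[i]], mp)
      members[i] <- basename(mp)
    }
    jsonlite::write_json(list(format = "morphopipe-chain", version = 1L,
                              members = members),
                         path, auto_unbox = TRUE)
  } else stop("not a transform: ", class(t)[1])
  invisible(path)
}

#' Read a transform from disk
#'
#' @param path file written by [write_transform()].
#' @return `mp_affine`, `mp_field` or `mp_chain`.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("no such transform file: ", path)
  if (grepl("\\.txt$", path)) {
    lines <- readLines(path)
    tag <- sub(".*dof=", "", lines[1])
    m <- do.call(rbind, lapply(lines[2:5], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    affine_transform(m, dof_tag = tag)
  } else if (grepl("\\.json$", path)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(spec$format, "morphopipe-chain"))
      stop("not a chain manifest: ", path)
    parts <- lapply(file.path(dirname(path), spec$members), read_transform)
    do.call(transform_chain, parts)
  } else {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 5 && d[4] == 1 && d[5] == 3) {
      affine <- unname(structure(RNifti::xform(img), class = NULL))
      displacement_field(array(as.numeric(img), c(d[1:3], 3)), affine)
    } else stop("not a displacement-field NIfTI (need nx,ny,nz,1,3): ", path)
  }
}
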