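# Multi-atlas label propagation with majority-vote fusion (MAGeT-style):
# a small set of labeled atlases is bootstrapped into a template library
# by registering every atlas to every subject, propagating labels, then
# cross-propagating each subject's labels through subject-subject
# registrations before voting.

#' Build a multi-atlas label-fusion pipeline
#'
#' Steps: (A) each atlas is registered (LSQ12 + nonlinear) to each
#' subject; (B) the atlas labels are propagated through the resulting
#' transform, labeling every subject once per atlas; (C) every subject
#' is registered to every other subject with the same hierarchical
#' registration; (D) each subject's step-B labels are propagated to
#' every other subject, building a library of `m x n` label sets per
#' subject (m atlases, n subjects); (E) per-voxel majority voting fuses
#' each subject's library into its final segmentation.
#'
#' @param subjects paths of subject volumes.
#' @param atlases list of `list(volume = <path>, labels = <path>)`.
#' @param output_dir output root.
#' @param lsq12_protocol,nlin_protocol protocols.
#' @param p pipeline to extend.
#' @return pipeline with `p$artifacts$maget`: `fused` (per subject),
#'   `library` (per subject, the label artifacts voted over).
#' @export
build_maget <- function(subjects, atlases, output_dir,
                        lsq12_protocol = NULL, nlin_protocol = NULL,
                        p = NULL) {
  p <- builder_pipeline(p)
  stopifnot(length(atlases) >= 1)
  subjects <- norm_artifact(subjects)
  n <- length(subjects)
  m <- length(atlases)
  sp <- min(voxel_spacing(read_volume(subjects[1])))
  if (is.null(lsq12_protocol)) lsq12_protocol <- default_linear_protocol(sp)
  if (is.null(nlin_protocol))
    nlin_protocol <- default_nonlinear_protocol(sp)
  l12path <- materialize_protocol(lsq12_protocol, output_dir,
                                  "maget_lsq12")
  nlpath <- materialize_protocol(nlin_protocol, output_dir, "maget_nlin")
  # (A) + (B): atlas -> subject registration and label propagation
  own_labels <- matrix("", n, m)  # labels of subject s from atlas a
  for (a in seq_len(m)) {
    av <- norm_artifact(atlases[[a]]$volume)
    al <- norm_artifact(atlases[[a]]$labels)
    for (s in seq_len(n)) {
      fld <- chain_link_stages(p, av, subjects[s], l12path, nlpath,
                               output_dir,
                               tag = sprintf("maget_atlas%d", a))
      out <- norm_artifact(file.path(output_dir, "labels",
                                     sprintf("%s_from_atlas%d.nii.gz",
                                             sanitize_stem(subjects[s]),
                                             a)))
      add_stage(p, callable_stage(
        "run_resample_stage",
        args = list(input = al, output = out, like = subjects[s],
                    init = fld, labels = TRUE),
        inputs = c(al, subjects[s], fld), outputs = out))
      own_labels[s, a] <- out
    }
  }
  # (C): subject-subject registrations (transform maps t-space -> s-space
  # for register(source = s, target = t))
  cross <- matrix("", n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      cross[s, t] <- chain_link_stages(p, subjects[s], subjects[t],
                                       l12path, nlpath, output_dir,
                                       tag = "maget_x")
    }
  }
  # (D): propagate each subject's own labels to every other subject
  library_of <- lapply(seq_len(n), function(t) as.character(own_labels[t, ]))
  for (t in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == t) next
      for (a in seq_len(m)) {
        out <- norm_artifact(file.path(
          output_dir, "labels",
          sprintf("%s_via_%s_atlas%d.nii.gz",
                  sanitize_stem(subjects[t]),
                  sanitize_stem(subjects[s]), a)))
        add_stage(p, callable_stage(
          "run_resample_stage",
          args = list(input = own_labels[s, a], output = out,
                      like = subjects[t], init = cross[s, t],
                      labels = TRUE),
          inputs = c(own_labels[s, a], subjects[t], cross[s, t]),
          outputs = out))
        library_of[[t]] <- c(library_of[[t]], out)
      }
    }
  }
  # (E): vote
  fused <- character(n)
  for (t in seq_len(n)) {
    out <- norm_artifact(file.path(output_dir, "fused",
                                   paste0(sanitize_stem(subjects[t]),
                                          "_labels.nii.gz")))
    add_stage(p, callable_stage(
      "run_vote_stage",
      args = list(inputs = library_of[[t]], output = out),
      inputs = library_of[[t]], outputs = out))
    fused[t] <- out
  }
  p$artifacts$maget <- list(fused = fused, library = library_of,
                            own_labels = own_labels)
  p
}
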