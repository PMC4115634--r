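# Longitudinal applications: the adjacent-timepoint registration chain
# and the two-level (subject-then-population) design.

# Per-subject scan table from a cohort spec.
subject_table <- function(cohort) {
  stopifnot(!is.null(cohort$subject_of), !is.null(cohort$timepoint_of))
  split(data.frame(file = cohort$inputs,
                   timepoint = cohort$timepoint_of,
                   stringsAsFactors = FALSE),
        cohort$subject_of)
}

# One LSQ12 + nonlinear registration pair between two scans, as stages;
# returns the final field artifact (maps target space to source space).
chain_link_stages <- function(p, source, target, lsq12_path, nlin_path,
                              output_dir, tag) {
  sh <- file_handler(source, output_dir)
  th <- file_handler(target, output_dir)
  aff <- registration_output_name(sh, th, tag = paste0(tag, "_lsq12"),
                                  ext = ".aff.txt")
  add_stage(p, callable_stage(
    "run_linear_register_stage",
    args = list(source = source, target = target, output = aff,
                dof = 12, protocol = lsq12_path),
    inputs = c(source, target), outputs = aff))
  add_xfm(sh, th, aff)
  fld <- registration_output_name(sh, th, tag = paste0(tag, "_nlin"),
                                  ext = ".field.nii.gz")
  add_stage(p, callable_stage(
    "run_nonlinear_register_stage",
    args = list(source = source, target = target, output = fld,
                protocol = nlin_path, init = aff),
    inputs = c(source, target, aff), outputs = fld))
  fld
}

#' Build a longitudinal registration-chain pipeline
#'
#' Within each subject, timepoint `i` is registered (LSQ12 then
#' nonlinear) to timepoint `i + 1`; the stored link transform maps
#' timepoint `i + 1` space back to timepoint `i` space. All scans at the
#' common timepoint are registered together group-wise, and the
#' common-space-to-scan transform for every scan is the concatenation of
#' the group-wise transform with the chain links (inverted links for
#' timepoints after the common one).
#'
#' @param cohort a [cohort_spec()] with `subject_of` and `timepoint_of`.
#' @param output_dir output root.
#' @param common_timepoint timepoint registered group-wise (default: the
#'   earliest timepoint present).
#' @param lsq12_protocol,nlin_protocol protocols.
#' @param generations NLIN generations for the common-timepoint model.
#' @param stats_kernels determinant smoothing fwhms (mm).
#' @param calc_stats compute common-space determinants per scan.
#' @param pairwise_stats also compute determinants of each adjacent-pair
#'   link transform (default off).
#' @param p pipeline to extend.
#' @return pipeline with `p$artifacts$chain`: `links` (per subject, the
#'   link fields oldest-pair first), `common_average`, `scan_chains`
#'   (per scan, the common-to-scan chain part list).
#' @export
build_registration_chain <- function(cohort, output_dir,
                                     common_timepoint = NULL,
                                     lsq12_protocol = NULL,
                                     nlin_protocol = NULL,
                                     generations = 1,
                                     stats_kernels = NULL,
                                     calc_stats = TRUE,
                                     pairwise_stats = FALSE, p = NULL) {
  p <- builder_pipeline(p)
  subs <- subject_table(cohort)
  if (is.null(common_timepoint))
    common_timepoint <- min(cohort$timepoint_of)
  sp <- min(voxel_spacing(read_volume(cohort$inputs[1])))
  if (is.null(lsq12_protocol)) lsq12_protocol <- default_linear_protocol(sp)
  if (is.null(nlin_protocol))
    nlin_protocol <- default_nonlinear_protocol(sp)
  l12path <- materialize_protocol(lsq12_protocol, output_dir, "chain_lsq12")
  nlpath <- materialize_protocol(nlin_protocol, output_dir, "chain_nlin")
  for (s in names(subs)) {
    tab <- subs[[s]]
    if (!(common_timepoint %in% tab$timepoint) && nrow(tab) == 1)
      stop("subject ", s, " has a single scan away from the common ",
           "timepoint and cannot join the chain")
  }
  links <- list()
  for (s in names(subs)) {
    tab <- subs[[s]]
    links[[s]] <- character(max(nrow(tab) - 1, 0))
    for (i in seq_len(nrow(tab) - 1))
      links[[s]][i] <- chain_link_stages(p, tab$file[i], tab$file[i + 1],
                                         l12path, nlpath, output_dir,
                                         tag = sprintf("chain_s%s_t%d",
                                                       s, tab$timepoint[i]))
  }
  common_files <- vapply(names(subs), function(s) {
    tab <- subs[[s]]
    tab$file[match(common_timepoint, tab$timepoint)]
  }, "")
  p <- build_nlin(common_files, protocol = nlin_protocol,
                  generations = generations, output_dir = output_dir,
                  p = p)
  nlin <- p$artifacts$nlin
  scan_chains <- list()
  for (si in seq_along(subs)) {
    s <- names(subs)[si]
    tab <- subs[[s]]
    gw <- nlin$xfms[si]  # common space -> common-timepoint scan
    ci <- match(common_timepoint, tab$timepoint)
    for (r in seq_len(nrow(tab))) {
      key <- sanitize_stem(tab$file[r])
      if (r == ci) {
        scan_chains[[key]] <- list(gw)
      } else if (r < ci) {
        # walk backwards: link i maps t(i+1)-space -> t(i)-space
        scan_chains[[key]] <- c(list(gw),
                                as.list(rev(links[[s]][r:(ci - 1)])))
      } else {
        inv <- character()
        for (i in ci:(r - 1)) {
          invp <- sub("\\.field\\.nii\\.gz$", "_inv.field.nii.gz",
                      links[[s]][i])
          add_stage(p, callable_stage(
            "run_invert_stage",
            args = list(input = links[[s]][i], output = invp,
                        like = tab$file[i]),
            inputs = c(links[[s]][i], tab$file[i]), outputs = invp))
          inv <- c(inv, invp)
        }
        scan_chains[[key]] <- c(list(gw), as.list(inv))
      }
    }
  }
  if (calc_stats) {
    if (is.null(stats_kernels)) stats_kernels <- default_stats_kernels(sp)
    stats_dir <- norm_artifact(file.path(output_dir, "stats"))
    for (key in names(scan_chains)) {
      parts <- scan_chains[[key]]
      add_stage(p, callable_stage(
        "run_stats_stage",
        args = list(chain_parts = parts, like = nlin$average,
                    out_dir = stats_dir, prefix = key,
                    kernels = stats_kernels),
        inputs = c(unlist(parts), nlin$average),
        outputs = norm_artifact(
          file.path(stats_dir, paste0(key, "_full.field.nii.gz")))))
    }
    if (pairwise_stats) {
      for (s in names(subs)) {
        tab <- subs[[s]]
        for (i in seq_along(links[[s]])) {
          key <- paste0("pair_", sanitize_stem(tab$file[i + 1]))
          add_stage(p, callable_stage(
            "run_stats_stage",
            args = list(chain_parts = list(links[[s]][i]),
                        like = tab$file[i + 1], out_dir = stats_dir,
                        prefix = key, kernels = stats_kernels),
            inputs = c(links[[s]][i], tab$file[i + 1]),
            outputs = norm_artifact(
              file.path(stats_dir, paste0(key, "_full.field.nii.gz")))))
        }
      }
    }
  }
  p$artifacts$chain <- list(links = links,
                            common_average = nlin$average,
                            common_xfms = nlin$xfms,
                            scan_chains = scan_chains)
  p
}

#' Build a two-level (subject, then population) pipeline
#'
#' First level: each subject's scans are rigidly aligned and registered
#' group-wise into a subject-specific average (within-subject scale
#' change is biology, so no affine scaling is removed at this level).
#' Second level: the subject averages are registered group-wise (pairwise
#' LSQ12 then NLIN) into a population average. The population-to-scan
#' chain concatenates the population-to-subject-average and
#' subject-average-to-scan transforms.
#'
#' @param cohort a [cohort_spec()] with `subject_of` and `timepoint_of`.
#' @param output_dir output root.
#' @param lsq6_protocol,lsq12_protocol,nlin_protocol protocols.
#' @param generations NLIN generations at both levels.
#' @param p pipeline to extend.
#' @return pipeline with `p$artifacts$two_level`: `subject_averages`,
#'   `population_average`, `scan_chains` (population-to-scan part
#'   lists).
#' @export
build_two_level <- function(cohort, output_dir, lsq6_protocol = NULL,
                            lsq12_protocol = NULL, nlin_protocol = NULL,
                            generations = 1, p = NULL) {
  p <- builder_pipeline(p)
  subs <- subject_table(cohort)
  sp <- min(voxel_spacing(read_volume(cohort$inputs[1])))
  if (is.null(lsq6_protocol)) lsq6_protocol <- default_linear_protocol(sp)
  if (is.null(lsq12_protocol)) lsq12_protocol <- default_linear_protocol(sp)
  if (is.null(nlin_protocol))
    nlin_protocol <- default_nonlinear_protocol(sp)
  subj_avgs <- character(length(subs))
  level1 <- list()
  for (si in seq_along(subs)) {
    s <- names(subs)[si]
    tab <- subs[[s]]
    sdir <- file.path(output_dir, paste0("subject_", s))
    sc <- cohort_spec(tab$file, initial_target = "average",
                      mask_dir = cohort$mask_dir)
    p <- build_lsq6(sc, protocol = lsq6_protocol, output_dir = sdir,
                    p = p)
    l6 <- p$artifacts$lsq6
    p <- build_nlin(l6$resampled, protocol = nlin_protocol,
                    generations = generations, output_dir = sdir, p = p,
                    name = paste0("subject_", s, "_nlin"))
    nl <- p$artifacts$nlin
    subj_avgs[si] <- nl$average
    level1[[s]] <- list(files = tab$file, lsq6 = l6$xfms, nlin = nl$xfms)
  }
  pdir <- file.path(output_dir, "population")
  p <- build_lsq12_pairwise(subj_avgs, protocol = lsq12_protocol,
                            output_dir = pdir, p = p)
  l12 <- p$artifacts$lsq12
  p <- build_nlin(l12$resampled, protocol = nlin_protocol,
                  generations = generations, output_dir = pdir, p = p)
  nl2 <- p$artifacts$nlin
  scan_chains <- list()
  for (si in seq_along(subs)) {
    s <- names(subs)[si]
    lev1 <- level1[[s]]
    # population -> subject average: NLIN field then LSQ12 affine
    pop_part <- list(nl2$xfms[si], l12$xfms[si])
    for (r in seq_along(lev1$files)) {
      key <- sanitize_stem(lev1$files[r])
      scan_chains[[key]] <- c(pop_part,
                              list(lev1$nlin[r], lev1$lsq6[r]))
    }
  }
  p$artifacts$two_level <- list(subject_averages = subj_avgs,
                                population_average = nl2$average,
                                level1 = level1,
                                scan_chains = scan_chains)
  p
}
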