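# Application builders: stage-count accounting, graph structure, and
# small end-to-end executions. Full-size runs live in the acceptance
# suite.

write_inputs <- function(td, n = 3, n_grid = 16, seed = 1) {
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(td, sprintf("in%d.nii.gz", i))
    write_volume(tiny_phantom(n_grid, seed = seed + i)$volume, paths[i])
  }
  paths
}

test_that("LSQ6 builder emits the documented stage count", {
  td <- withr::local_tempdir()
  paths <- write_inputs(td, 3)
  model <- file.path(td, "model.nii.gz")
  write_volume(tiny_phantom(16, seed = 99)$volume, model)
  cohort <- cohort_spec(paths, initial_target = model)
  p <- build_lsq6(cohort, output_dir = file.path(td, "out"))
  L <- 3  # default protocol levels
  # n (L blurs + L registrations + 1 resample) + L shared target blurs
  expect_identical(p$counter, as.integer(3 * (2 * L + 1) + L))
  # rebuilding the same pipeline adds nothing (dedup across builders)
  p2 <- build_lsq6(cohort, output_dir = file.path(td, "out"), p = p)
  expect_identical(p2$counter, p$counter)
  # the graph is acyclic: draining visits every stage
  expect_length(drain_trace(p), p$counter)
})

test_that("pairwise LSQ12 builder registers all ordered pairs", {
  td <- withr::local_tempdir()
  paths <- write_inputs(td, 3)
  p <- build_lsq12_pairwise(paths, output_dir = file.path(td, "out"))
  funs <- vapply(p$stages, function(s) s$fun %||% "", "")
  expect_identical(sum(funs == "run_linear_register_stage"), 6L)
  expect_identical(sum(funs == "run_average_xfm_stage"), 3L)
  expect_identical(sum(funs == "run_resample_stage"), 3L)
  expect_identical(sum(funs == "run_average_stage"), 1L)
  expect_length(drain_trace(p), p$counter)
})

test_that("NLIN and MBM builders wire statistics to the final average", {
  td <- withr::local_tempdir()
  paths <- write_inputs(td, 3)
  cohort <- cohort_spec(paths, initial_target = "average")
  p <- build_mbm(cohort, output_dir = file.path(td, "out"),
                 generations = 2)
  # acyclic
  expect_length(drain_trace(p), p$counter)
  # every stats stage transitively depends on a NLIN registration stage
  funs <- vapply(p$stages, function(s) s$fun %||% "", "")
  stats_idx <- which(funs == "run_stats_stage")
  expect_length(stats_idx, 3L)
  nlin_idx <- which(funs == "run_nonlinear_register_stage")
  ancestors <- function(p, i) {
    seen <- integer(); frontier <- p$pred[[i]]
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(p$pred[frontier])), seen)
    }
    seen
  }
  for (i in stats_idx)
    expect_gt(length(intersect(ancestors(p, i), nlin_idx)), 0)
  # two generations register each input twice
  expect_identical(sum(funs == "run_nonlinear_register_stage"),
                   3L * 2L * 2L)  # inputs x generations x protocol rows
})

test_that("registration chain builder counts links and validates cohorts", {
  td <- withr::local_tempdir()
  paths <- write_inputs(td, 6)
  cohort <- cohort_spec(paths, subject_of = rep(c("a", "b"), each = 3),
                        timepoint_of = rep(1:3, 2))
  p <- build_registration_chain(cohort, output_dir = file.path(td, "out"),
                                calc_stats = FALSE)
  # 2 subjects x 2 consecutive pairs, one LSQ12 + one NLIN stage each
  funs <- vapply(p$stages, function(s) s$fun %||% "", "")
  expect_identical(sum(funs == "run_linear_register_stage"), 4L)
  links <- p$artifacts$chain$links
  expect_identical(lengths(links), c(a = 2L, b = 2L))
  # scan at the common timepoint needs no chain links beyond groupwise
  sc <- p$artifacts$chain$scan_chains
  expect_length(sc[[morphopipe:::sanitize_stem(paths[1])]], 1L)
  expect_length(sc[[morphopipe:::sanitize_stem(paths[3])]], 3L)
  expect_length(drain_trace(p), p$counter)
  # a subject whose single scan misses the common timepoint is rejected
  bad <- cohort_spec(paths[c(1, 2, 3, 5)],
                     subject_of = c("a", "a", "a", "b"),
                     timepoint_of = c(1, 2, 3, 2))
  expect_error(build_registration_chain(bad,
                                        output_dir = file.path(td, "o2")),
               "common")
})

test_that("two-level builder keeps first-level subgraphs disjoint", {
  td <- withr::local_tempdir()
  paths <- write_inputs(td, 4)
  cohort <- cohort_spec(paths, subject_of = rep(c("a", "b"), each = 2),
                        timepoint_of = rep(1:2, 2))
  p <- build_two_level(cohort, output_dir = file.path(td, "out"))
  expect_length(drain_trace(p), p$counter)
  # population -> scan chain is population->subject then subject->scan
  sc <- p$artifacts$two_level$scan_chains
  expect_length(sc, 4L)
  for (parts in sc) expect_length(parts, 4L)
  # level-1 subgraphs of different subjects share no artifacts (the
  # /subject_<s>/ directories hold each subject's own groupwise run)
  arts_a <- unlist(lapply(p$stages, function(s)
    grep("/subject_a/", c(s$inputs, s$outputs), value = TRUE)))
  arts_b <- unlist(lapply(p$stages, function(s)
    grep("/subject_b/", c(s$inputs, s$outputs), value = TRUE)))
  expect_gt(length(arts_a), 0)
  expect_length(intersect(arts_a, arts_b), 0L)
})

test_that("MAGeT builder creates an m x n library per subject", {
  td <- withr::local_tempdir()
  subj <- write_inputs(td, 3)
  atl <- list(list(volume = file.path(td, "atlas.nii.gz"),
                   labels = file.path(td, "atlas_lab.nii.gz")),
              list(volume = file.path(td, "atlas2.nii.gz"),
                   labels = file.path(td, "atlas2_lab.nii.gz")))
  ph <- tiny_phantom(16, seed = 50)
  write_volume(ph$volume, atl[[1]]$volume)
  write_volume(ph$labels, atl[[1]]$labels)
  ph2 <- tiny_phantom(16, seed = 51)
  write_volume(ph2$volume, atl[[2]]$volume)
  write_volume(ph2$labels, atl[[2]]$labels)
  p <- build_maget(subj, atl, output_dir = file.path(td, "out"))
  lib <- p$artifacts$maget$library
  expect_identical(lengths(lib), rep(2L * 3L, 3))  # m x n each
  funs <- vapply(p$stages, function(s) s$fun %||% "", "")
  expect_identical(sum(funs == "run_vote_stage"), 3L)
  # atlas->subject (m x n) plus subject-subject (n(n-1)) registrations
  expect_identical(sum(funs == "run_nonlinear_register_stage"),
                   2L * 3L + 3L * 2L)
  expect_length(drain_trace(p), p$counter)
})

test_that("a degenerate MAGeT run (atlas == only subject) is exact", {
  td <- withr::local_tempdir()
  ph <- tiny_phantom(20, seed = 52)
  av <- file.path(td, "atlas.nii.gz"); al <- file.path(td, "lab.nii.gz")
  write_volume(ph$volume, av); write_volume(ph$labels, al)
  p <- build_maget(av, list(list(volume = av, labels = al)),
                   output_dir = file.path(td, "out"),
                   nlin_protocol = default_nonlinear_protocol(
                     1, iterations = c(10, 5)))
  rep <- execute(p, executor_spec())
  expect_identical(rep$failed, 0L)
  fused <- read_volume(p$artifacts$maget$fused[1])
  expect_identical(fused$data, ph$labels$data)
})

test_that("cohort CSV parsing orders scans and validates timepoints", {
  td <- withr::local_tempdir()
  paths <- write_inputs(td, 4)
  csv <- file.path(td, "cohort.csv")
  write.csv(data.frame(file = paths[c(2, 1, 4, 3)],
                       subject = c("a", "a", "b", "b"),
                       timepoint = c(2, 1, 2, 1)),
            csv, row.names = FALSE)
  cs <- read_cohort_csv(csv)
  expect_identical(basename(cs$inputs),
                   basename(morphopipe:::norm_artifact(paths)))
  expect_error(cohort_spec(paths, subject_of = rep("a", 4),
                           timepoint_of = c(1, 2, 2, 3)),
               "increasing")
  expect_error(cohort_spec(paths[1]), "two inputs")
})
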