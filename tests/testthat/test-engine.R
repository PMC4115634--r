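# Pipeline engine: dependency inference, duplicate elimination,
# scheduling, failure propagation, checkpoint/restart, execution.

test_that("dependencies are inferred from artifact footprints", {
  td <- withr::local_tempdir()
  p <- pipeline()
  a <- command_stage("true", outputs = file.path(td, "f1"))
  b <- command_stage("true", inputs = file.path(td, "f1"),
                     outputs = file.path(td, "f2"))
  ia <- add_stage(p, a)
  ib <- add_stage(p, b)
  expect_identical(p$succ[[ia]], ib)
  expect_identical(p$pred[[ib]], ia)
  # consumer with no producer is a graph head, runnable immediately
  c <- command_stage("true", inputs = file.path(td, "f9"),
                     outputs = file.path(td, "f3"))
  ic <- add_stage(p, c)
  expect_length(p$pred[[ic]], 0)
  expect_true(ic %in% p$queue)
  # a producer added after its consumer still creates the edge
  d <- command_stage(c("true", "x"), outputs = file.path(td, "f9"))
  id <- add_stage(p, d)
  expect_identical(p$pred[[ic]], id)
})

test_that("duplicate stages are inserted once and conflicts rejected", {
  td <- withr::local_tempdir()
  p <- pipeline()
  s <- command_stage("true", outputs = file.path(td, "out"))
  i1 <- add_stage(p, s)
  i2 <- add_stage(p, command_stage("true", outputs = file.path(td, "out")))
  expect_identical(i1, i2)
  expect_identical(p$counter, 1L)
  # same output from different work -> ill-formed pipeline
  expect_error(add_stage(p, command_stage(c("touch", "x"),
                                          outputs = file.path(td, "out"))),
               "conflict")
})

test_that("merging pipelines dedups across the union", {
  td <- withr::local_tempdir()
  a <- command_stage("true", outputs = file.path(td, "a"))
  b <- command_stage("true", inputs = file.path(td, "a"),
                     outputs = file.path(td, "b"))
  p <- pipeline(); add_stage(p, a)
  q <- pipeline(); add_stage(q, a); add_stage(q, b)
  add_pipeline(p, q)
  expect_identical(p$counter, 2L)
  # cross-pipeline edge exists and matches the from-scratch edge oracle
  expect_identical(edges_oracle(p$stages), matrix(c(1L, 2L), 1))
  # merging an empty pipeline changes nothing
  add_pipeline(p, pipeline())
  expect_identical(p$counter, 2L)
})

test_that("insertion order does not change the deduped graph", {
  td <- withr::local_tempdir()
  stages <- random_dag_stages(td, 20, p_edge = 0.15, seed = 9)
  fp <- function(p) sort(vapply(p$stages, `[[`, "", "fingerprint"))
  canon_edges <- function(p) {
    e <- edges_oracle(p$stages)
    fps <- vapply(p$stages, `[[`, "", "fingerprint")
    sort(paste(fps[e[, 1]], fps[e[, 2]]))
  }
  p1 <- pipeline()
  for (s in stages) add_stage(p1, s)
  set.seed(1)
  for (rep in 1:3) {
    p2 <- pipeline()
    for (s in sample(stages)) add_stage(p2, s)
    expect_identical(fp(p1), fp(p2))
    expect_identical(canon_edges(p1), canon_edges(p2))
  }
})

test_that("scheduling respects the dependency partial order", {
  td <- withr::local_tempdir()
  # chain: only the head is runnable, completion order is chain order
  p <- pipeline()
  for (s in random_dag_stages(td, 5, p_edge = 2, seed = 1)) # p>1: full chain
    add_stage(p, s)
  expect_identical(drain_trace(p), 1:5)
  # random DAGs: every emitted order is a linear extension (edge oracle)
  for (seed in 1:5) {
    td2 <- withr::local_tempdir()
    stages <- random_dag_stages(td2, 40, p_edge = 0.08, seed = seed)
    p <- pipeline()
    for (s in stages) add_stage(p, s)
    trace <- drain_trace(p)
    expect_setequal(trace, seq_along(stages))
    pos <- match(seq_along(stages), trace)
    e <- edges_oracle(stages)
    if (nrow(e)) expect_true(all(pos[e[, 1]] < pos[e[, 2]]))
  }
})

test_that("failure blocks exactly the transitive dependents", {
  td <- withr::local_tempdir()
  f <- function(n) file.path(td, n)
  # A finished, B failed, C depends on B, D depends on A -> D runs, C never
  p <- pipeline()
  add_stage(p, command_stage(c("true", "A"), outputs = f("a")))
  add_stage(p, command_stage(c("true", "B"), outputs = f("b")))
  add_stage(p, command_stage(c("true", "C"), inputs = f("b"),
                             outputs = f("c")))
  add_stage(p, command_stage(c("true", "D"), inputs = f("a"),
                             outputs = f("d")))
  trace <- drain_trace(p, fail = 2L)
  expect_true(4L %in% trace)
  expect_false(3L %in% trace)
  expect_identical(as.integer(pipeline_status_counts(p)[c("failed",
                                                          "blocked")]),
                   c(1L, 1L))
  # diamond: one failed parent blocks the join even if the other finished
  p2 <- pipeline()
  add_stage(p2, command_stage(c("true", "A"), outputs = f("da")))
  add_stage(p2, command_stage(c("true", "B"), inputs = f("da"),
                              outputs = f("db")))
  add_stage(p2, command_stage(c("true", "C"), inputs = f("da"),
                              outputs = f("dc")))
  add_stage(p2, command_stage(c("true", "D"),
                              inputs = c(f("db"), f("dc")),
                              outputs = f("dd")))
  drain_trace(p2, fail = 2L)
  expect_identical(p2$status[4], "blocked")
  # failed chain: 1 failed, rest blocked, none runnable
  p3 <- pipeline()
  for (s in random_dag_stages(td, 3, p_edge = 2, seed = 3))
    add_stage(p3, s)
  drain_trace(p3, fail = 1L)
  st <- pipeline_status_counts(p3)
  expect_identical(as.integer(st[c("failed", "blocked")]), c(1L, 2L))
  expect_null(next_runnable(p3))
  # status partition always sums to the stage count
  expect_identical(as.integer(sum(st)), 3L)
})

test_that("completing a non-running stage is a state error", {
  td <- withr::local_tempdir()
  p <- pipeline()
  add_stage(p, command_stage("true", outputs = file.path(td, "x")))
  expect_error(complete_stage(p, 1L, "finished"), "not 'running'")
})

test_that("checkpoint and restore round-trip the pipeline state", {
  td <- withr::local_tempdir()
  stages <- random_dag_stages(td, 12, p_edge = 0.2, seed = 4)
  p <- pipeline()
  for (s in stages) add_stage(p, s)
  ck <- file.path(td, "ck.json")
  # untouched round trip: graph, fingerprints, statuses all equal
  checkpoint(p, ck)
  q <- restore(ck)
  expect_identical(vapply(q$stages, `[[`, "", "fingerprint"),
                   vapply(p$stages, `[[`, "", "fingerprint"))
  expect_identical(q$status, p$status)
  expect_identical(lapply(q$succ, sort), lapply(p$succ, sort))
  # finish 3 stages, checkpoint, restore: 3 finished, rest pending
  for (k in 1:3) complete_stage(p, next_runnable(p), "finished")
  checkpoint(p, ck)
  q2 <- restore(ck)
  expect_identical(sum(q2$status == "finished"), 3L)
  expect_identical(sum(q2$status == "pending"), 9L)
  # the restored run executes exactly the stages pending at checkpoint
  pending_at_ck <- which(q2$status == "pending")
  expect_setequal(drain_trace(q2), pending_at_ck)
  expect_error(restore(file.path(td, "nothere.json")), "checkpoint")
})

test_that("kill-and-restore at random boundaries re-runs the remainder", {
  td <- withr::local_tempdir()
  stages <- random_dag_stages(td, 30, p_edge = 0.1, seed = 5)
  set.seed(11)
  for (rep in 1:4) {
    p <- pipeline()
    for (s in stages) add_stage(p, s)
    k <- sample(0:29, 1)
    for (i in seq_len(k)) complete_stage(p, next_runnable(p), "finished")
    ck <- file.path(td, sprintf("ck%d.json", rep))
    checkpoint(p, ck)
    q <- restore(ck)
    finished_before <- which(p$status == "finished")
    trace <- drain_trace(q)
    expect_setequal(trace, setdiff(1:30, finished_before))
    expect_true(all(q$status == "finished"))
  }
})

test_that("execution runs commands, captures logs, honors resources", {
  td <- withr::local_tempdir()
  p <- pipeline()
  outs <- file.path(td, paste0("t", 1:6))
  for (o in outs)
    add_stage(p, command_stage(c("touch", o), outputs = o,
                               log_path = paste0(o, ".log")))
  rep <- execute(p, executor_spec(threads_per_executor = 4))
  expect_identical(rep$finished, 6L)
  expect_identical(rep$failed, 0L)
  expect_true(all(file.exists(outs)))
  expect_true(all(file.exists(paste0(outs, ".log"))))
  # nonzero exit -> stage failed, engine keeps going
  p2 <- pipeline()
  add_stage(p2, command_stage("false", outputs = file.path(td, "bad")))
  add_stage(p2, command_stage(c("touch", file.path(td, "ok")),
                              outputs = file.path(td, "ok")))
  rep2 <- execute(p2, executor_spec())
  expect_identical(rep2$failed, 1L)
  expect_identical(rep2$finished, 1L)
  # a stage over every executor budget is reported unrunnable, not run
  p3 <- pipeline()
  add_stage(p3, command_stage("true", outputs = file.path(td, "huge"),
                              mem_hint = 64))
  add_stage(p3, command_stage("true", inputs = file.path(td, "huge"),
                              outputs = file.path(td, "child")))
  rep3 <- execute(p3, executor_spec(mem_per_executor = 4))
  expect_identical(rep3$unrunnable, 1L)
  expect_identical(rep3$finished, 0L)
})

test_that("callable stages execute package functions by name", {
  td <- withr::local_tempdir()
  src <- file.path(td, "in.nii.gz")
  v <- tiny_phantom(16)$volume
  write_volume(v, src)
  out <- file.path(td, "blur.nii.gz")
  p <- pipeline()
  add_stage(p, callable_stage("run_blur_stage",
                              args = list(input = src, output = out,
                                          fwhm = 2),
                              inputs = src, outputs = out))
  rep <- execute(p, executor_spec())
  expect_identical(rep$finished, 1L)
  expect_equal(read_volume(out)$data,
               gaussian_blur(v, 2)$data, tolerance = 1e-12)
  # an erroring callable marks the stage failed with the error logged
  p2 <- pipeline()
  add_stage(p2, callable_stage("run_blur_stage",
                               args = list(input = file.path(td, "no"),
                                           output = out, fwhm = 2),
                               outputs = file.path(td, "x2")))
  rep2 <- execute(p2, executor_spec())
  expect_identical(rep2$failed, 1L)
})

test_that("stage invariants are enforced", {
  td <- withr::local_tempdir()
  f <- file.path(td, "same")
  expect_error(command_stage("true", inputs = f, outputs = f), "disjoint")
  # fingerprint is a pure function of the work definition, not resources
  s1 <- command_stage(c("prog", "-x"), outputs = file.path(td, "o"),
                      mem_hint = 1)
  s2 <- command_stage(c("prog", "-x"), outputs = file.path(td, "o"),
                      mem_hint = 16)
  expect_identical(s1$fingerprint, s2$fingerprint)
  s3 <- command_stage(c("prog", "-y"), outputs = file.path(td, "o"))
  expect_false(identical(s1$fingerprint, s3$fingerprint))
})
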