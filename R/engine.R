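# Application-independent pipeline engine.
#
# A pipeline is a directed acyclic graph over stages, inferred from the
# artifact (file) footprints each stage declares: an edge runs from the
# producer of an artifact to every consumer of it. Stages with identical
# fingerprints are inserted once (duplicate elimination), the graph is
# checkpointed to a versioned JSON record after every completed stage,
# and execution polls a runnable queue under per-executor resource
# budgets, shutting down once no more stages can run.

CHECKPOINT_FORMAT <- "morphopipe-pipeline"
CHECKPOINT_VERSION <- 1L

norm_artifact <- function(paths) {
  if (length(paths) == 0) return(character())
  vapply(paths, function(p) normalizePath(p, winslash = "/",
                                          mustWork = FALSE), "")
}

# Canonicalize callable arguments so fingerprints and the JSON checkpoint
# agree: integers widen to doubles, lists recurse, everything else must be
# an atomic vector or NULL.
canonical_args <- function(args) {
  lapply(args, function(a) {
    if (is.null(a)) NULL
    else if (is.integer(a)) as.numeric(a)
    else if (is.atomic(a)) a
    else if (is.list(a)) canonical_args(a)
    else stop("callable stage arguments must be atomic values or lists ",
              "of them (got ", class(a)[1], "); pass large objects by ",
              "file path instead")
  })
}

stage_fingerprint <- function(kind, work, inputs, outputs) {
  digest::digest(list(kind = kind, work = work,
                      inputs = sort(inputs), outputs = sort(outputs)),
                 algo = "md5")
}

validate_stage <- function(s) {
  if (length(intersect(s$inputs, s$outputs)) > 0)
    stop("stage inputs and outputs must be disjoint")
  invisible(s)
}

#' Create a command stage
#'
#' One unit of work running a single command-line executable.
#'
#' @param argv character vector: the executable and its arguments.
#' @param inputs,outputs artifact identifiers (file paths) the command
#'   reads/writes; normalized to absolute paths. Dependencies between
#'   stages are inferred from these footprints.
#' @param mem_hint,proc_hint resource hints (GB / threads) checked against
#'   an executor's budget before the stage is claimed.
#' @param log_path log file; defaults to `<first output>.log`.
#' @return a `pp_stage` list.
#' @export
command_stage <- function(argv, inputs = character(), outputs = character(),
                          mem_hint = 1, proc_hint = 1, log_path = NULL) {
  stopifnot(length(argv) >= 1)
  inputs <- norm_artifact(inputs)
  outputs <- norm_artifact(outputs)
  if (is.null(log_path))
    log_path <- if (length(outputs)) paste0(sort(outputs)[1], ".log")
                else tempfile(fileext = ".log")
  s <- structure(list(kind = "command", argv = as.character(argv),
                      fun = NULL, args = NULL,
                      inputs = inputs, outputs = outputs,
                      mem_hint = mem_hint, proc_hint = proc_hint,
                      log_path = log_path,
                      fingerprint = stage_fingerprint("command",
                                                      as.character(argv),
                                                      inputs, outputs)),
                 class = "pp_stage")
  validate_stage(s)
}

#' Create a callable stage
#'
#' One unit of work running an R function, referenced by name so the
#' stage (and the whole pipeline) is serializable to a checkpoint.
#'
#' @param fun function name (character); resolved in the package
#'   namespace, then the global environment, at execution time.
#' @param args named list of arguments (atomic values, or lists of them;
#'   pass large objects by file path).
#' @inheritParams command_stage
#' @return a `pp_stage` list.
#' @export
callable_stage <- function(fun, args = list(), inputs = character(),
                           outputs = character(), mem_hint = 1,
                           proc_hint = 1, log_path = NULL) {
  stopifnot(is.character(fun), length(fun) == 1)
  args <- canonical_args(args)
  inputs <- norm_artifact(inputs)
  outputs <- norm_artifact(outputs)
  if (is.null(log_path))
    log_path <- if (length(outputs)) paste0(sort(outputs)[1], ".log")
                else tempfile(fileext = ".log")
  s <- structure(list(kind = "callable", argv = NULL,
                      fun = fun, args = args,
                      inputs = inputs, outputs = outputs,
                      mem_hint = mem_hint, proc_hint = proc_hint,
                      log_path = log_path,
                      fingerprint = stage_fingerprint("callable",
                                                      list(fun, args),
                                                      inputs, outputs)),
                 class = "pp_stage")
  validate_stage(s)
}

#' @export
print.pp_stage <- function(x, ...) {
  cat("<pp_stage ", x$kind, "> ",
      if (x$kind == "command") paste(x$argv, collapse = " ") else x$fun,
      "\n  in:  ", length(x$inputs), " artifact(s)",
      "\n  out: ", length(x$outputs), " artifact(s)\n", sep = "")
  invisible(x)
}

#' Create an empty pipeline
#'
#' @param backup_path optional checkpoint file; when set, the pipeline
#'   state is re-written there after every completed stage.
#' @return a `pp_pipeline` environment.
#' @export
pipeline <- function(backup_path = NULL) {
  p <- new.env(parent = emptyenv())
  p$stages <- list()
  p$status <- character()
  p$pred <- list()
  p$succ <- list()
  p$by_fp <- new.env(parent = emptyenv())
  p$by_output <- new.env(parent = emptyenv())
  p$by_input <- new.env(parent = emptyenv())
  p$counter <- 0L
  p$npred_unfinished <- integer()
  p$queue <- integer()
  p$backup_path <- backup_path
  class(p) <- "pp_pipeline"
  p
}

#' @export
print.pp_pipeline <- function(x, ...) {
  st <- pipeline_status_counts(x)
  cat("<pp_pipeline> ", x$counter, " stage(s): ",
      paste(names(st), st, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Status counts of a pipeline
#' @param p a `pp_pipeline`.
#' @return named integer vector over
#'   pending/running/finished/failed/blocked.
#' @export
pipeline_status_counts <- function(p) {
  lv <- c("pending", "running", "finished", "failed", "blocked")
  table(factor(p$status, levels = lv))
}

push_runnable <- function(p, idx) {
  p$queue <- c(p$queue, idx)
}

#' Add a stage to a pipeline
#'
#' Dependencies are inferred from artifact footprints: an edge is added
#' from every registered producer of the stage's inputs, and to every
#' existing consumer of its outputs. A stage whose fingerprint is already
#' present is skipped (the existing index is returned and the pipeline is
#' left unchanged).
#'
#' @param p a `pp_pipeline`.
#' @param s a `pp_stage`.
#' @return the stage's index, invisibly.
#' @export
add_stage <- function(p, s) {
  stopifnot(inherits(p, "pp_pipeline"), inherits(s, "pp_stage"))
  fp <- s$fingerprint
  existing <- p$by_fp[[fp]]
  if (!is.null(existing)) return(invisible(existing))
  for (o in s$outputs) {
    prod <- p$by_output[[o]]
    if (!is.null(prod))
      stop("output conflict: artifact '", o, "' already produced by ",
           "stage ", prod, " with a different fingerprint")
  }
  idx <- p$counter + 1L
  p$counter <- idx
  p$stages[[idx]] <- s
  p$status[idx] <- "pending"
  preds <- integer()
  for (i in s$inputs) {
    prod <- p$by_output[[i]]
    if (!is.null(prod)) preds <- c(preds, prod)
    p$by_input[[i]] <- c(p$by_input[[i]], idx)
  }
  preds <- unique(preds)
  succs <- integer()
  for (o in s$outputs) {
    p$by_output[[o]] <- idx
    cons <- p$by_input[[o]]
    if (!is.null(cons)) succs <- c(succs, cons)
  }
  succs <- setdiff(unique(succs), idx)
  p$pred[[idx]] <- preds
  p$succ[[idx]] <- succs
  for (pr in preds) p$succ[[pr]] <- unique(c(p$succ[[pr]], idx))
  p$npred_unfinished[idx] <-
    sum(p$status[preds] != "finished")
  # a late-added producer turns existing consumers into dependents
  for (su in succs) {
    p$pred[[su]] <- unique(c(p$pred[[su]], idx))
    p$npred_unfinished[su] <- p$npred_unfinished[su] + 1L
  }
  p$by_fp[[fp]] <- idx
  if (p$npred_unfinished[idx] == 0L) push_runnable(p, idx)
  invisible(idx)
}

#' Merge one pipeline into another
#'
#' Equivalent to adding each of `q`'s stages to `p` in order; duplicate
#' elimination applies across the merged whole.
#'
#' @param p destination `pp_pipeline` (modified in place).
#' @param q source `pp_pipeline`.
#' @return `p`, invisibly.
#' @export
add_pipeline <- function(p, q) {
  stopifnot(inherits(q, "pp_pipeline"))
  for (s in q$stages) add_stage(p, s)
  invisible(p)
}

#' Next runnable stage
#'
#' Returns a pending stage whose graph predecessors are all finished,
#' marking it running; `NULL` if none exists. Stages with a failed
#' ancestor are never returned.
#'
#' @param p a `pp_pipeline`.
#' @param exclude stage indices to skip (used by the executor loop for
#'   stages no executor can ever claim).
#' @return the claimed `pp_stage` (with its index in attribute
#'   `"index"`), or `NULL`.
#' @export
next_runnable <- function(p, exclude = integer()) {
  parked <- integer()
  res <- NULL
  while (length(p$queue) > 0) {
    idx <- p$queue[1]
    p$queue <- p$queue[-1]
    if (p$status[idx] != "pending") next  # stale entry
    if (idx %in% exclude) { parked <- c(parked, idx); next }
    p$status[idx] <- "running"
    res <- p$stages[[idx]]
    attr(res, "index") <- idx
    break
  }
  p$queue <- c(parked, p$queue)
  res
}

stage_index <- function(p, s) {
  if (is.numeric(s)) return(as.integer(s))
  idx <- attr(s, "index")
  if (is.null(idx)) idx <- p$by_fp[[s$fingerprint]]
  if (is.null(idx)) stop("stage not found in pipeline")
  idx
}

#' Record completion of a running stage
#'
#' On `finished`, successors whose predecessors are now all finished
#' become runnable; on `failed`, every transitive dependent is permanently
#' blocked. Writes a checkpoint when the pipeline has a `backup_path`.
#'
#' @param p a `pp_pipeline`.
#' @param s the stage (or its index); must currently be running.
#' @param outcome `"finished"` or `"failed"`.
#' @return `p`, invisibly.
#' @export
complete_stage <- function(p, s, outcome = c("finished", "failed")) {
  outcome <- match.arg(outcome)
  idx <- stage_index(p, s)
  if (p$status[idx] != "running")
    stop("cannot complete stage ", idx, ": status is '", p$status[idx],
         "', not 'running'")
  p$status[idx] <- outcome
  if (outcome == "finished") {
    for (su in p$succ[[idx]]) {
      p$npred_unfinished[su] <- p$npred_unfinished[su] - 1L
      if (p$npred_unfinished[su] == 0L && p$status[su] == "pending")
        push_runnable(p, su)
    }
  } else {
    frontier <- p$succ[[idx]]
    while (length(frontier) > 0) {
      nxt <- integer()
      for (su in frontier) {
        if (p$status[su] %in% c("pending", "blocked")) {
          if (p$status[su] == "pending") {
            p$status[su] <- "blocked"
            nxt <- c(nxt, p$succ[[su]])
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  if (!is.null(p$backup_path)) checkpoint(p, p$backup_path)
  invisible(p)
}

#' Checkpoint a pipeline
#'
#' Serializes the pipeline to a versioned JSON record holding the
#' directed graph, the stage array, the stage counter, the fingerprint
#' lookup, the output-artifact lookup, and the status array.
#'
#' @param p a `pp_pipeline`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
checkpoint <- function(p, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  edges <- do.call(rbind, c(list(matrix(integer(), 0, 2)),
                            lapply(seq_along(p$succ), function(i) {
                              if (length(p$succ[[i]]))
                                cbind(i, p$succ[[i]])
                            })))
  stages <- lapply(p$stages, function(s) {
    list(kind = s$kind, argv = s$argv, fun = s$fun, args = s$args,
         inputs = as.list(s$inputs), outputs = as.list(s$outputs),
         mem_hint = s$mem_hint, proc_hint = s$proc_hint,
         log_path = s$log_path, fingerprint = s$fingerprint)
  })
  by_output <- as.list(p$by_output)
  by_fp <- as.list(p$by_fp)
  rec <- list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
              counter = p$counter,
              statuses = as.list(p$status),
              edges_from = as.list(edges[, 1]),
              edges_to = as.list(edges[, 2]),
              by_fingerprint = by_fp,
              by_output = by_output,
              stages = stages)
  ok <- tryCatch({
    jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
    TRUE
  }, error = function(e) stop("cannot write checkpoint to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Restore a pipeline from a checkpoint
#'
#' Rebuilds graph heads and edges by iterating the saved graph. Finished
#' stages keep their status (and are never re-executed); running, failed
#' and blocked stages return to pending so the unfinished remainder can
#' be re-run.
#'
#' @param path checkpoint file written by [checkpoint()].
#' @param backup_path optional new checkpoint path for the restored
#'   pipeline (defaults to `path`).
#' @return a `pp_pipeline`.
#' @export
restore <- function(path, backup_path = path) {
  if (!file.exists(path)) stop("no checkpoint at ", path)
  rec <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("corrupt checkpoint: ",
                                           conditionMessage(e)))
  if (!identical(rec$format, CHECKPOINT_FORMAT))
    stop("not a pipeline checkpoint: ", path)
  p <- pipeline(backup_path = backup_path)
  n <- rec$counter
  p$counter <- as.integer(n)
  p$stages <- vector("list", n)
  p$status <- character(n)
  p$pred <- rep(list(integer()), n)
  p$succ <- rep(list(integer()), n)
  for (i in seq_len(n)) {
    sr <- rec$stages[[i]]
    s <- structure(list(kind = sr$kind,
                        argv = if (!is.null(sr$argv))
                          unlist(sr$argv, use.names = FALSE),
                        fun = sr$fun,
                        args = restore_args(sr$args),
                        inputs = unlist(sr$inputs) %||% character(),
                        outputs = unlist(sr$outputs) %||% character(),
                        mem_hint = sr$mem_hint,
                        proc_hint = sr$proc_hint,
                        log_path = sr$log_path,
                        fingerprint = sr$fingerprint),
                   class = "pp_stage")
    p$stages[[i]] <- s
    st <- rec$statuses[[i]]
    p$status[i] <- if (identical(st, "finished")) "finished" else "pending"
    p$by_fp[[s$fingerprint]] <- i
    for (o in s$outputs) p$by_output[[o]] <- i
    for (inp in s$inputs) p$by_input[[inp]] <- c(p$by_input[[inp]], i)
  }
  ef <- unlist(rec$edges_from); et <- unlist(rec$edges_to)
  for (e in seq_along(ef)) {
    a <- ef[e]; b <- et[e]
    p$succ[[a]] <- c(p$succ[[a]], b)
    p$pred[[b]] <- c(p$pred[[b]], a)
  }
  p$npred_unfinished <- vapply(seq_len(n), function(i)
    sum(p$status[p$pred[[i]]] != "finished"), integer(1))
  for (i in seq_len(n))
    if (p$status[i] == "pending" && p$npred_unfinished[i] == 0L)
      push_runnable(p, i)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON round-trip turns lists of scalars into nested lists; collapse
# unnamed scalar lists back to atomic vectors.
restore_args <- function(a) {
  if (is.null(a)) return(list())
  simplify <- function(x) {
    if (is.list(x)) {
      if (length(x) > 0 && is.null(names(x)) &&
          all(vapply(x, function(e) is.atomic(e) && length(e) == 1 &&
                       !is.null(e), TRUE)))
        return(unlist(x, use.names = FALSE))
      return(lapply(x, simplify))
    }
    x
  }
  simplify(a)
}

#' Executor specification
#'
#' @param n_executors number of executors in the worker pool.
#' @param threads_per_executor thread budget of each executor.
#' @param mem_per_executor memory budget of each executor (GB).
#' @param poll_interval sleep between polls when nothing can be claimed
#'   (seconds).
#' @return an `executor_spec` list.
#' @export
executor_spec <- function(n_executors = 1, threads_per_executor = 1,
                          mem_per_executor = 4, poll_interval = 0.05) {
  stopifnot(n_executors > 0, threads_per_executor > 0,
            mem_per_executor > 0, poll_interval > 0)
  structure(list(n_executors = n_executors,
                 threads_per_executor = threads_per_executor,
                 mem_per_executor = mem_per_executor,
                 poll_interval = poll_interval),
            class = "executor_spec")
}

run_stage_work <- function(s) {
  dir.create(dirname(s$log_path), recursive = TRUE, showWarnings = FALSE)
  con <- file(s$log_path, open = "at")
  on.exit(close(con), add = TRUE)
  t0 <- Sys.time()
  if (s$kind == "command") {
    out <- tryCatch(
      suppressWarnings(system2(s$argv[1], s$argv[-1], stdout = TRUE,
                               stderr = TRUE)),
      error = function(e) structure(conditionMessage(e), status = 127L))
    code <- attr(out, "status") %||% 0L
    writeLines(c(paste("$", paste(s$argv, collapse = " ")),
                 as.character(out),
                 sprintf("[exit %d after %.2fs]", code,
                         as.numeric(Sys.time() - t0, units = "secs"))),
               con)
    if (code == 0L) "finished" else "failed"
  } else {
    fn <- tryCatch(
      get(s$fun, envir = asNamespace("morphopipe")),
      error = function(e) tryCatch(get(s$fun, envir = globalenv()),
                                   error = function(e2) NULL))
    if (is.null(fn)) {
      writeLines(paste("cannot resolve callable:", s$fun), con)
      return("failed")
    }
    res <- tryCatch({
      txt <- utils::capture.output(
        withCallingHandlers(do.call(fn, s$args),
                            warning = function(w) {
                              writeLines(paste("WARN:",
                                               conditionMessage(w)), con)
                              invokeRestart("muffleWarning")
                            }))
      writeLines(c(paste("callable:", s$fun), txt,
                   sprintf("[ok after %.2fs]",
                           as.numeric(Sys.time() - t0, units = "secs"))),
                 con)
      "finished"
    }, error = function(e) {
      writeLines(c(paste("callable:", s$fun),
                   paste("ERROR:", conditionMessage(e))), con)
      "failed"
    })
    res
  }
}

#' Execute a pipeline
#'
#' Workers repeatedly poll for the next runnable stage and claim it only
#' if an executor's memory and thread budget covers the stage's hints;
#' stages no executor can ever satisfy are reported as unrunnable and
#' skipped. Execution terminates when all stages have finished, or when
#' failures exist and no further stage can run. Each stage's output and
#' error text is appended to its log file. Stages run one at a time
#' within the calling R process; the claim/release accounting follows the
#' per-executor budgets.
#'
#' @param p a `pp_pipeline`.
#' @param spec an [executor_spec()].
#' @return run report: list with `finished`, `failed`, `blocked`,
#'   `pending` counts, `unrunnable` (stage indices no executor could
#'   claim), `trace` (stage indices in completion order), and `logs`.
#' @export
execute <- function(p, spec = executor_spec()) {
  stopifnot(inherits(p, "pp_pipeline"), inherits(spec, "executor_spec"))
  unrunnable <- integer()
  trace <- integer()
  fits <- function(s) (s$mem_hint <= spec$mem_per_executor &&
                         s$proc_hint <= spec$threads_per_executor)
  repeat {
    s <- next_runnable(p, exclude = unrunnable)
    if (is.null(s)) break  # nothing runnable: done, or shutdown on failure
    idx <- attr(s, "index")
    if (!fits(s)) {
      # no executor budget can ever satisfy this stage
      p$status[idx] <- "pending"
      unrunnable <- c(unrunnable, idx)
      next
    }
    outcome <- run_stage_work(s)
    trace <- c(trace, idx)
    complete_stage(p, idx, outcome)
  }
  st <- pipeline_status_counts(p)
  list(finished = unname(st["finished"]), failed = unname(st["failed"]),
       blocked = unname(st["blocked"]),
       pending = unname(st["pending"]) ,
       unrunnable = unrunnable, trace = trace,
       logs = vapply(p$stages, `[[`, "", "log_path"))
}
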