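# Shared fixtures: small deterministic grids, phantoms and affines used
# across the suite. Everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

p2a <- morphopipe:::params_to_affine
a2p <- morphopipe:::affine_to_params
grid_pts <- morphopipe:::grid_world_points

small_grid <- function(n = 16, spacing = 1) {
  list(affine = diag(c(spacing, spacing, spacing, 1)), dim = rep(n, 3))
}

random_affine <- function(seed, dof = 12, center = c(0, 0, 0),
                          trans = 3, rot_deg = 8, scale = 0.08,
                          shear = 0.04) {
  set.seed(seed)
  p <- c(runif(3, -trans, trans), runif(3, -rot_deg, rot_deg) * pi / 180,
         if (dof == 12) c(runif(3, -scale, scale),
                          runif(3, -shear, shear)) else rep(0, 6))
  affine_transform(p2a(p, center, 12),
                   dof_tag = if (dof == 6) "lsq6" else "lsq12")
}

tiny_phantom <- function(n = 24, seed = 1, noise_sd = 0.02) {
  make_labeled_phantom(phantom_spec(shape = rep(n, 3), seed = seed,
                                    noise_sd = noise_sd))
}

# write a phantom cohort to disk; returns paths and the cohort object
write_cohort <- function(dir, cohort) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    paths[i] <- file.path(dir, sprintf("subj%02d.nii.gz", i))
    write_volume(cohort$subjects[[i]], paths[i])
  }
  paths
}

# quick no-op artifact paths for engine tests
art <- local({
  counter <- 0
  function(dir, ...) {
    file.path(dir, paste0(c(...), collapse = "_"))
  }
})

# independent edge oracle: recompute all producer->consumer edges of a
# pipeline from scratch from stage footprints
edges_oracle <- function(stages) {
  prod <- list()
  for (i in seq_along(stages))
    for (o in stages[[i]]$outputs) prod[[o]] <- i
  out <- matrix(integer(), 0, 2)
  for (j in seq_along(stages))
    for (inp in stages[[j]]$inputs) {
      i <- prod[[inp]]
      if (!is.null(i)) out <- rbind(out, c(i, j))
    }
  unique(out)
}

# random DAG of command stages over artificial artifacts
random_dag_stages <- function(dir, n_stages, p_edge = 0.05, seed = 1) {
  set.seed(seed)
  stages <- vector("list", n_stages)
  arts <- file.path(dir, paste0("a", seq_len(n_stages)))
  for (i in seq_len(n_stages)) {
    preds <- if (i > 1) which(runif(i - 1) < p_edge) else integer()
    if (length(preds) > 6) preds <- sample(preds, 6)
    stages[[i]] <- command_stage("true", inputs = arts[preds],
                                 outputs = arts[i])
  }
  stages
}

# drain a pipeline without executing anything: emitted index order
drain_trace <- function(p, fail = integer()) {
  trace <- integer()
  repeat {
    s <- next_runnable(p)
    if (is.null(s)) break
    idx <- attr(s, "index")
    trace <- c(trace, idx)
    complete_stage(p, idx, if (idx %in% fail) "failed" else "finished")
  }
  trace
}
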