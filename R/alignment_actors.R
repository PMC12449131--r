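#' Alignment job configuration
#'
#' @param mode Task composition: `all_pairs` (every unordered pair of the
#'   dataset, the default), `query_vs_db` (every query against every target)
#'   or `pair_list` (an explicit index pair list).
#' @param workers Scheduler lanes for the actor runtime, `>= 1`.
#' @param max_in_flight Cap on concurrently live pair actors; defaults to
#'   `2 * workers` (keeps lanes busy while bounding concurrent matrices).
#' @param scheme A [scoring_scheme()].
#' @param policy A [backtrack_policy()].
#' @param intra Use intraalignment parallelism (block actors over the
#'   wavefront) inside each pair actor.
#' @param block_rows,block_cols Tile dimensions for `intra` mode.
#' @param score_only Skip traceback; scores and end coordinates only.
#' @param pairs For `pair_list` mode: a 2-column matrix/data.frame of
#'   sequence indices (or id strings).
#' @param inject_failures Integer task ids whose pair actors fail on
#'   purpose; a fault-isolation testing hook.
#' @param seed Seed echoed into the report; alignment itself is
#'   deterministic and seed-free.
#' @return Object of class `job_config`.
#' @export
job_config <- function(mode = c("all_pairs", "query_vs_db", "pair_list"),
                       workers = 1L, max_in_flight = NULL,
                       scheme = scoring_scheme(),
                       policy = backtrack_policy(),
                       intra = FALSE, block_rows = 256L, block_cols = 256L,
                       score_only = FALSE, pairs = NULL,
                       inject_failures = integer(0), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(workers) || length(workers) != 1L || is.na(workers) ||
      workers < 1 || workers != round(workers))
    stop("workers must be an integer >= 1", call. = FALSE)
  workers <- as.integer(workers)
  if (is.null(max_in_flight)) max_in_flight <- 2L * workers
  if (!is.numeric(max_in_flight) || max_in_flight < 1)
    stop("max_in_flight must be >= 1", call. = FALSE)
  stopifnot(inherits(scheme, "scoring_scheme"),
            inherits(policy, "backtrack_policy"))
  if (mode == "pair_list" && is.null(pairs))
    stop("pair_list mode requires pairs", call. = FALSE)
  structure(list(mode = mode, workers = workers,
                 max_in_flight = as.integer(max_in_flight),
                 scheme = scheme, policy = policy,
                 intra = isTRUE(intra),
                 block_rows = as.integer(block_rows),
                 block_cols = as.integer(block_cols),
                 score_only = isTRUE(score_only), pairs = pairs,
                 inject_failures = as.integer(inject_failures),
                 seed = seed),
            class = "job_config")
}

#' Enumerate alignment tasks
#'
#' @param dataset List of [seq_record()]s (queries).
#' @param config A [job_config()].
#' @param targets Target list for `query_vs_db` mode.
#' @return A data.frame with columns `task_id`, `qi`, `ti` (sequence
#'   indices; `ti` indexes `targets` in `query_vs_db` mode, `dataset`
#'   otherwise).  Task ids are assigned deterministically in enumeration
#'   order.
#' @export
enumerate_tasks <- function(dataset, config, targets = NULL) {
  n <- length(dataset)
  if (n < 1L) stop("dataset is empty", call. = FALSE)
  if (config$mode == "all_pairs") {
    if (n < 2L) {
      tasks <- data.frame(task_id = integer(0), qi = integer(0),
                          ti = integer(0))
    } else {
      cmb <- utils::combn(n, 2L)
      tasks <- data.frame(task_id = seq_len(ncol(cmb)),
                          qi = cmb[1L, ], ti = cmb[2L, ])
    }
  } else if (config$mode == "query_vs_db") {
    if (is.null(targets) || length(targets) < 1L)
      stop("query_vs_db mode requires a target dataset", call. = FALSE)
    grid <- expand.grid(ti = seq_along(targets), qi = seq_len(n))
    tasks <- data.frame(task_id = seq_len(nrow(grid)),
                        qi = grid$qi, ti = grid$ti)
  } else {
    pr <- config$pairs
    if (is.data.frame(pr)) pr <- as.matrix(pr)
    if (!is.matrix(pr) || ncol(pr) != 2L)
      stop("pairs must be a 2-column matrix", call. = FALSE)
    ids <- vapply(dataset, function(s) s$id, character(1))
    to_idx <- function(x) {
      if (is.character(x)) {
        idx <- match(x, ids)
        if (anyNA(idx))
          stop(sprintf("pair_list references missing id '%s'",
                       x[which(is.na(idx))[1L]]), call. = FALSE)
        idx
      } else {
        idx <- as.integer(x)
        if (anyNA(idx) || any(idx < 1L | idx > n))
          stop("pair_list index out of range", call. = FALSE)
        idx
      }
    }
    tasks <- data.frame(task_id = seq_len(nrow(pr)),
                        qi = to_idx(pr[, 1L]), ti = to_idx(pr[, 2L]))
  }
  tasks
}

# ---- behaviors --------------------------------------------------------

failed_result <- function(task_id, query_id, target_id, error) {
  list(task_id = task_id, query_id = query_id, target_id = target_id,
       alignment = NULL, status = "failed", error = error,
       diagnostics = list(cells = NA_real_, blocks = NA_integer_))
}

#' Manager actor behavior
#'
#' The manager spawns pair actors (at most `max_in_flight` live at once),
#' sends each its alignment task, records incoming task results, dispatches
#' pending tasks as results arrive, and converts pair-actor failures into
#' failed task results without stopping the job.
#'
#' @param tasks Task table from [enumerate_tasks()].
#' @param dataset,targets Sequence lists.
#' @param config A [job_config()].
#' @return An actor [behavior()] answering `start`, `task_result` and
#'   `actor_failed`.
#' @export
manager_behavior <- function(tasks, dataset, targets, config) {
  dispatch <- function(ctx, st) {
    while (st$next_task <= nrow(st$tasks) &&
           length(st$inflight) < st$config$max_in_flight) {
      row <- st$tasks[st$next_task, ]
      st$next_task <- st$next_task + 1L
      p <- st$dataset[[row$qi]]
      q <- st$targets[[row$ti]]
      ref <- spawn(ctx, pair_behavior(list(task_id = row$task_id,
                                           p = p, q = q),
                                      st$config, ctx$self))
      st$inflight[[ref]] <- row$task_id
      st$live <- st$live + 1L
      st$max_live <- max(st$max_live, st$live)
      send(ctx, ref, "compute")
    }
    st
  }
  record <- function(ctx, st, task_id, result) {
    st$results[[task_id]] <- result
    st$done <- st$done + 1L
    st
  }
  behavior(
    handlers = list(
      start = function(ctx, state, msg) dispatch(ctx, state),
      task_result = function(ctx, state, msg) {
        ref <- msg$sender
        state$inflight[[ref]] <- NULL
        state$live <- state$live - 1L
        state <- record(ctx, state, msg$args$result$task_id,
                        msg$args$result)
        dispatch(ctx, state)
      },
      actor_failed = function(ctx, state, msg) {
        ref <- msg$args$ref
        task_id <- state$inflight[[ref]]
        state$inflight[[ref]] <- NULL
        state$live <- state$live - 1L
        if (!is.null(task_id)) {
          row <- state$tasks[state$tasks$task_id == task_id, ]
          state <- record(ctx, state, task_id,
                          failed_result(task_id,
                                        state$dataset[[row$qi]]$id,
                                        state$targets[[row$ti]]$id,
                                        msg$args$error))
        }
        dispatch(ctx, state)
      }),
    state = list(tasks = tasks, dataset = dataset, targets = targets,
                 config = config, next_task = 1L,
                 results = vector("list", nrow(tasks)),
                 inflight = list(), live = 0L, max_live = 0L, done = 0L))
}

#' Pair actor behavior
#'
#' A pair actor computes one alignment task.  Without intraalignment
#' parallelism it runs the serial kernel and replies.  With it, the actor
#' spawns a bounded pool of block actors, releases block tasks level by
#' level along the wavefront, becomes a collecting behavior that only
#' accepts block results, folds halos and local maxima as they arrive, then
#' assembles the matrix (traceback mode) or not (score-only) and replies to
#' its manager.
#'
#' @param task List with `task_id`, `p`, `q` ([seq_record()]s).
#' @param config A [job_config()].
#' @param manager The manager's actor reference.
#' @return An actor [behavior()] answering `compute`.
#' @export
pair_behavior <- function(task, config, manager) {
  behavior(
    handlers = list(compute = function(ctx, state, msg) {
      if (state$task$task_id %in% state$config$inject_failures)
        stop("injected failure in task ", state$task$task_id)
      p <- state$task$p; q <- state$task$q
      cfg <- state$config
      if (!cfg$intra || p$length == 0L || q$length == 0L)
        return(pair_reply_serial(ctx, state))
      grid <- make_grid(p$length, q$length, cfg$block_rows, cfg$block_cols)
      sched <- wavefront_order(grid)
      pool_n <- min(cfg$workers, min(grid$grid_rows, grid$grid_cols))
      pool <- vapply(seq_len(pool_n), function(k)
        spawn(ctx, block_behavior(ctx$self)), character(1))
      state$grid <- grid
      state$sched <- sched
      state$pool <- pool
      state$level <- 0L
      state$outstanding <- 0L
      state$store <- list()
      state$best <- NULL
      state$blocks <- 0L
      if (!cfg$score_only) {
        m <- p$length; n <- q$length
        state$mats <- structure(
          list(H = matrix(0L, m + 1L, n + 1L),
               E = matrix(NA_integer_, m + 1L, n + 1L),
               F = matrix(NA_integer_, m + 1L, n + 1L), m = m, n = n),
          class = "dp_matrices")
      }
      state <- dispatch_level(ctx, state, 1L)
      become(ctx, collecting_behavior())
      state
    }),
    state = list(task = task, config = config, manager = manager))
}

pair_reply_serial <- function(ctx, state) {
  p <- state$task$p; q <- state$task$q; cfg <- state$config
  aln <- align_serial(p, q, cfg$scheme, cfg$policy, cfg$score_only)
  send(ctx, state$manager, "task_result",
       result = list(task_id = state$task$task_id,
                     query_id = p$id, target_id = q$id,
                     alignment = aln, status = "ok", error = NULL,
                     diagnostics = list(cells = as.numeric(p$length) *
                                          q$length,
                                        blocks = 1L)))
  state
}

# Send every block of wavefront level `k` to the block-actor pool,
# round-robin.  All halos the level needs are already in state$store.
dispatch_level <- function(ctx, state, k) {
  lev <- state$sched$levels[[k]]
  cfg <- state$config
  p <- state$task$p; q <- state$task$q
  for (r in seq_len(nrow(lev))) {
    I <- lev[r, "I"]; J <- lev[r, "J"]
    ext <- block_extent(state$grid, I, J)
    bnd <- gather_boundary(state$grid, I, J, state$store)
    who <- state$pool[[(r - 1L) %% length(state$pool) + 1L]]
    send(ctx, who, "block_task",
         id = c(I, J),
         pc = p$codes[ext$i0:ext$i1], qc = q$codes[ext$j0:ext$j1],
         boundary = bnd, scheme = cfg$scheme,
         keep_tile = !cfg$score_only, ext = ext)
  }
  state$level <- k
  state$outstanding <- nrow(lev)
  state
}

# After `compute`, a pair actor only accepts block results (and its state).
collecting_behavior <- function() {
  behavior(handlers = list(
    block_result = function(ctx, state, msg) {
      res <- msg$args$result
      ext <- msg$args$ext
      state$blocks <- state$blocks + 1L
      state$best <- better_max(state$best, res, ext)
      if (!state$config$score_only) {
        ri <- (ext$i0:ext$i1) + 1L; cj <- (ext$j0:ext$j1) + 1L
        state$mats$H[ri, cj] <- res$H
        state$mats$E[ri, cj] <- res$E
        state$mats$F[ri, cj] <- res$F
        res$H <- res$E <- res$F <- NULL
      }
      state$store[[halo_key(res$id[1L], res$id[2L])]] <- res
      state$outstanding <- state$outstanding - 1L
      if (state$outstanding > 0L) return(state)
      # level complete: prune stale halos, advance or finish
      if (state$level > 2L) {
        old <- state$sched$levels[[state$level - 2L]]
        for (r in seq_len(nrow(old)))
          state$store[[halo_key(old[r, "I"], old[r, "J"])]] <- NULL
      }
      if (state$level < length(state$sched$levels))
        return(dispatch_level(ctx, state, state$level + 1L))
      pair_finish(ctx, state)
    }))
}

pair_finish <- function(ctx, state) {
  cfg <- state$config
  p <- state$task$p; q <- state$task$q
  best <- state$best
  mx <- if (best$score <= 0L)
    list(score = 0L, i = NA_integer_, j = NA_integer_, no_alignment = TRUE)
  else
    list(score = best$score, i = best$i, j = best$j, no_alignment = FALSE)
  aln <- finish_alignment(mx, state$mats, p, q, cfg$scheme, cfg$policy,
                          cfg$score_only)
  send(ctx, state$manager, "task_result",
       result = list(task_id = state$task$task_id,
                     query_id = p$id, target_id = q$id,
                     alignment = aln, status = "ok", error = NULL,
                     diagnostics = list(cells = as.numeric(p$length) *
                                          q$length,
                                        blocks = state$blocks)))
  state
}

#' Block actor behavior
#'
#' A block actor computes score-matrix tiles on request and reports each
#' result (including the tile-local maximum) back to its pair actor, then
#' awaits the next block task — the same actor is reused across blocks.
#'
#' @param parent The pair actor's reference.
#' @return An actor [behavior()] answering `block_task`.
#' @export
block_behavior <- function(parent) {
  behavior(handlers = list(
    block_task = function(ctx, state, msg) {
      a <- msg$args
      res <- compute_block(a$id, a$pc, a$qc, a$boundary, a$scheme,
                           keep_tile = a$keep_tile)
      send(ctx, state$parent, "block_result", result = res, ext = a$ext)
      state
    }),
    state = list(parent = parent))
}

#' Run an alignment job on the actor runtime
#'
#' Wires the single-node topology — one manager actor dispatching alignment
#' tasks to pair actors, each optionally spawning block actors over the
#' wavefront — runs the scheduler to quiescence and collects a report.  For
#' fixed inputs the report is identical for any `workers`, any block
#' dimensions, and intra on or off (the parallel paths are exact).
#'
#' @param dataset List of [seq_record()]s.
#' @param config A [job_config()].
#' @param targets Optional target list (`query_vs_db` mode).
#' @return Object of class `job_report`: `results` (one task result per
#'   task, ordered by task id), `totals` (`tasks`, `ok`, `failed`, `cells`,
#'   `max_live_pairs`), `config`, and the runtime `stats`.
#' @examples
#' ds <- lapply(1:3, function(i) seq_record(paste0("s", i), "ACGTACGT"))
#' run_job(ds, job_config(workers = 2))
#' @export
run_job <- function(dataset, config = job_config(), targets = NULL) {
  stopifnot(inherits(config, "job_config"))
  if (!is.list(dataset) || length(dataset) < 1L)
    stop("dataset must be a non-empty list of seq_record", call. = FALSE)
  dataset <- lapply(dataset, as_seq_record)
  if (!is.null(targets)) targets <- lapply(targets, as_seq_record)
  tasks <- enumerate_tasks(dataset, config, targets)
  tgt <- if (config$mode == "query_vs_db") targets else dataset
  if (nrow(tasks) == 0L) {
    return(structure(list(results = list(),
                          totals = list(tasks = 0L, ok = 0L, failed = 0L,
                                        cells = 0, max_live_pairs = 0L),
                          config = config, stats = NULL),
                     class = "job_report"))
  }
  rt <- actor_system(workers = config$workers)
  mgr <- spawn(rt, manager_behavior(tasks, dataset, tgt, config))
  send(rt, mgr, "start")
  stats <- run_until_quiescent(rt)
  st <- get(mgr, envir = rt$actors)$state
  if (st$done != nrow(tasks))
    stop(sprintf("job stalled: %d of %d tasks completed", st$done,
                 nrow(tasks)), call. = FALSE)
  results <- st$results
  ok <- vapply(results, function(r) identical(r$status, "ok"), logical(1))
  cells <- vapply(results, function(r)
    if (is.na(r$diagnostics$cells)) 0 else r$diagnostics$cells, numeric(1))
  structure(list(results = results,
                 totals = list(tasks = nrow(tasks), ok = sum(ok),
                               failed = sum(!ok), cells = sum(cells),
                               max_live_pairs = st$max_live),
                 config = config, stats = stats),
            class = "job_report")
}

#' @export
print.job_report <- function(x, ...) {
  cat(sprintf(paste0("<job_report> %d task(s): %d ok, %d failed; ",
                     "%.0f cells; mode %s, %d worker(s), intra %s\n"),
              x$totals$tasks, x$totals$ok, x$totals$failed,
              x$totals$cells, x$config$mode, x$config$workers,
              if (x$config$intra) "on" else "off"))
  invisible(x)
}
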