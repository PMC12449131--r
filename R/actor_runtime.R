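#' A minimal in-process actor runtime
#'
#' Actors are isolated entities owning private state, communicating only via
#' asynchronous messages held in per-actor mailboxes.  On receiving a
#' message an actor may send messages, spawn new actors, or become a new
#' behavior.  A scheduler serves the ready queue (actors with non-empty
#' mailboxes; each actor appears at most once) in rounds of up to
#' `workers` actors; handler execution is effect-based — a handler returns
#' its new state plus a record of its sends/spawns/become — and effects are
#' applied in deterministic slot order, so single-lane and multi-lane
#' execution produce identical results.  With `workers > 1` the handlers of
#' one round run on forked parallel lanes via [parallel::mclapply()].
#'
#' Delivery is in-process and exactly-once, FIFO per (sender, receiver)
#' pair.  Sends to terminated actors go to a dead-letter log.  A handler
#' error marks that actor failed and routes an `actor_failed` message to its
#' creator; the run continues.
#'
#' @param workers Number of execution lanes, `>= 1`.
#' @return An object of class `actor_system`.
#' @examples
#' rt <- actor_system()
#' echo <- behavior(list(ping = function(ctx, state, msg) {
#'   send(ctx, msg$sender, "pong")
#'   state
#' }))
#' a <- spawn(rt, echo)
#' send(rt, a, "ping")
#' run_until_quiescent(rt)$messages_processed
#' @export
actor_system <- function(workers = 1L) {
  if (!is.numeric(workers) || length(workers) != 1L || is.na(workers) ||
      workers < 1 || workers != round(workers))
    stop("workers must be an integer >= 1", call. = FALSE)
  rt <- new.env(parent = emptyenv())
  rt$workers <- as.integer(workers)
  rt$actors <- new.env(parent = emptyenv())
  rt$ready <- character(0)
  rt$next_id <- 0L
  rt$round <- 0L
  rt$closed <- FALSE
  rt$stats <- list(messages_sent = 0L, messages_processed = 0L,
                   dead_letters = 0L, spawned = 0L, failed = 0L,
                   rounds = 0L, per_worker = integer(workers))
  rt$dead_letter_log <- list()
  class(rt) <- "actor_system"
  rt
}

#' @export
print.actor_system <- function(x, ...) {
  cat(sprintf("<actor_system> %d worker lane(s), %d actor(s) spawned\n",
              x$workers, x$stats$spawned))
  invisible(x)
}

#' Define an actor behavior
#'
#' @param handlers Named list mapping message types to handler functions
#'   `function(ctx, state, msg)`; a handler returns the actor's new state.
#'   `msg` has fields `type`, `args` (list) and `sender`.
#' @param state Initial private state (a list).
#' @return Object of class `actor_behavior`.
#' @export
behavior <- function(handlers, state = list()) {
  if (!is.list(handlers) || length(handlers) == 0L ||
      is.null(names(handlers)) || any(!nzchar(names(handlers))) ||
      !all(vapply(handlers, is.function, logical(1))))
    stop("handlers must be a named list of functions", call. = FALSE)
  if (anyDuplicated(names(handlers)))
    stop("duplicate handler for one message signature", call. = FALSE)
  structure(list(handlers = handlers, state = state),
            class = "actor_behavior")
}

is_ctx <- function(x) inherits(x, "actor_context")

#' Spawn an actor
#'
#' Callable on the runtime (top level) or on a handler context (an actor
#' spawning actors from within a handler).
#'
#' @param where An `actor_system` or a handler `ctx`.
#' @param b An [behavior()] object.
#' @param .creator Internal.
#' @return An actor reference (opaque string).
#' @export
spawn <- function(where, b, .creator = NULL) {
  stopifnot(inherits(b, "actor_behavior"))
  if (is_ctx(where)) {
    ctx <- where
    if (!isTRUE(ctx$active))
      stop("spawn: handler context is no longer active", call. = FALSE)
    ctx$spawn_k <- ctx$spawn_k + 1L
    ref <- sprintf("%s.s%d", ctx$grant, ctx$spawn_k)
    ctx$effects[[length(ctx$effects) + 1L]] <-
      list(kind = "spawn", id = ref, behavior = b, creator = ctx$self)
    return(ref)
  }
  rt <- where
  stopifnot(inherits(rt, "actor_system"))
  if (rt$closed) stop("spawn after shutdown", call. = FALSE)
  rt$next_id <- rt$next_id + 1L
  ref <- sprintf("a%d", rt$next_id)
  register_actor(rt, ref, b, .creator)
  ref
}

register_actor <- function(rt, ref, b, creator) {
  a <- new.env(parent = emptyenv())
  a$behavior <- b
  a$state <- b$state
  a$mailbox <- list()
  a$alive <- TRUE
  a$creator <- creator
  a$queued <- FALSE
  a$processing <- FALSE   # reentrancy guard, assertable in tests
  assign(ref, a, envir = rt$actors)
  rt$stats$spawned <- rt$stats$spawned + 1L
  invisible(ref)
}

#' Send an asynchronous message
#'
#' Returns immediately; the message is enqueued in the target's mailbox
#' (from a handler, after the handler completes, in deterministic order).
#' Sending to a terminated or unknown actor records a dead letter instead of
#' raising.
#'
#' @param where An `actor_system` or a handler `ctx`.
#' @param to Target actor reference.
#' @param type Message type (selects the handler).
#' @param ... Message arguments (immutable once sent).
#' @param sender Optional sender reference for top-level sends.
#' @return Invisibly, `NULL`.
#' @export
send <- function(where, to, type, ..., sender = NULL) {
  msg <- list(type = as.character(type), args = list(...), sender = sender)
  if (is_ctx(where)) {
    ctx <- where
    if (!isTRUE(ctx$active))
      stop("send: handler context is no longer active", call. = FALSE)
    msg$sender <- ctx$self
    ctx$effects[[length(ctx$effects) + 1L]] <-
      list(kind = "send", to = to, msg = msg)
    return(invisible(NULL))
  }
  rt <- where
  stopifnot(inherits(rt, "actor_system"))
  deliver(rt, to, msg)
  invisible(NULL)
}

deliver <- function(rt, to, msg) {
  rt$stats$messages_sent <- rt$stats$messages_sent + 1L
  a <- get0(to, envir = rt$actors)
  if (is.null(a) || !a$alive) {
    rt$stats$dead_letters <- rt$stats$dead_letters + 1L
    rt$dead_letter_log[[length(rt$dead_letter_log) + 1L]] <-
      list(to = to, type = msg$type)
    return(invisible(NULL))
  }
  a$mailbox[[length(a$mailbox) + 1L]] <- msg
  if (!a$queued) {
    a$queued <- TRUE
    rt$ready <- c(rt$ready, to)
  }
  invisible(NULL)
}

#' Replace the running actor's behavior
#'
#' Callable only from within a handler; the in-flight message completes
#' under the old behavior, subsequent messages use `new_behavior` (its
#' handlers; the actor's current state is kept unless the returned state
#' changes it).
#'
#' @param ctx The handler context.
#' @param new_behavior An [behavior()].
#' @export
become <- function(ctx, new_behavior) {
  if (!is_ctx(ctx) || !isTRUE(ctx$active))
    stop("become can only be called inside a message handler",
         call. = FALSE)
  stopifnot(inherits(new_behavior, "actor_behavior"))
  ctx$become <- new_behavior
  invisible(NULL)
}

# Execute one handler invocation in isolation; never throws.
run_handler <- function(b, state, msg, self, grant) {
  ctx <- new.env(parent = emptyenv())
  ctx$self <- self
  ctx$sender <- msg$sender
  ctx$grant <- grant
  ctx$spawn_k <- 0L
  ctx$effects <- list()
  ctx$become <- NULL
  ctx$active <- TRUE
  class(ctx) <- "actor_context"
  h <- b$handlers[[msg$type]]
  if (is.null(h)) {
    ctx$active <- FALSE
    return(list(state = state, effects = list(), become = NULL,
                error = sprintf("no handler matches message type '%s'",
                                msg$type)))
  }
  out <- tryCatch(
    list(state = h(ctx, state, msg), error = NULL),
    error = function(e) list(state = state, error = conditionMessage(e)))
  ctx$active <- FALSE
  list(state = if (is.null(out$error)) out$state else state,
       effects = ctx$effects, become = ctx$become, error = out$error)
}

#' Run the scheduler to quiescence
#'
#' Serves the ready queue in rounds until every mailbox is empty and no
#' handler is executing, then returns scheduling statistics.
#'
#' @param rt An [actor_system()].
#' @return A list: `messages_sent`, `messages_processed`, `dead_letters`,
#'   `spawned`, `failed`, `rounds`, `per_worker` (messages per lane).
#' @export
run_until_quiescent <- function(rt) {
  stopifnot(inherits(rt, "actor_system"))
  while (length(rt$ready) > 0L) {
    rt$round <- rt$round + 1L
    rt$stats$rounds <- rt$stats$rounds + 1L
    nb <- min(rt$workers, length(rt$ready))
    batch <- rt$ready[seq_len(nb)]
    rt$ready <- rt$ready[-seq_len(nb)]
    jobs <- vector("list", nb)
    for (s in seq_len(nb)) {
      a <- get(batch[s], envir = rt$actors)
      stopifnot(!a$processing)          # per-actor serialization guard
      a$processing <- TRUE
      msg <- a$mailbox[[1L]]
      a$mailbox <- a$mailbox[-1L]
      jobs[[s]] <- list(b = a$behavior, state = a$state, msg = msg,
                        self = batch[s],
                        grant = sprintf("%s.r%d", batch[s], rt$round))
    }
    results <- if (nb == 1L || rt$workers == 1L) {
      lapply(jobs, function(j)
        run_handler(j$b, j$state, j$msg, j$self, j$grant))
    } else {
      parallel::mclapply(jobs, function(j)
        run_handler(j$b, j$state, j$msg, j$self, j$grant),
        mc.cores = nb, mc.preschedule = TRUE)
    }
    for (s in seq_len(nb)) {
      ref <- batch[s]
      a <- get(ref, envir = rt$actors)
      res <- results[[s]]
      if (!is.list(res) || is.null(res$effects))
        stop("worker lane failed: ", paste(res, collapse = " "),
             call. = FALSE)
      rt$stats$messages_processed <- rt$stats$messages_processed + 1L
      rt$stats$per_worker[s] <- rt$stats$per_worker[s] + 1L
      if (is.null(res$error)) {
        a$state <- res$state
        if (!is.null(res$become)) {
          a$behavior <- res$become
        }
        for (ef in res$effects) {
          if (ef$kind == "spawn")
            register_actor(rt, ef$id, ef$behavior, creator = ef$creator)
          else
            deliver(rt, ef$to, ef$msg)
        }
      } else {
        # failure poisons this actor only; supervise via the creator
        a$alive <- FALSE
        rt$stats$failed <- rt$stats$failed + 1L
        for (dm in a$mailbox) {
          rt$stats$dead_letters <- rt$stats$dead_letters + 1L
          rt$dead_letter_log[[length(rt$dead_letter_log) + 1L]] <-
            list(to = ref, type = dm$type)
        }
        a$mailbox <- list()
        if (!is.null(a$creator))
          deliver(rt, a$creator,
                  list(type = "actor_failed",
                       args = list(ref = ref, error = res$error),
                       sender = ref))
      }
      a$processing <- FALSE
      a$queued <- FALSE
      if (a$alive && length(a$mailbox) > 0L) {
        a$queued <- TRUE
        rt$ready <- c(rt$ready, ref)
      }
    }
  }
  rt$stats
}

#' Is an actor still alive?
#' @param rt An `actor_system`.
#' @param ref An actor reference.
#' @return Logical.
#' @export
actor_alive <- function(rt, ref) {
  a <- get0(ref, envir = rt$actors)
  !is.null(a) && a$alive
}

#' Shut the runtime down
#'
#' Marks the runtime closed; further [spawn()] calls raise a lifecycle
#' error.
#' @param rt An `actor_system`.
#' @export
shutdown <- function(rt) {
  stopifnot(inherits(rt, "actor_system"))
  rt$closed <- TRUE
  invisible(rt)
}
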