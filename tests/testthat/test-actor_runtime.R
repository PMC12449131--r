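echo_behavior <- function() {
  behavior(list(ping = function(ctx, state, msg) {
    send(ctx, msg$sender, "pong", value = msg$args$value)
    state
  }))
}

test_that("a single echo round-trip processes two messages", {
  rt <- actor_system()
  got <- new.env()
  sink_b <- behavior(list(pong = function(ctx, state, msg) {
    got$value <- msg$args$value
    state
  }))
  sink <- spawn(rt, sink_b)
  eb <- spawn(rt, echo_behavior())
  send(rt, eb, "ping", value = "x", sender = sink)
  stats <- run_until_quiescent(rt)
  expect_identical(got$value, "x")
  expect_identical(stats$messages_processed, 2L)
  expect_identical(stats$dead_letters, 0L)
})

test_that("independent counter actors accumulate independently", {
  rt <- actor_system(workers = 4)
  counter <- behavior(list(inc = function(ctx, state, msg) {
    state$n <- state$n + 1L
    state
  }), state = list(n = 0L))
  refs <- vapply(1:100, function(i) spawn(rt, counter), character(1))
  expect_identical(anyDuplicated(refs), 0L)
  for (r in refs) send(rt, r, "inc")
  run_until_quiescent(rt)
  total <- sum(vapply(refs, function(r)
    get(r, envir = rt$actors)$state$n, integer(1)))
  expect_identical(total, 100L)
})

test_that("delivery between one sender and one receiver preserves order", {
  rt <- actor_system(workers = 3)
  recorder <- behavior(list(note = function(ctx, state, msg) {
    state$seen <- c(state$seen, msg$args$k)
    state
  }), state = list(seen = integer(0)))
  rec <- spawn(rt, recorder)
  emitter <- behavior(list(go = function(ctx, state, msg) {
    for (k in 1:50) send(ctx, state$to, "note", k = k)
    state
  }), state = list(to = rec))
  em <- spawn(rt, emitter)
  send(rt, em, "go")
  run_until_quiescent(rt)
  expect_identical(get(rec, envir = rt$actors)$state$seen, 1:50)
})

test_that("interleaving from two senders preserves each pairwise order", {
  rt <- actor_system(workers = 2)
  recorder <- behavior(list(note = function(ctx, state, msg) {
    state$seen[[length(state$seen) + 1L]] <- c(msg$args$who, msg$args$k)
    state
  }), state = list(seen = list()))
  rec <- spawn(rt, recorder)
  emitter <- function(who) behavior(list(go = function(ctx, state, msg) {
    for (k in 1:20) send(ctx, state$to, "note", who = who, k = k)
    state
  }), state = list(to = rec))
  e1 <- spawn(rt, emitter(1L)); e2 <- spawn(rt, emitter(2L))
  send(rt, e1, "go"); send(rt, e2, "go")
  run_until_quiescent(rt)
  seen <- get(rec, envir = rt$actors)$state$seen
  for (who in 1:2) {
    ks <- vapply(Filter(function(x) x[1] == who, seen), `[`, 0L, 2L)
    expect_identical(ks, 1:20)
  }
})

test_that("become changes future behavior, not the in-flight message", {
  rt <- actor_system()
  off <- behavior(list(
    query = function(ctx, state, msg) {
      send(ctx, msg$sender, "answer", state = "off")
      state
    },
    switch = function(ctx, state, msg) state))
  on <- behavior(list(
    query = function(ctx, state, msg) {
      send(ctx, msg$sender, "answer", state = "on")
      state
    },
    switch = function(ctx, state, msg) {
      become(ctx, off)
      send(ctx, msg$sender, "answer", state = "still-on-while-switching")
      state
    }))
  seen <- new.env(); seen$answers <- character(0)
  probe <- spawn(rt, behavior(list(answer = function(ctx, state, msg) {
    seen$answers <- c(seen$answers, msg$args$state)
    state
  })))
  toggle <- spawn(rt, on)
  send(rt, toggle, "query", sender = probe)
  send(rt, toggle, "switch", sender = probe)
  send(rt, toggle, "query", sender = probe)
  run_until_quiescent(rt)
  expect_identical(seen$answers, c("on", "still-on-while-switching", "off"))
})

test_that("become outside a handler is a usage error", {
  expect_error(become(list(), behavior(list(x = function(ctx, s, m) s))),
               "inside a message handler")
})

test_that("spawn after shutdown is a lifecycle error", {
  rt <- actor_system()
  shutdown(rt)
  expect_error(spawn(rt, echo_behavior()), "shutdown")
})

test_that("sends to failed actors become dead letters, not exceptions", {
  rt <- actor_system()
  bomb <- spawn(rt, behavior(list(boom = function(ctx, state, msg)
    stop("kaboom"))))
  send(rt, bomb, "boom")
  run_until_quiescent(rt)
  expect_false(actor_alive(rt, bomb))
  send(rt, bomb, "boom")
  stats <- run_until_quiescent(rt)
  expect_identical(stats$dead_letters, 1L)
  expect_identical(rt$dead_letter_log[[1]]$to, bomb)
})

test_that("a handler error is routed to the creator as supervision", {
  rt <- actor_system()
  parent <- behavior(list(
    go = function(ctx, state, msg) {
      child <- spawn(ctx, behavior(list(work = function(ctx, s, m)
        stop("worker exploded"))))
      send(ctx, child, "work")
      state
    },
    actor_failed = function(ctx, state, msg) {
      state$failure <- msg$args$error
      state
    }))
  pa <- spawn(rt, parent)
  send(rt, pa, "go")
  stats <- run_until_quiescent(rt)
  expect_match(get(pa, envir = rt$actors)$state$failure, "worker exploded")
  expect_identical(stats$failed, 1L)
})

test_that("messages are conserved at quiescence", {
  rt <- actor_system(workers = 4)
  relay <- behavior(list(hop = function(ctx, state, msg) {
    if (msg$args$ttl > 0L)
      send(ctx, state$next_ref, "hop", ttl = msg$args$ttl - 1L)
    state
  }), state = list(next_ref = NULL))
  ring <- vapply(1:5, function(i) spawn(rt, relay), character(1))
  for (i in 1:5) {
    a <- get(ring[i], envir = rt$actors)
    a$state$next_ref <- ring[i %% 5 + 1]
  }
  send(rt, ring[1], "hop", ttl = 37L)
  stats <- run_until_quiescent(rt)
  expect_identical(stats$messages_sent,
                   stats$messages_processed + stats$dead_letters)
  expect_identical(stats$messages_processed, 38L)
})

test_that("worker lane count changes scheduling, not results", {
  run_with <- function(workers) {
    rt <- actor_system(workers = workers)
    acc <- behavior(list(add = function(ctx, state, msg) {
      state$sum <- state$sum + msg$args$x
      state
    }), state = list(sum = 0))
    refs <- vapply(1:8, function(i) spawn(rt, acc), character(1))
    for (i in 1:64) send(rt, refs[(i - 1) %% 8 + 1], "add", x = i)
    stats <- run_until_quiescent(rt)
    sums <- vapply(refs, function(r)
      get(r, envir = rt$actors)$state$sum, numeric(1))
    list(sums = unname(sums), per_worker = stats$per_worker)
  }
  r1 <- run_with(1); r8 <- run_with(8)
  expect_identical(r1$sums, r8$sums)
  expect_identical(length(r1$per_worker), 1L)
  expect_identical(length(r8$per_worker), 8L)
  expect_identical(sum(r1$per_worker), sum(r8$per_worker))
  expect_true(sum(r8$per_worker > 0L) > 1L)  # work spread across lanes
})

test_that("message payloads are not shared mutable state", {
  rt <- actor_system()
  payload <- list(v = 1L)
  holder <- spawn(rt, behavior(list(take = function(ctx, state, msg) {
    state$got <- msg$args$p
    state
  })))
  send(rt, holder, "take", p = payload)
  payload$v <- 99L   # mutation after send must not be visible
  run_until_quiescent(rt)
  expect_identical(get(holder, envir = rt$actors)$state$got, list(v = 1L))
})
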