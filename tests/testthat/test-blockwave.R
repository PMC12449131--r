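test_that("grids tile the matrix exactly, ragged edges included", {
  g <- make_grid(8, 8, 4, 4)
  expect_identical(c(g$grid_rows, g$grid_cols), c(2L, 2L))
  g1 <- make_grid(8, 8, 8, 8)
  expect_identical(c(g1$grid_rows, g1$grid_cols), c(1L, 1L))
  g2 <- make_grid(10, 7, 4, 3)
  expect_identical(c(g2$grid_rows, g2$grid_cols), c(3L, 3L))
  last <- wavealign:::block_extent(g2, 2L, 2L)
  expect_identical(last$i1 - last$i0 + 1L, 2L)  # ragged rows
  expect_identical(last$j1 - last$j0 + 1L, 1L)  # ragged cols
  # every interior cell in exactly one block
  cover <- matrix(0L, g2$m, g2$n)
  for (I in 0:(g2$grid_rows - 1L)) for (J in 0:(g2$grid_cols - 1L)) {
    e <- wavealign:::block_extent(g2, I, J)
    cover[e$i0:e$i1, e$j0:e$j1] <- cover[e$i0:e$i1, e$j0:e$j1] + 1L
  }
  expect_true(all(cover == 1L))
  expect_error(make_grid(8, 8, 0, 4), ">=")
})

test_that("block dependencies are the existing upper/left/diagonal set", {
  g <- make_grid(12, 12, 3, 3)
  expect_identical(block_dependencies(g, 0, 0), list())
  expect_identical(block_dependencies(g, 0, 3), list(c(0L, 2L)))
  deps <- block_dependencies(g, 2, 2)
  expect_setequal(lapply(deps, paste, collapse = ","),
                  list("1,2", "2,1", "1,1"))
  expect_error(block_dependencies(g, 4, 0), "outside")
})

test_that("wavefront levels group blocks by antidiagonal", {
  expect_length(wavefront_order(make_grid(5, 5, 5, 5))$levels, 1L)
  w2 <- wavefront_order(make_grid(8, 8, 4, 4))
  expect_length(w2$levels, 3L)
  expect_identical(unname(w2$levels[[2]][, "I"]), c(0L, 1L))
  w3 <- wavefront_order(make_grid(9, 9, 3, 3))
  expect_identical(max(vapply(w3$levels, nrow, integer(1))), 3L)
  expect_identical(which.max(vapply(w3$levels, nrow, integer(1))), 3L)
  # every dependency sits in a strictly earlier level
  g <- make_grid(20, 14, 3, 4)
  sched <- wavefront_order(g)
  level_of <- function(I, J) I + J + 1L
  for (k in seq_along(sched$levels)) {
    lev <- sched$levels[[k]]
    for (r in seq_len(nrow(lev))) {
      for (d in block_dependencies(g, lev[r, "I"], lev[r, "J"]))
        expect_lt(level_of(d[1], d[2]), k)
    }
  }
})

test_that("blocks computed from halos reassemble the serial matrices", {
  sch <- std_scheme()
  p <- seq_record("p", worked_query)
  q <- seq_record("q", worked_target)
  serial <- fill_matrices(p, q, sch)
  for (dims in list(c(1L, 1L), c(3L, 3L), c(2L, 5L))) {
    g <- make_grid(p$length, q$length, dims[1], dims[2])
    sched <- wavefront_order(g)
    store <- list()
    H <- matrix(0L, p$length + 1L, q$length + 1L)
    best <- NULL
    for (lev in sched$levels) for (r in seq_len(nrow(lev))) {
      I <- lev[r, "I"]; J <- lev[r, "J"]
      e <- wavealign:::block_extent(g, I, J)
      bnd <- wavealign:::gather_boundary(g, I, J, store)
      res <- compute_block(c(I, J), p$codes[e$i0:e$i1],
                           q$codes[e$j0:e$j1], bnd, sch, keep_tile = TRUE)
      H[(e$i0:e$i1) + 1L, (e$j0:e$j1) + 1L] <- res$H
      best <- wavealign:::better_max(best, res, e)
      store[[wavealign:::halo_key(I, J)]] <- res
    }
    expect_identical(H, unname(serial$H))
    expect_identical(best$score, 6L)
    expect_identical(c(best$i, best$j), c(3L, 6L))
  }
})

test_that("halo length mismatches are contract violations", {
  sch <- std_scheme()
  bnd <- block_boundary(top_H = c(0L, 0L), top_F = c(0L, 0L),
                        left_H = 0L, left_E = 0L, corner_H = 0L)
  expect_error(compute_block(c(0, 0), c(1L, 2L), c(1L, 2L), bnd, sch),
               "halo")
})

test_that("an all-mismatch block with zero halos stays at zero", {
  sch <- std_scheme()
  a <- seq_record("a", "AAAA"); t <- seq_record("t", "TTTT")
  neg <- wavealign:::.neg_sentinel()
  bnd <- block_boundary(integer(4), rep(neg, 4), integer(4), rep(neg, 4), 0L)
  res <- compute_block(c(0, 0), a$codes, t$codes, bnd, sch,
                       keep_tile = TRUE)
  expect_true(all(res$H == 0L))
  expect_identical(res$local_max$score, 0L)
})

test_that("blockwise alignment equals serial for every legal block size", {
  set.seed(303)
  schemes <- list(scoring_scheme(2, -1, -2),
                  scoring_scheme(3, -2, gap_open = -5, gap_extend = -1))
  for (k in 1:12) {
    m <- sample(1:120, 1); n <- sample(1:120, 1)
    p <- random_dna(m); q <- random_dna(n)
    sch <- schemes[[k %% 2 + 1]]
    ref <- alignment_fields(align_serial(p, q, sch))
    for (dims in list(c(1L, 1L), c(1L, n), c(3L, 7L), c(64L, 64L),
                      c(m, n))) {
      got <- align_blockwise(p, q, sch, dims[1], dims[2])
      expect_identical(alignment_fields(got), ref)
    }
  }
})

test_that("score-only blockwise runs keep only wavefront halos", {
  set.seed(404)
  p <- random_dna(200); q <- random_dna(200)
  sch <- std_scheme()
  got <- align_blockwise(p, q, sch, 10, 10, score_only = TRUE)
  ref <- align_serial(p, q, sch, score_only = TRUE)
  expect_identical(alignment_fields(got), alignment_fields(ref))
  d <- attr(got, "diagnostics")
  expect_identical(d$blocks_computed, 400L)
  # in-flight halo store is bounded by ~3 wavefront levels, not the grid
  expect_lte(d$max_halo_entries, 3L * 20L)
  expect_lt(d$max_halo_entries, 400L)
})

test_that("blocks within a level are order-independent", {
  set.seed(505)
  p <- seq_record("p", random_dna(40))
  q <- seq_record("q", random_dna(40))
  sch <- std_scheme()
  g <- make_grid(40, 40, 7, 9)
  sched <- wavefront_order(g)
  run_shuffled <- function(perm_seed) {
    set.seed(perm_seed)
    store <- list()
    H <- matrix(0L, 41L, 41L)
    for (lev in sched$levels) {
      order_r <- sample(nrow(lev))
      for (r in order_r) {
        I <- lev[r, "I"]; J <- lev[r, "J"]
        e <- wavealign:::block_extent(g, I, J)
        bnd <- wavealign:::gather_boundary(g, I, J, store)
        res <- compute_block(c(I, J), p$codes[e$i0:e$i1],
                             q$codes[e$j0:e$j1], bnd, sch,
                             keep_tile = TRUE)
        H[(e$i0:e$i1) + 1L, (e$j0:e$j1) + 1L] <- res$H
        store[[wavealign:::halo_key(I, J)]] <- res
      }
    }
    H
  }
  H1 <- run_shuffled(1); H2 <- run_shuffled(99)
  expect_identical(H1, H2)
  expect_identical(H1, unname(fill_matrices(p, q, sch)$H))
})
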