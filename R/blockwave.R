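#' Partition a score matrix into a block grid
#'
#' The interior cells `[1..m] x [1..n]` of the score matrix are tiled by
#' `block_rows x block_cols` rectangles; the last row/column of tiles may be
#' ragged.  Row strips (`block_cols = n`) and the single-tile grid
#' (`block_rows = m, block_cols = n`, which degenerates to the serial kernel)
#' are special cases.
#'
#' @param m,n Interior matrix dimensions (sequence lengths), `>= 0`.
#' @param block_rows,block_cols Tile dimensions, `>= 1`.
#' @return An object of class `block_grid` with fields `m`, `n`,
#'   `block_rows`, `block_cols`, `grid_rows`, `grid_cols`.
#' @examples
#' make_grid(10, 7, 4, 3)
#' @export
make_grid <- function(m, n, block_rows, block_cols) {
  chk <- function(x, nm, lo) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo ||
        x != round(x))
      stop(sprintf("%s must be an integer >= %d", nm, lo), call. = FALSE)
    as.integer(x)
  }
  m <- chk(m, "m", 0L); n <- chk(n, "n", 0L)
  block_rows <- chk(block_rows, "block_rows", 1L)
  block_cols <- chk(block_cols, "block_cols", 1L)
  structure(list(m = m, n = n,
                 block_rows = block_rows, block_cols = block_cols,
                 grid_rows = as.integer(ceiling(m / block_rows)),
                 grid_cols = as.integer(ceiling(n / block_cols))),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> %d x %d cells as %d x %d tiles of %d x %d\n",
              x$m, x$n, x$grid_rows, x$grid_cols,
              x$block_rows, x$block_cols))
  invisible(x)
}

# Residue index span of block (I, J); block ids are 0-based.
block_extent <- function(grid, I, J) {
  list(i0 = I * grid$block_rows + 1L,
       i1 = min((I + 1L) * grid$block_rows, grid$m),
       j0 = J * grid$block_cols + 1L,
       j1 = min((J + 1L) * grid$block_cols, grid$n))
}

check_block_id <- function(grid, I, J) {
  if (I < 0L || J < 0L || I >= grid$grid_rows || J >= grid$grid_cols)
    stop(sprintf("block (%d, %d) outside %d x %d grid",
                 I, J, grid$grid_rows, grid$grid_cols), call. = FALSE)
}

#' Dependencies of a block
#'
#' A block needs the finished halos of its upper, left and upper-left
#' neighbours (the data dependence of the recursion crossing tile edges).
#'
#' @param grid A [make_grid()] object.
#' @param I,J 0-based block indices.
#' @return List of `c(I, J)` integer pairs (empty for the top-left block).
#' @export
block_dependencies <- function(grid, I, J) {
  I <- as.integer(I); J <- as.integer(J)
  check_block_id(grid, I, J)
  deps <- list()
  if (I > 0L) deps <- c(deps, list(c(I - 1L, J)))
  if (J > 0L) deps <- c(deps, list(c(I, J - 1L)))
  if (I > 0L && J > 0L) deps <- c(deps, list(c(I - 1L, J - 1L)))
  deps
}

#' Antidiagonal wavefront schedule
#'
#' Groups blocks into levels of constant `I + J`.  All dependencies of a
#' block lie in strictly earlier levels, so the blocks of one level can be
#' evaluated simultaneously and in any order.
#'
#' @param grid A [make_grid()] object.
#' @return Object of class `wavefront_schedule`: a list `levels`, each an
#'   integer matrix with columns `I`, `J`, plus the grid.  The number of
#'   levels is `grid_rows + grid_cols - 1`.
#' @export
wavefront_order <- function(grid) {
  stopifnot(inherits(grid, "block_grid"))
  n_levels <- max(grid$grid_rows + grid$grid_cols - 1L, 0L)
  levels <- vector("list", n_levels)
  if (n_levels > 0L) {
    for (k in 0:(n_levels - 1L)) {
      I <- max(0L, k - grid$grid_cols + 1L):min(k, grid$grid_rows - 1L)
      levels[[k + 1L]] <- cbind(I = I, J = k - I)
    }
  }
  structure(list(levels = levels, grid = grid),
            class = "wavefront_schedule")
}

#' Block boundary (halo) values
#'
#' The values a tile imports across its edges: `H` and `F` along the row
#' above (the vertical gap state crosses row boundaries), `H` and `E` along
#' the column to the left, and the single `H` value diagonally above-left.
#' On matrix edges the `H` halos are the zero boundary and the gap states are
#' an impossible-state sentinel.
#'
#' @param top_H,top_F Integer vectors over the block's column span.
#' @param left_H,left_E Integer vectors over the block's row span.
#' @param corner_H Single integer.
#' @return Object of class `block_boundary`.
#' @export
block_boundary <- function(top_H, top_F, left_H, left_E, corner_H) {
  structure(list(top_H = as.integer(top_H), top_F = as.integer(top_F),
                 left_H = as.integer(left_H), left_E = as.integer(left_E),
                 corner_H = as.integer(corner_H)),
            class = "block_boundary")
}

# Boundary for block (I, J) given a store of finished block results,
# a plain list keyed by "I,J" (see halo_key).
gather_boundary <- function(grid, I, J, store) {
  ext <- block_extent(grid, I, J)
  mb <- ext$i1 - ext$i0 + 1L
  nb <- ext$j1 - ext$j0 + 1L
  neg <- .neg_sentinel()
  if (I == 0L) {
    top_H <- integer(nb); top_F <- rep(neg, nb)
  } else {
    up <- store[[halo_key(I - 1L, J)]]
    top_H <- up$bottom_H; top_F <- up$bottom_F
  }
  if (J == 0L) {
    left_H <- integer(mb); left_E <- rep(neg, mb)
  } else {
    lf <- store[[halo_key(I, J - 1L)]]
    left_H <- lf$right_H; left_E <- lf$right_E
  }
  corner_H <- if (I == 0L || J == 0L) 0L else
    store[[halo_key(I - 1L, J - 1L)]]$out_corner_H
  block_boundary(top_H, top_F, left_H, left_E, corner_H)
}

halo_key <- function(I, J) paste0(I, ",", J)

#' Compute one score-matrix block from its halos
#'
#' Evaluates the recursion over a tile given the halo values of its
#' dependency blocks (or the matrix-edge boundary), returning the outgoing
#' halos, the tile-local maximum, and optionally the full `H`/`E`/`F` tile
#' for traceback assembly.
#'
#' @param id Integer pair `c(I, J)` identifying the block (0-based).
#' @param p_slice,q_slice Integer residue codes (or [seq_record()]s) covering
#'   the block's row/column span.
#' @param boundary A [block_boundary()]; vector lengths must match the
#'   slices, otherwise a contract-violation error is raised.
#' @param scheme A [scoring_scheme()].
#' @param keep_tile Return the full tile matrices.
#' @return Object of class `block_result`: `id`, outgoing halos `bottom_H`,
#'   `bottom_F`, `right_H`, `right_E`, `out_corner_H`, `local_max`
#'   (`score`, `i`, `j`, tile-local 1-based), and `H`/`E`/`F` when
#'   `keep_tile`.
#' @export
compute_block <- function(id, p_slice, q_slice, boundary, scheme,
                          keep_tile = FALSE) {
  stopifnot(inherits(boundary, "block_boundary"),
            inherits(scheme, "scoring_scheme"))
  pc <- if (inherits(p_slice, "seq_record")) p_slice$codes else
    as.integer(p_slice)
  qc <- if (inherits(q_slice, "seq_record")) q_slice$codes else
    as.integer(q_slice)
  res <- .sw_block_kernel(pc, qc,
                          boundary$top_H, boundary$top_F,
                          boundary$left_H, boundary$left_E,
                          boundary$corner_H,
                          scheme$match, scheme$mismatch,
                          scheme$gap_open_extend, scheme$gap_extend,
                          keep_tile)
  res$id <- as.integer(id)
  res$local_max <- list(score = res$local_max[1L],
                        i = res$local_max[2L], j = res$local_max[3L])
  class(res) <- "block_result"
  res
}

# Fold a block's local max (tile-local) into the running global optimum,
# preserving the serial tie rule (max score, then min i, then min j).
better_max <- function(best, res, ext) {
  gi <- unname(ext$i0 - 1L + res$local_max$i)
  gj <- unname(ext$j0 - 1L + res$local_max$j)
  s <- res$local_max$score
  if (is.null(best) || s > best$score ||
      (s == best$score && (gi < best$i || (gi == best$i && gj < best$j))))
    list(score = s, i = gi, j = gj)
  else best
}

#' Blockwise wavefront Smith-Waterman alignment
#'
#' Evaluates the score matrix as a grid of tiles, level by level along the
#' antidiagonal wavefront, and returns a result identical to
#' [align_serial()] for every legal block size.  In traceback mode the tiles
#' are assembled into full matrices before backtracking; in `score_only`
#' mode only halos are retained (memory bounded by the wavefront, not the
#' matrix).
#'
#' @inheritParams align_serial
#' @param block_rows,block_cols Tile dimensions (default 256 x 256 cells).
#' @return An `sw_alignment` with a `diagnostics` attribute
#'   (`blocks_computed`, `cells`, `max_halo_entries`).
#' @examples
#' align_blockwise("ATCGACTT", "GATATCTG", scoring_scheme(2, -1, -2),
#'                 block_rows = 2, block_cols = 3)
#' @export
align_blockwise <- function(p, q, scheme = scoring_scheme(),
                            block_rows = 256L, block_cols = 256L,
                            policy = backtrack_policy(),
                            score_only = FALSE) {
  p <- as_seq_record(p); q <- as_seq_record(q)
  m <- p$length; n <- q$length
  grid <- make_grid(m, n, block_rows, block_cols)
  diag_info <- list(blocks_computed = 0L, cells = as.numeric(m) * n,
                    max_halo_entries = 0L)
  if (m == 0L || n == 0L) {
    res <- empty_alignment()
    attr(res, "diagnostics") <- diag_info
    return(res)
  }
  keep <- !score_only
  mats <- if (keep) {
    structure(list(H = matrix(0L, m + 1L, n + 1L),
                   E = matrix(NA_integer_, m + 1L, n + 1L),
                   F = matrix(NA_integer_, m + 1L, n + 1L),
                   m = m, n = n),
              class = "dp_matrices")
  } else NULL
  sched <- wavefront_order(grid)
  store <- list()
  best <- NULL
  for (k in seq_along(sched$levels)) {
    lev <- sched$levels[[k]]
    for (r in seq_len(nrow(lev))) {
      I <- lev[r, "I"]; J <- lev[r, "J"]
      ext <- block_extent(grid, I, J)
      bnd <- gather_boundary(grid, I, J, store)
      res <- compute_block(c(I, J), p$codes[ext$i0:ext$i1],
                           q$codes[ext$j0:ext$j1], bnd, scheme,
                           keep_tile = keep)
      diag_info$blocks_computed <- diag_info$blocks_computed + 1L
      best <- better_max(best, res, ext)
      if (keep) {
        mats$H[(ext$i0:ext$i1) + 1L, (ext$j0:ext$j1) + 1L] <- res$H
        mats$E[(ext$i0:ext$i1) + 1L, (ext$j0:ext$j1) + 1L] <- res$E
        mats$F[(ext$i0:ext$i1) + 1L, (ext$j0:ext$j1) + 1L] <- res$F
        res$H <- res$E <- res$F <- NULL
      }
      store[[halo_key(I, J)]] <- res
    }
    diag_info$max_halo_entries <- max(diag_info$max_halo_entries,
                                      length(store))
    # halos from level k-2 (0-based: k-3 in 1-based list) are fully consumed
    if (k > 2L) {
      old <- sched$levels[[k - 2L]]
      for (r in seq_len(nrow(old)))
        store[[halo_key(old[r, "I"], old[r, "J"])]] <- NULL
    }
  }
  mx <- if (best$score <= 0L)
    list(score = 0L, i = NA_integer_, j = NA_integer_, no_alignment = TRUE)
  else
    list(score = best$score, i = best$i, j = best$j, no_alignment = FALSE)
  out <- finish_alignment(mx, mats, p, q, scheme, policy, score_only)
  attr(out, "diagnostics") <- diag_info
  out
}
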