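#' Fill the Smith-Waterman dynamic-programming matrices
#'
#' Computes the Gotoh three-state recursion for local alignment of `p`
#' (query, rows) against `q` (target, columns).  `H[i, j]` is the best score
#' of a local alignment ending at residues `i` of `p` and `j` of `q`;
#' `E` holds scores ending with a gap in the query (a horizontal move),
#' `F` scores ending with a gap in the target (a vertical move):
#' \deqn{H_{i,j} = \max\{0,\; H_{i-1,j-1} + s(p_i, q_j),\; E_{i,j},\; F_{i,j}\}}
#' \deqn{E_{i,j} = \max\{H_{i,j-1} - G_{oe},\; E_{i,j-1} - G_e\}}
#' \deqn{F_{i,j} = \max\{H_{i-1,j} - G_{oe},\; F_{i-1,j} - G_e\}}
#' with `H` clamped at zero and zero boundary row/column.  The linear gap
#' model is the special case `Goe == Ge`.  All arithmetic is integer; no
#' floating point enters the kernel, so results are bitwise reproducible.
#'
#' @param p,q [seq_record()] objects (or plain strings, coerced).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `dp_matrices`: integer matrices `H`, `E`, `F`
#'   of dimension `(m+1) x (n+1)` (border row/column 0), plus `m` and `n`.
#'   Border entries of `E` and `F`, where those gap states are undefined, are
#'   `NA`.
#' @examples
#' fill_matrices("ATCGACTT", "GATATCTG", scoring_scheme(2, -1, -2))$H
#' @export
fill_matrices <- function(p, q, scheme) {
  p <- as_seq_record(p); q <- as_seq_record(q)
  stopifnot(inherits(scheme, "scoring_scheme"))
  m <- p$length; n <- q$length
  H <- matrix(0L, m + 1L, n + 1L)
  E <- matrix(NA_integer_, m + 1L, n + 1L)
  F_ <- matrix(NA_integer_, m + 1L, n + 1L)
  if (m > 0L && n > 0L) {
    neg <- .neg_sentinel()
    res <- .sw_block_kernel(p$codes, q$codes,
                            top_H = integer(n), top_F = rep(neg, n),
                            left_H = integer(m), left_E = rep(neg, m),
                            corner_H = 0L,
                            match = scheme$match, mismatch = scheme$mismatch,
                            goe = scheme$gap_open_extend,
                            ge = scheme$gap_extend,
                            keep_tile = TRUE)
    H[-1L, -1L] <- res$H
    E[-1L, -1L] <- res$E
    F_[-1L, -1L] <- res$F
  }
  structure(list(H = H, E = E, F = F_, m = m, n = n), class = "dp_matrices")
}

#' Locate the optimal local alignment score
#'
#' Scans `H` for its maximum, the optimal local alignment score `S`.  Ties
#' are broken deterministically by the smallest query position `i`, then the
#' smallest target position `j`.  A matrix with no positive entry means no
#' local alignment scores above zero ("no alignment").
#'
#' @param mats A `dp_matrices` object from [fill_matrices()].
#' @return A list `score` (integer), `i`, `j` (1-based residue end positions,
#'   `NA` when there is no alignment) and `no_alignment` (logical).
#' @export
find_max <- function(mats) {
  stopifnot(inherits(mats, "dp_matrices"))
  H <- mats$H
  s <- max(H)
  if (s <= 0L)
    return(list(score = 0L, i = NA_integer_, j = NA_integer_,
                no_alignment = TRUE))
  idx <- which(H == s)
  ri <- (idx - 1L) %% nrow(H)      # 0-based matrix row == residue index i
  cj <- (idx - 1L) %/% nrow(H)     # 0-based matrix col == residue index j
  k <- order(ri, cj)[1L]
  list(score = s, i = ri[k], j = cj[k], no_alignment = FALSE)
}

# An empty "no alignment" result (score 0, coordinates 0, cigar "*").
empty_alignment <- function(score = 0L) {
  structure(list(score = as.integer(score),
                 query_start = 0L, query_end = 0L,
                 target_start = 0L, target_end = 0L,
                 aligned_query = "", aligned_target = "",
                 cigar = "*", no_alignment = TRUE),
            class = "sw_alignment")
}

ops_to_cigar <- function(ops) {
  if (length(ops) == 0L) return("*")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Backtrack an alignment path
#'
#' Reconstructs the gapped alignment from a starting cell (normally the
#' [find_max()] position) by walking to the predecessor that produced each
#' cell's value — diagonally (match/mismatch), up (gap in the target), or
#' left (gap in the query) — until a cell at or below the policy threshold is
#' reached.  Affine gaps are followed through the `E`/`F` states so that a
#' gap opened once is extended at the extension penalty.  When several
#' predecessors explain a value, the policy's `tie_order` decides.
#'
#' @param mats `dp_matrices` from [fill_matrices()].
#' @param p,q The aligned [seq_record()]s (rows / columns).
#' @param scheme The [scoring_scheme()] used to fill the matrices.
#' @param start Integer vector `c(i, j)`, 1-based residue end positions.
#' @param policy A [backtrack_policy()].
#' @return An object of class `sw_alignment`: `score`, 1-based inclusive
#'   coordinates `query_start`/`query_end`/`target_start`/`target_end`,
#'   gapped strings `aligned_query`/`aligned_target` (`-` = gap) and a
#'   `cigar` over `M` (aligned pair), `I` (gap in target) and `D` (gap in
#'   query).
#' @export
backtrack <- function(mats, p, q, scheme, start,
                      policy = backtrack_policy()) {
  stopifnot(inherits(mats, "dp_matrices"))
  p <- as_seq_record(p); q <- as_seq_record(q)
  i <- as.integer(start[1L]); j <- as.integer(start[2L])
  if (is.na(i) || is.na(j) || i < 0L || j < 0L || i > mats$m || j > mats$n)
    stop("backtrack start out of bounds", call. = FALSE)
  H <- mats$H; E <- mats$E; F_ <- mats$F
  hv <- function(i, j) H[i + 1L, j + 1L]
  ev <- function(i, j) { v <- E[i + 1L, j + 1L]; if (is.na(v)) -Inf else v }
  fv <- function(i, j) { v <- F_[i + 1L, j + 1L]; if (is.na(v)) -Inf else v }
  sub <- function(i, j) {
    a <- p$codes[i]; b <- q$codes[j]
    if (a == b && a > 0L) scheme$match else scheme$mismatch
  }
  score <- hv(i, j)
  thr <- policy$threshold
  if (i == 0L || j == 0L || score <= thr) return(empty_alignment())
  goe <- scheme$gap_open_extend; ge <- scheme$gap_extend
  ops <- character(0L)
  state <- "H"
  end_i <- i; end_j <- j
  repeat {
    if (state == "H") {
      if (i == 0L || j == 0L || hv(i, j) <= thr) break
      moved <- FALSE
      for (mv in policy$tie_order) {
        if (mv == "diagonal" &&
            hv(i, j) == hv(i - 1L, j - 1L) + sub(i, j)) {
          ops <- c(ops, "M"); i <- i - 1L; j <- j - 1L
          moved <- TRUE; break
        } else if (mv == "up" && hv(i, j) == fv(i, j)) {
          state <- "F"; moved <- TRUE; break
        } else if (mv == "left" && hv(i, j) == ev(i, j)) {
          state <- "E"; moved <- TRUE; break
        }
      }
      if (!moved) break       # the zero option produced this cell
    } else if (state == "F") {
      # vertical gap chain: consume p, '-' in target
      ops <- c(ops, "I")
      if (fv(i, j) == hv(i - 1L, j) - goe) state <- "H"
      i <- i - 1L
    } else {                  # state == "E": horizontal gap chain
      ops <- c(ops, "D")
      if (ev(i, j) == hv(i, j - 1L) - goe) state <- "H"
      j <- j - 1L
    }
  }
  ops <- rev(ops)
  pc <- strsplit(p$residues, "", fixed = TRUE)[[1]]
  qc <- strsplit(q$residues, "", fixed = TRUE)[[1]]
  ai <- i; aj <- j
  aq <- character(length(ops)); at <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == "M") {
      ai <- ai + 1L; aj <- aj + 1L
      aq[k] <- pc[ai]; at[k] <- qc[aj]
    } else if (ops[k] == "I") {
      ai <- ai + 1L
      aq[k] <- pc[ai]; at[k] <- "-"
    } else {
      aj <- aj + 1L
      aq[k] <- "-"; at[k] <- qc[aj]
    }
  }
  structure(list(score = score,
                 query_start = i + 1L, query_end = end_i,
                 target_start = j + 1L, target_end = end_j,
                 aligned_query = paste0(aq, collapse = ""),
                 aligned_target = paste0(at, collapse = ""),
                 cigar = ops_to_cigar(ops), no_alignment = FALSE),
            class = "sw_alignment")
}

#' Serial Smith-Waterman local alignment
#'
#' The reference path: [fill_matrices()], [find_max()], then [backtrack()]
#' unless `score_only`.  Every parallel execution mode in the package is
#' required (and tested) to reproduce this result exactly.
#'
#' @inheritParams backtrack
#' @param score_only If `TRUE`, skip traceback: the result carries the score
#'   and the 1-based end coordinates (`query_end`, `target_end`), with start
#'   coordinates 0, empty alignment strings and cigar `"*"`.
#' @return An `sw_alignment` (see [backtrack()]).
#' @examples
#' align_serial("ATCGACTT", "GATATCTG", scoring_scheme(2, -1, -2))
#' @export
align_serial <- function(p, q, scheme = scoring_scheme(),
                         policy = backtrack_policy(), score_only = FALSE) {
  p <- as_seq_record(p); q <- as_seq_record(q)
  if (score_only) {
    # single kernel pass, halo-only memory; the kernel's row-major strict
    # maximum reproduces the find_max tie rule
    m <- p$length; n <- q$length
    if (m == 0L || n == 0L) return(empty_alignment())
    neg <- .neg_sentinel()
    res <- .sw_block_kernel(p$codes, q$codes,
                            top_H = integer(n), top_F = rep(neg, n),
                            left_H = integer(m), left_E = rep(neg, m),
                            corner_H = 0L,
                            match = scheme$match, mismatch = scheme$mismatch,
                            goe = scheme$gap_open_extend,
                            ge = scheme$gap_extend, keep_tile = FALSE)
    mx <- if (res$local_max[1L] <= 0L)
      list(score = 0L, i = NA_integer_, j = NA_integer_,
           no_alignment = TRUE)
    else
      list(score = res$local_max[1L], i = res$local_max[2L],
           j = res$local_max[3L], no_alignment = FALSE)
    return(finish_alignment(mx, NULL, p, q, scheme, policy, TRUE))
  }
  mats <- fill_matrices(p, q, scheme)
  mx <- find_max(mats)
  finish_alignment(mx, mats, p, q, scheme, policy, score_only)
}

# Shared tail of the serial and blockwise paths.
finish_alignment <- function(mx, mats, p, q, scheme, policy, score_only) {
  if (mx$no_alignment) return(empty_alignment())
  if (score_only) {
    res <- empty_alignment(mx$score)
    res$query_end <- mx$i; res$target_end <- mx$j
    res$no_alignment <- FALSE
    return(res)
  }
  backtrack(mats, p, q, scheme, start = c(mx$i, mx$j), policy = policy)
}

#' Re-score a gapped alignment
#'
#' Independently re-derives the score of an alignment from its gapped
#' strings: matches and mismatches per the scheme, each gap run charged
#' `gap_open_extend` for its first position and `gap_extend` for each
#' further one.  Used as a consistency check on traceback output.
#'
#' @param aligned_query,aligned_target Equal-length gapped strings.
#' @param scheme A [scoring_scheme()].
#' @param alphabet Alphabet for residue comparison.
#' @return Integer score.
#' @export
rescore_alignment <- function(aligned_query, aligned_target, scheme,
                              alphabet = dna_alphabet()) {
  a <- strsplit(toupper(aligned_query), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_target), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("aligned strings must have equal length", call. = FALSE)
  if (length(a) == 0L) return(0L)
  if (any(a == "-" & b == "-"))
    stop("gap aligned to gap is invalid", call. = FALSE)
  wc <- alphabet$wildcard
  score <- 0L
  in_gap_q <- FALSE; in_gap_t <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      score <- score - if (in_gap_q) scheme$gap_extend else
        scheme$gap_open_extend
      in_gap_q <- TRUE; in_gap_t <- FALSE
    } else if (b[k] == "-") {
      score <- score - if (in_gap_t) scheme$gap_extend else
        scheme$gap_open_extend
      in_gap_t <- TRUE; in_gap_q <- FALSE
    } else {
      hit <- a[k] == b[k] && (is.null(wc) || a[k] != wc)
      score <- score + if (hit) scheme$match else scheme$mismatch
      in_gap_q <- in_gap_t <- FALSE
    }
  }
  score
}

#' @export
print.sw_alignment <- function(x, ...) {
  if (x$no_alignment) {
    cat("<sw_alignment> no alignment (score 0)\n")
    return(invisible(x))
  }
  cat(sprintf("<sw_alignment> score %d  query %d-%d  target %d-%d  cigar %s\n",
              x$score, x$query_start, x$query_end,
              x$target_start, x$target_end, x$cigar))
  if (nzchar(x$aligned_query)) {
    a <- strsplit(x$aligned_query, "")[[1]]
    b <- strsplit(x$aligned_target, "")[[1]]
    bar <- ifelse(a == b & a != "-", "|", " ")
    cat("  ", x$aligned_query, "\n  ", paste0(bar, collapse = ""),
        "\n  ", x$aligned_target, "\n", sep = "")
  }
  invisible(x)
}
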