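# Independent oracle: top-down recursive evaluation of the three-state local
# alignment recursion with memoization.  Deliberately a different algorithm
# shape from the package's iterative rolling-row kernel; shared code: none.
oracle_matrices <- function(p, q, match, mismatch, goe, ge) {
  pp <- strsplit(toupper(p), "")[[1]]
  qq <- strsplit(toupper(q), "")[[1]]
  m <- length(pp); n <- length(qq)
  Hm <- new.env(parent = emptyenv())
  Em <- new.env(parent = emptyenv())
  Fm <- new.env(parent = emptyenv())
  sub <- function(a, b) {
    if (a == b && a != "N") match else mismatch
  }
  E <- function(i, j) {
    if (j == 0L) return(-Inf)
    k <- paste(i, j)
    v <- Em[[k]]
    if (!is.null(v)) return(v)
    v <- max(H(i, j - 1L) - goe, E(i, j - 1L) - ge)
    Em[[k]] <- v
    v
  }
  Fo <- function(i, j) {
    if (i == 0L) return(-Inf)
    k <- paste(i, j)
    v <- Fm[[k]]
    if (!is.null(v)) return(v)
    v <- max(H(i - 1L, j) - goe, Fo(i - 1L, j) - ge)
    Fm[[k]] <- v
    v
  }
  H <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    k <- paste(i, j)
    v <- Hm[[k]]
    if (!is.null(v)) return(v)
    v <- max(0, H(i - 1L, j - 1L) + sub(pp[i], qq[j]), E(i, j), Fo(i, j))
    Hm[[k]] <- v
    v
  }
  Hmat <- matrix(0, m + 1L, n + 1L)
  Emat <- matrix(-Inf, m + 1L, n + 1L)
  Fmat <- matrix(-Inf, m + 1L, n + 1L)
  if (m > 0L && n > 0L) {
    for (i in seq_len(m)) for (j in seq_len(n)) {
      Hmat[i + 1L, j + 1L] <- H(i, j)
      Emat[i + 1L, j + 1L] <- E(i, j)
      Fmat[i + 1L, j + 1L] <- Fo(i, j)
    }
  }
  list(H = Hmat, E = Emat, F = Fmat)
}

oracle_score <- function(p, q, match, mismatch, goe, ge) {
  max(oracle_matrices(p, q, match, mismatch, goe, ge)$H)
}

# Seeded random DNA strings.
random_dna <- function(len) {
  if (len == 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Compare a package dp_matrices object with the oracle's matrices:
# H everywhere, E and F on the interior (the border gap states are NA in the
# package and -Inf in the oracle, both meaning "undefined").
expect_matches_oracle <- function(mats, orc) {
  expect_identical(unname(mats$H), matrix(as.integer(orc$H), nrow(orc$H)))
  if (mats$m > 0L && mats$n > 0L) {
    expect_identical(matrix(as.numeric(mats$E[-1L, -1L]), mats$m),
                     unname(orc$E[-1L, -1L, drop = FALSE]) * 1)
    expect_identical(matrix(as.numeric(mats$F[-1L, -1L]), mats$m),
                     unname(orc$F[-1L, -1L, drop = FALSE]) * 1)
  }
}

# Strip a classed alignment down to comparable fields.
alignment_fields <- function(a) {
  unclass(a)[c("score", "query_start", "query_end", "target_start",
               "target_end", "aligned_query", "aligned_target", "cigar",
               "no_alignment")]
}

worked_query <- "ATCGACTT"
worked_target <- "GATATCTG"
std_scheme <- function() scoring_scheme(2, -1, -2)
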