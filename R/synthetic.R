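# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable per-record seed: record k of a dataset seeded with `seed` is the
# same regardless of how many records follow it.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Synthetic dataset specification
#'
#' Shapes are stated as a sequence count and a length range; lengths are
#' drawn uniformly over `[min_len, max_len]` and residues uniformly over the
#' alphabet letters (the wildcard is never generated).
#'
#' @param n_sequences Number of sequences, `>= 1`.
#' @param min_len,max_len Length range, `0 <= min_len <= max_len`.
#' @param alphabet An [sw_alphabet()].
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_sequences, min_len, max_len,
                         alphabet = dna_alphabet(), seed = 1L) {
  if (!is.numeric(n_sequences) || n_sequences < 1)
    stop("n_sequences must be >= 1", call. = FALSE)
  if (min_len < 0 || max_len < min_len)
    stop("need 0 <= min_len <= max_len", call. = FALSE)
  structure(list(n_sequences = as.integer(n_sequences),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Generate random sequences
#'
#' @param spec A [dataset_spec()].
#' @param prefix Id prefix; record `k` is named `<prefix><k>`.
#' @return List of [seq_record()]s; identical on every call with the same
#'   spec, and records are stable under growth of `n_sequences`.
#' @examples
#' random_sequences(dataset_spec(3, 10, 20, seed = 42))
#' @export
random_sequences <- function(spec, prefix = "syn") {
  stopifnot(inherits(spec, "dataset_spec"))
  letters_ <- spec$alphabet$letters
  lapply(seq_len(spec$n_sequences), function(k) {
    with_local_seed(derive_seed(spec$seed, k), {
      len <- if (spec$max_len > spec$min_len)
        sample(spec$min_len:spec$max_len, 1L) else spec$min_len
      res <- if (len > 0L)
        paste0(sample(letters_, len, replace = TRUE), collapse = "") else ""
      seq_record(sprintf("%s%d", prefix, k), res, spec$alphabet)
    })
  })
}

#' Mutation specification
#'
#' Per-site edit rates for deriving a mutated copy of a sequence.  Rates
#' must each lie in `[0, 1)` and sum to less than 1.
#'
#' @param sub_rate,ins_rate,del_rate Per-site substitution / insertion /
#'   deletion probabilities.
#' @param seed Integer seed.
#' @return Object of class `mutation_spec`.
#' @export
mutation_spec <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                          seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("rates must lie in [0, 1) and sum to < 1", call. = FALSE)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = as.integer(seed)),
            class = "mutation_spec")
}

#' Derive a mutated copy of a sequence
#'
#' Walks the original once: each site is deleted with `del_rate`,
#' substituted (to a different letter) with `sub_rate`, and followed by an
#' inserted random letter with `ins_rate`.  The true edits are recorded so
#' tests can bound the expected alignment score from the known mutation
#' path.
#'
#' @param seq A [seq_record()].
#' @param spec A [mutation_spec()].
#' @return List: `original`, `mutated` (id suffixed `_mut`), and `edits`, a
#'   data.frame with columns `pos` (1-based position in the original), `op`
#'   (`sub`/`ins`/`del`), `from`, `to`.
#' @export
mutate_pair <- function(seq, spec) {
  stopifnot(inherits(seq, "seq_record"), inherits(spec, "mutation_spec"))
  letters_ <- seq$alphabet$letters
  chars <- if (seq$length > 0L) strsplit(seq$residues, "")[[1]] else
    character(0)
  with_local_seed(spec$seed, {
    out <- character(0)
    edits <- list()
    note <- function(pos, op, from, to)
      edits[[length(edits) + 1L]] <<- data.frame(pos = pos, op = op,
                                                 from = from, to = to)
    for (k in seq_along(chars)) {
      u <- runif(1)
      if (u < spec$del_rate) {
        note(k, "del", chars[k], "")
      } else if (u < spec$del_rate + spec$sub_rate) {
        to <- sample(setdiff(letters_, chars[k]), 1L)
        out <- c(out, to)
        note(k, "sub", chars[k], to)
      } else {
        out <- c(out, chars[k])
      }
      if (runif(1) < spec$ins_rate) {
        ins <- sample(letters_, 1L)
        out <- c(out, ins)
        note(k, "ins", "", ins)
      }
    }
    edits <- if (length(edits)) do.call(rbind, edits) else
      data.frame(pos = integer(0), op = character(0),
                 from = character(0), to = character(0))
    list(original = seq,
         mutated = seq_record(paste0(seq$id, "_mut"),
                              paste0(out, collapse = ""), seq$alphabet),
         edits = edits)
  })
}

# Reduced-scale emulations of the benchmark dataset shapes (sequence counts
# and length ranges of the BRCA1/BRCA2/Titin/heterogeneous gene sets),
# shrunk by the given factors so they are generable and alignable at desk
# scale.
fixture_shapes <- function(scale_n = 0.1, scale_len = 0.1) {
  shapes <- list(
    brca1 = list(n = 300, min = 504, max = 10496),
    brca2 = list(n = 659, min = 85, max = 17977),
    titin = list(n = 700, min = 52968, max = 74778),
    heterogeneous = list(n = 583, min = 716, max = 74675))
  lapply(shapes, function(s)
    list(n = max(2L, as.integer(round(s$n * scale_n))),
         min = max(1L, as.integer(round(s$min * scale_len))),
         max = max(2L, as.integer(round(s$max * scale_len)))))
}

#' Emit the reduced-scale synthetic dataset suite
#'
#' Writes one seeded FASTA per emulated dataset shape into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param scale_n,scale_len Shrink factors for sequence counts and lengths.
#' @return Named character vector of the files written.
#' @export
make_fixture_datasets <- function(dir, seed = 1L, scale_n = 0.1,
                                  scale_len = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shapes <- fixture_shapes(scale_n, scale_len)
  out <- character(0)
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    spec <- dataset_spec(sh$n, sh$min, sh$max,
                         seed = derive_seed(seed, match(nm, names(shapes))))
    recs <- random_sequences(spec, prefix = paste0(nm, "_"))
    path <- file.path(dir, paste0(nm, ".fasta"))
    write_fasta(recs, path)
    out[nm] <- path
  }
  out
}
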