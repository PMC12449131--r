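#' Scoring schemes
#'
#' Scores are integers: `match` is added when two residues are identical,
#' `mismatch` when they differ.  Gap penalties follow the usual sign
#' convention of alignment tools: `gap`, `gap_open` and `gap_extend` are
#' entered as the (typically negative) values printed on a command line and
#' stored internally as non-negative magnitudes that the recursion subtracts.
#' A single `gap` value selects the linear model (every gapped position costs
#' the same); supplying `gap_open` and `gap_extend` selects the affine Gotoh
#' model, where `gap_open` is the combined open-plus-extend cost of the first
#' gapped position and `gap_extend` the cost of each further one.
#'
#' @param match Integer score for identical residues (must exceed `mismatch`).
#' @param mismatch Integer score for differing residues.
#' @param gap Signed linear gap value (e.g. `-2`); ignored when `gap_open`
#'   and `gap_extend` are given.
#' @param gap_open,gap_extend Signed affine gap values; both or neither.
#' @return An object of class `scoring_scheme` with fields `match`,
#'   `mismatch`, `gap_open_extend`, `gap_extend` (magnitudes) and `gap_mode`
#'   (`"linear"` or `"affine"`).
#' @examples
#' scoring_scheme(match = 2, mismatch = -1, gap = -2)
#' scoring_scheme(match = 2, mismatch = -1, gap_open = -4, gap_extend = -1)
#' @export
scoring_scheme <- function(match = 2L, mismatch = -1L, gap = -2L,
                           gap_open = NULL, gap_extend = NULL) {
  as_int <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
      stop(sprintf("%s must be a single integer", nm), call. = FALSE)
    as.integer(x)
  }
  match <- as_int(match, "match"); mismatch <- as_int(mismatch, "mismatch")
  if (match <= mismatch)
    stop("match score must exceed mismatch score", call. = FALSE)
  if (xor(is.null(gap_open), is.null(gap_extend)))
    stop("gap_open and gap_extend must be given together", call. = FALSE)
  if (!is.null(gap_open)) {
    goe <- abs(as_int(gap_open, "gap_open"))
    ge <- abs(as_int(gap_extend, "gap_extend"))
    mode <- "affine"
  } else {
    goe <- ge <- abs(as_int(gap, "gap"))
    mode <- "linear"
  }
  if (goe < ge)
    stop("gap open+extend penalty must be >= gap extend penalty",
         call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open_extend = goe, gap_extend = ge, gap_mode = mode),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> match=%d mismatch=%d %s gap (Goe=%d, Ge=%d)\n",
              x$match, x$mismatch, x$gap_mode,
              x$gap_open_extend, x$gap_extend))
  invisible(x)
}

#' Substitution score of two residues
#'
#' @param a,b Single residues.
#' @param scheme A [scoring_scheme()].
#' @param alphabet Alphabet used to validate the residues.
#' @return `match` if the residues are identical (and not the wildcard),
#'   otherwise `mismatch`.
#' @examples
#' substitution_score("A", "A", scoring_scheme(match = 3, mismatch = 1))
#' @export
substitution_score <- function(a, b, scheme,
                               alphabet = dna_alphabet()) {
  ca <- encode_residues(toupper(a), alphabet, "residue a")
  cb <- encode_residues(toupper(b), alphabet, "residue b")
  if (length(ca) != 1L || length(cb) != 1L)
    stop("a and b must be single residues", call. = FALSE)
  if (ca == cb && ca > 0L) scheme$match else scheme$mismatch
}

#' Traceback policy
#'
#' Backtracking walks from the maximal score-matrix cell to the first cell at
#' or below `threshold` (0 by default), preferring moves in `tie_order` when
#' several predecessors explain a cell's value.
#'
#' @param threshold Non-negative integer stop value.
#' @param tie_order Permutation of `c("diagonal", "up", "left")`.
#' @return An object of class `backtrack_policy`.
#' @export
backtrack_policy <- function(threshold = 0L,
                             tie_order = c("diagonal", "up", "left")) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold != round(threshold))
    stop("threshold must be a non-negative integer", call. = FALSE)
  if (!setequal(tie_order, c("diagonal", "up", "left")) ||
      length(tie_order) != 3L)
    stop("tie_order must be a permutation of diagonal/up/left", call. = FALSE)
  structure(list(threshold = as.integer(threshold),
                 tie_order = as.character(tie_order)),
            class = "backtrack_policy")
}
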