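#' Residue alphabets
#'
#' An alphabet is the set of letters a sequence may use, plus an optional
#' wildcard letter that scores as a mismatch against everything, including
#' itself.  The default DNA alphabet is `A, C, G, T` with wildcard `N`;
#' ambiguity codes beyond `N` are not interpreted.
#'
#' @param letters Character vector of allowed single-character residues
#'   (upper case).
#' @param wildcard Optional single character treated as an always-mismatch
#'   wildcard.
#' @return An object of class `sw_alphabet`.
#' @examples
#' dna_alphabet()
#' sw_alphabet(c("A", "B"))
#' @export
sw_alphabet <- function(letters, wildcard = NULL) {
  letters <- toupper(as.character(letters))
  if (length(letters) < 1L || anyDuplicated(letters) ||
      any(nchar(letters) != 1L))
    stop("alphabet must be distinct single characters", call. = FALSE)
  if (!is.null(wildcard)) {
    wildcard <- toupper(wildcard)
    if (length(wildcard) != 1L || nchar(wildcard) != 1L)
      stop("wildcard must be a single character", call. = FALSE)
    letters <- setdiff(letters, wildcard)
  }
  structure(list(letters = letters, wildcard = wildcard),
            class = "sw_alphabet")
}

#' @rdname sw_alphabet
#' @export
dna_alphabet <- function() sw_alphabet(c("A", "C", "G", "T"), wildcard = "N")

alphabet_chars <- function(alphabet) c(alphabet$letters, alphabet$wildcard)

# Integer-encode residues: wildcard -> 0L, letters -> 1..K.
# Unknown residues raise an invalid-residue error naming the offender.
encode_residues <- function(residues, alphabet, what = "sequence") {
  if (nchar(residues) == 0L) return(integer(0))
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  codes <- match(chars, alphabet$letters)
  if (!is.null(alphabet$wildcard))
    codes[chars == alphabet$wildcard] <- 0L
  bad <- which(is.na(codes))
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  codes
}

#' Identified sequence records
#'
#' A `seq_record` couples a non-empty identifier with a residue string over a
#' declared alphabet.  Residues are case-folded to upper case and validated on
#' construction; empty sequences are legal (they align to everything with
#' score 0).
#'
#' @param id Non-empty identifier string.
#' @param residues Residue string (case-insensitive).
#' @param alphabet An [sw_alphabet()]; defaults to DNA with `N` wildcard.
#' @return An object of class `seq_record` with fields `id`, `residues`,
#'   `length`, `codes` (integer encoding) and `alphabet`.
#' @examples
#' seq_record("s1", "ATCGACTT")
#' @export
seq_record <- function(id, residues, alphabet = dna_alphabet()) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("sequence id must be a non-empty string", call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("residues must be a single string", call. = FALSE)
  residues <- toupper(residues)
  codes <- encode_residues(residues, alphabet, what = sprintf("record '%s'", id))
  structure(list(id = id, residues = residues, length = nchar(residues),
                 codes = codes, alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  shown <- if (x$length > 60L) paste0(substr(x$residues, 1L, 57L), "...")
           else x$residues
  cat(sprintf("<seq_record> %s (%d nt): %s\n", x$id, x$length, shown))
  invisible(x)
}

as_seq_record <- function(x, alphabet = dna_alphabet()) {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(seq_record(if (is.null(names(x))) "seq" else names(x), x, alphabet))
  stop("cannot interpret object as a seq_record", call. = FALSE)
}
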