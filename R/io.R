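#' Read sequences from a FASTA file
#'
#' Parses standard multi-line FASTA (via Biostrings), taking the header text
#' after `>` up to the first whitespace as the id.  Residues are case-folded
#' to upper case and validated against the alphabet; duplicate ids are
#' rejected; blank lines are ignored.  An empty file yields an empty list
#' with a warning.  A file whose first content is not a `>` header raises a
#' parse error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param alphabet An [sw_alphabet()].
#' @return List of [seq_record()]s.
#' @export
read_fasta <- function(path, alphabet = dna_alphabet()) {
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) {
    warning(sprintf("empty FASTA file: %s", path), call. = FALSE)
    return(list())
  }
  first <- content[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("%s: line %d: sequence data before any '>' header",
                 path, first), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop(sprintf("%s: record %d has an empty id", path,
                 which(!nzchar(ids))[1L]), call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate sequence id '%s'", path,
                 ids[duplicated(ids)][1L]), call. = FALSE)
  out <- vector("list", length(set))
  for (k in seq_along(set))
    out[[k]] <- seq_record(ids[k], as.character(set[[k]]), alphabet)
  out
}

#' Write sequences to a FASTA file
#'
#' @param records List of [seq_record()]s.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  seqs <- Biostrings::BStringSet(vapply(records, function(s) s$residues,
                                        character(1)))
  names(seqs) <- vapply(records, function(s) s$id, character(1))
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Tabulate a job report
#'
#' One row per task: `query_id`, `target_id`, `score`, `q_start`, `q_end`,
#' `t_start`, `t_end`, `cigar`, `status`.  Coordinates are 1-based
#' inclusive; a "no alignment" result (and a failed task) renders
#' coordinates as 0 and cigar `*`.
#'
#' @param report A [run_job()] report.
#' @return A data.frame of output records.
#' @export
report_records <- function(report) {
  stopifnot(inherits(report, "job_report"))
  rows <- lapply(report$results, function(r) {
    a <- r$alignment
    if (identical(r$status, "ok") && !is.null(a)) {
      data.frame(query_id = r$query_id, target_id = r$target_id,
                 score = a$score, q_start = a$query_start,
                 q_end = a$query_end, t_start = a$target_start,
                 t_end = a$target_end, cigar = a$cigar, status = "ok")
    } else {
      data.frame(query_id = r$query_id, target_id = r$target_id,
                 score = 0L, q_start = 0L, q_end = 0L, t_start = 0L,
                 t_end = 0L, cigar = "*", status = "failed")
    }
  })
  if (length(rows) == 0L)
    return(data.frame(query_id = character(0), target_id = character(0),
                      score = integer(0), q_start = integer(0),
                      q_end = integer(0), t_start = integer(0),
                      t_end = integer(0), cigar = character(0),
                      status = character(0)))
  do.call(rbind, rows)
}

#' Write alignment results
#'
#' `tsv` emits a header line then one tab-separated row per record in the
#' exact column order of [report_records()]; `pretty` emits the gapped
#' alignment pairs with a `|` match line.
#'
#' @param records Data.frame from [report_records()], or a [run_job()]
#'   report (converted).
#' @param path Output path (or `""` for stdout).
#' @param format `"tsv"` or `"pretty"`.
#' @export
write_results <- function(records, path, format = c("tsv", "pretty")) {
  format <- match.arg(format)
  if (inherits(records, "job_report")) {
    report <- records
    records <- report_records(report)
  } else report <- NULL
  if (format == "tsv") {
    write.table(records, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  } else {
    if (is.null(report))
      stop("pretty format needs the full job report", call. = FALSE)
    con <- if (nzchar(path)) file(path, "w") else stdout()
    if (nzchar(path)) on.exit(close(con))
    for (r in report$results) {
      a <- r$alignment
      writeLines(sprintf("# %s vs %s", r$query_id, r$target_id), con)
      if (identical(r$status, "ok") && !is.null(a) && !a$no_alignment) {
        writeLines(sprintf("score %d  query %d-%d  target %d-%d  cigar %s",
                           a$score, a$query_start, a$query_end,
                           a$target_start, a$target_end, a$cigar), con)
        if (nzchar(a$aligned_query)) {
          ac <- strsplit(a$aligned_query, "")[[1]]
          bc <- strsplit(a$aligned_target, "")[[1]]
          bar <- ifelse(ac == bc & ac != "-", "|", " ")
          writeLines(c(a$aligned_query, paste0(bar, collapse = ""),
                       a$aligned_target, ""), con)
        }
      } else if (identical(r$status, "ok")) {
        writeLines(c("no alignment (score 0)", ""), con)
      } else {
        writeLines(c(sprintf("FAILED: %s", r$error), ""), con)
      }
    }
  }
  invisible(path)
}
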