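#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a protein
#' record data frame.  Sequences are uppercased, stop (`*`) and gap (`-`)
#' characters are stripped with a warning, and the ambiguity letters
#' B, Z, U, O and J are normalized to the single wildcard `X` so that every
#' sequence is written over a 21-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with character columns `id` (the first whitespace
#'   delimited token of each header) and `sequence`, one row per record, in
#'   file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV", ">p2", "mk", "vl"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1)
  sequences <- toupper(as.character(seqs))
  protein_records(ids, sequences)
}

#' Assemble and validate a protein record collection
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of amino-acid sequences (normalized to
#'   the 21-letter alphabet; see [read_fasta()]).
#' @return A validated `data.frame` with columns `id` and `sequence`.
#' @export
protein_records <- function(id, sequence) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  stopifnot(length(id) == length(sequence))
  if (any(!nzchar(id)) || anyNA(id)) {
    stop("protein ids must be non-empty")
  }
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  }
  n_strip <- sum(lengths(regmatches(sequence, gregexpr("[*-]", sequence))))
  if (n_strip > 0) {
    warning("stripped ", n_strip, " stop ('*') / gap ('-') character(s)")
    sequence <- gsub("[*-]", "", sequence)
  }
  sequence <- chartr("BZUOJ", "XXXXX", sequence)
  bad <- grepl(sprintf("[^%s]", paste(AA_FULL, collapse = "")), sequence)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ",
         paste(utils::head(id[bad], 5), collapse = ", "))
  }
  empty <- !nzchar(sequence)
  if (any(empty)) {
    stop("empty sequence for id(s): ",
         paste(utils::head(id[empty], 5), collapse = ", "))
  }
  data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records A protein record data frame (`id`, `sequence`).
#' @param path Output file path.
#' @param width Line-wrap width in residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  seqs <- Biostrings::BStringSet(records$sequence)
  names(seqs) <- records$id
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Write a tab-separated score report
#'
#' Emits one row per scored protein with a fixed six-decimal score format,
#' preserving input order, under the header `id  score  predicted_label`.
#'
#' @param records A data frame with columns `id`, `score` (in \[0, 1\]) and
#'   `label` (0/1).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(records, path) {
  stopifnot(all(c("id", "score", "label") %in% names(records)))
  if (nrow(records) > 0 &&
      (any(records$score < 0) || any(records$score > 1))) {
    stop("scores must lie in [0, 1]")
  }
  lines <- c("id\tscore\tpredicted_label",
             if (nrow(records) > 0) {
               sprintf("%s\t%.6f\t%d", records$id, records$score,
                       as.integer(records$label))
             })
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
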