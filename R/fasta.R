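#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record amino-acid FASTA file into a
#' protein tibble. The record identifier is the first whitespace-delimited
#' token of the `>` header line; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta_proteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  tibble::tibble(id = ids, sequence = unname(toupper(as.character(ss))))
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_proteins <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Validate protein sequences against the 20-letter alphabet
#'
#' Checks each sequence for characters outside the 20 standard amino-acid
#' letters. In strict mode (default) an offending record raises an error that
#' names the record and the first offending position; in lenient mode the
#' non-standard letters (such as X, B, Z, U) are stripped before any
#' downstream use.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param lenient If `TRUE`, strip non-standard letters instead of erroring.
#' @return The validated (possibly cleaned) protein tibble.
#' @export
validate_proteins <- function(proteins, lenient = FALSE) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  seqs <- toupper(proteins$sequence)
  if (any(!nzchar(seqs))) {
    rlang::abort(paste0(
      "empty sequence for record(s): ",
      paste(proteins$id[!nzchar(seqs)], collapse = ", ")
    ))
  }
  bad_pos <- vapply(
    strsplit(seqs, ""),
    function(ch) {
      w <- which(!ch %in% AA20)
      if (length(w)) w[1] else 0L
    },
    integer(1)
  )
  if (any(bad_pos > 0L)) {
    if (lenient) {
      seqs <- vapply(
        strsplit(seqs, ""),
        function(ch) paste(ch[ch %in% AA20], collapse = ""),
        character(1)
      )
    } else {
      i <- which(bad_pos > 0L)[1]
      rlang::abort(sprintf(
        "non-standard residue '%s' at position %d of record '%s' (use lenient = TRUE to strip)",
        substr(seqs[i], bad_pos[i], bad_pos[i]), bad_pos[i], proteins$id[i]
      ))
    }
  }
  dplyr::mutate(proteins, sequence = seqs)
}
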