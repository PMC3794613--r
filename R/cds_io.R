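# Reading, validating and codonizing coding sequences.

#' Split a nucleotide string into codons
#'
#' @param sequence Nucleotide string (DNA or RNA letters; normalized to RNA).
#' @param frame_offset 0-based offset of the reading frame (0, 1 or 2).
#' @return Character vector of non-overlapping triplets starting at
#'   `frame_offset`; a trailing partial triplet is dropped with a warning.
#' @examples
#' codonize("AUGGGG")         # "AUG" "GGG"
#' codonize("AAUGGGG", 1)     # "AUG" "GGG"
#' @export
codonize <- function(sequence, frame_offset = 0L) {
  stopifnot(frame_offset >= 0L, frame_offset <= 2L)
  s <- normalize_rna(sequence)
  n <- nchar(s)
  usable <- n - frame_offset
  if (usable < 3L) {
    if (usable > 0L) warning("trailing partial triplet dropped")
    return(character(0))
  }
  n_codons <- usable %/% 3L
  if (usable %% 3L != 0L) warning("trailing partial triplet dropped")
  starts <- frame_offset + 1L + 3L * (seq_len(n_codons) - 1L)
  substring(s, starts, starts + 2L)
}

# Build a validated coding_sequence from raw codons; returns NULL (with a
# recorded reason) when the record is unusable under the lenient policy.
make_coding_sequence <- function(id, codons, source_length_nt) {
  structure(list(id = id, codons = codons,
                 source_length_nt = as.integer(source_length_nt)),
            class = "coding_sequence")
}

#' Construct a coding sequence from a nucleotide string
#'
#' Convenience constructor applying the same normalization as
#' [read_cds_fasta()]: T -> U, terminal stop codon stripped, codons with
#' ambiguity letters replaced by `NA` placeholders (so downstream dicodon
#' counting can exclude the windows that overlap them).
#'
#' @param id Record identifier.
#' @param sequence Nucleotide string.
#' @param frame_offset 0-based frame offset passed to [codonize()].
#' @return A `coding_sequence` object with fields `id`, `codons` and
#'   `source_length_nt`.
#' @export
coding_sequence <- function(id, sequence, frame_offset = 0L) {
  s <- normalize_rna(sequence)
  codons <- codonize(s, frame_offset)
  if (length(codons) && codons[length(codons)] %in% stop_codons)
    codons <- codons[-length(codons)]
  if (length(codons) == 0L) stop(sprintf("record '%s': no codons", id))
  codons[grepl("[^ACGU]", codons)] <- NA_character_
  make_coding_sequence(id, codons, nchar(s) - frame_offset)
}

#' Bundle coding sequences into a transcriptome
#'
#' @param records List of `coding_sequence` objects.
#' @param label Free-text label.
#' @return A `transcriptome` object (list with `records`, `label`).
#' @export
transcriptome <- function(records, label = "unlabeled") {
  if (length(records) == 0L) stop("transcriptome is empty")
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate record ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = records, label = label), class = "transcriptome")
}

#' Read coding sequences from a FASTA file
#'
#' Sequences are taken to be CDSs in frame from the configured offset. T is
#' normalized to U, a terminal stop codon is stripped, and codons containing
#' ambiguity letters (N etc.) are masked so that dicodon windows overlapping
#' them are excluded downstream.
#'
#' @param path FASTA file (plain or gzip-compressed).
#' @param policy `"strict"` errors on any invalid record (length not a
#'   multiple of 3, internal stop codon); `"lenient"` truncates at the first
#'   internal stop, tolerates trailing partial codons, and skips records that
#'   end up empty, counting them in the `skipped` attribute.
#' @param frame_offset 0-based reading-frame offset applied to every record.
#' @param label Transcriptome label; defaults to the file name.
#' @return A `transcriptome`.
#' @export
read_cds_fasta <- function(path, policy = c("strict", "lenient"),
                           frame_offset = 0L, label = NULL) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- basename(path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  records <- list()
  skipped <- character(0)
  for (i in seq_along(seqs)) {
    s <- normalize_rna(as.character(seqs[[i]]))
    usable <- nchar(s) - frame_offset
    if (policy == "strict" && usable %% 3L != 0L)
      stop(sprintf("record '%s': length not multiple of 3", ids[i]))
    codons <- suppressWarnings(codonize(s, frame_offset))
    if (length(codons) && codons[length(codons)] %in% stop_codons)
      codons <- codons[-length(codons)]
    internal_stop <- which(codons %in% stop_codons)
    if (length(internal_stop)) {
      if (policy == "strict")
        stop(sprintf("record '%s': internal stop codon at codon %d",
                     ids[i], internal_stop[1]))
      codons <- codons[seq_len(internal_stop[1] - 1L)]
    }
    if (length(codons) == 0L) {
      if (policy == "strict") stop(sprintf("record '%s': no codons", ids[i]))
      skipped <- c(skipped, ids[i])
      next
    }
    codons[grepl("[^ACGU]", codons)] <- NA_character_
    records[[length(records) + 1L]] <-
      make_coding_sequence(ids[i], codons, usable)
  }
  if (length(skipped))
    warning(length(skipped), " record(s) skipped: ",
            paste(skipped, collapse = ", "))
  out <- transcriptome(records, label)
  attr(out, "skipped") <- skipped
  out
}

#' Write a transcriptome to FASTA
#'
#' @param t A `transcriptome`.
#' @param path Output FASTA path.
#' @param alphabet `"RNA"` (default) or `"DNA"` letters in the output.
#' @param append_stop Append a UAA stop codon to every record (so that a
#'   write/read round trip through [read_cds_fasta()] strict validation
#'   reproduces the codon lists exactly).
#' @export
write_cds_fasta <- function(t, path, alphabet = c("RNA", "DNA"),
                            append_stop = TRUE) {
  stopifnot(inherits(t, "transcriptome"))
  alphabet <- match.arg(alphabet)
  seqs <- vapply(t$records, function(r) {
    codons <- r$codons
    codons[is.na(codons)] <- "NNN"
    s <- paste(codons, collapse = "")
    if (append_stop) s <- paste0(s, "UAA")
    if (alphabet == "DNA") chartr("U", "T", s) else s
  }, character(1))
  names(seqs) <- vapply(t$records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @export
print.transcriptome <- function(x, ...) {
  lens <- vapply(x$records, function(r) length(r$codons), integer(1))
  cat(sprintf("Transcriptome '%s': %d records, %d-%d codons (median %d)\n",
              x$label, length(x$records), min(lens), max(lens),
              as.integer(stats::median(lens))))
  invisible(x)
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("Coding sequence '%s': %d codons (%d nt source)\n",
              x$id, length(x$codons), x$source_length_nt))
  invisible(x)
}
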