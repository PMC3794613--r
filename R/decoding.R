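# Isoacceptor sets, tRNA-pair enumeration and codon -> isoacceptor assignment.

special_aa_labels <- c("iMet", "fMet", "SeC", "Sec", "Sup")

#' Construct an isoacceptor set
#'
#' An isoacceptor is a tRNA species identified by its amino acid and anticodon.
#' The set is the universe from which unordered tRNA pairs are enumerated and
#' from which codons are assigned a decoder.
#'
#' @param amino_acid Character vector of 3-letter amino-acid codes.
#' @param anticodon Character vector of anticodon 3-mers (5'->3'); DNA letters
#'   are normalized to RNA (T -> U).
#' @param gene_count Optional non-negative integer vector (gene copies per
#'   isoacceptor); defaults to 1 for every member.
#' @param species_label Free-text label for the set.
#'
#' @return An object of class `isoacceptor_set`: a data frame with columns
#'   `amino_acid`, `anticodon`, `gene_count` and canonical `id`
#'   (`"<AA>-<anticodon>"`), one row per unique (amino acid, anticodon) pair.
#'   Duplicate rows are merged with gene counts summed.
#' @examples
#' iso <- isoacceptor_set(c("Ile", "Gly"), c("UAU", "CCC"))
#' iso$id
#' @export
isoacceptor_set <- function(amino_acid, anticodon, gene_count = NULL,
                            species_label = "unlabeled") {
  if (length(amino_acid) == 0L) stop("no isoacceptors")
  if (length(anticodon) != length(amino_acid))
    stop("amino_acid and anticodon lengths differ")
  if (is.null(gene_count)) gene_count <- rep(1L, length(amino_acid))
  anticodon <- normalize_rna(anticodon)
  bad <- which(nchar(anticodon) != 3L | grepl("[^ACGU]", anticodon))
  if (length(bad))
    stop(sprintf("malformed anticodon in row %d: '%s'", bad[1], anticodon[bad[1]]))
  known <- c(unname(aa_three_letter), special_aa_labels)
  unknown <- setdiff(unique(amino_acid), known)
  if (length(unknown))
    stop("unknown amino-acid code(s): ", paste(unknown, collapse = ", "))
  if (any(gene_count < 0)) stop("gene_count must be non-negative")

  key <- paste(amino_acid, anticodon, sep = "-")
  agg <- rowsum(as.numeric(gene_count), key)
  ord <- sort(rownames(agg))
  first <- match(ord, key)
  out <- data.frame(
    amino_acid = amino_acid[first],
    anticodon = anticodon[first],
    gene_count = as.integer(agg[ord, 1L]),
    id = ord,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, species_label = species_label,
            class = c("isoacceptor_set", "data.frame"))
}

#' Parse a tab-separated isoacceptor table
#'
#' Reads a gtRNAdb-style species table with header columns `amino_acid`,
#' `anticodon` and optional `gene_count`. Rows for initiator Met or
#' selenocysteine tRNAs are excluded by default: only elongator isoacceptors
#' take part in dicodon decoding at adjacent ribosomal sites.
#'
#' @param file Path to a TSV file, or a connection.
#' @param species_label Label stored on the returned set; defaults to the
#'   file name.
#' @param include_special Keep initiator-Met / Sec rows (`FALSE` by default).
#' @return An [isoacceptor_set()].
#' @export
parse_isoacceptor_table <- function(file, species_label = NULL,
                                    include_special = FALSE) {
  if (is.null(species_label))
    species_label <- if (is.character(file)) basename(file) else "stream"
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 0L) stop("no isoacceptors")
  need <- c("amino_acid", "anticodon")
  if (!all(need %in% names(tab)))
    stop("isoacceptor table must have columns: amino_acid, anticodon")
  gc <- if ("gene_count" %in% names(tab)) tab$gene_count else rep(1L, nrow(tab))
  gc[is.na(gc)] <- 1L
  keep <- rep(TRUE, nrow(tab))
  if (!include_special) keep <- !(tab$amino_acid %in% special_aa_labels)
  if (!any(keep)) stop("no isoacceptors")
  out <- isoacceptor_set(tab$amino_acid[keep], tab$anticodon[keep],
                         gc[keep], species_label)
  attr(out, "n_excluded_special") <- sum(!keep)
  out
}

#' Path to the packaged synthetic mammalian-like isoacceptor table
#'
#' A synthetic 48-isoacceptor elongator repertoire modeled on the typical
#' anticodon usage of mammalian genomes (not a copy of any database export).
#' Together with the default wobble rules it decodes all 61 sense codons.
#'
#' @return File path of the TSV table.
#' @export
synthetic_trna_table <- function() {
  system.file("extdata", "synthetic_mammalian_trna.tsv",
              package = "dicodon", mustWork = TRUE)
}

#' Canonical identifier of an unordered tRNA pair
#'
#' @param id1,id2 Isoacceptor ids. Vectors are accepted elementwise.
#' @return `"<lo>:<hi>"` with the two ids in lexicographic order, so that
#'   `pair_id(a, b) == pair_id(b, a)`.
#' @export
pair_id <- function(id1, id2) {
  lo <- ifelse(id1 <= id2, id1, id2)
  hi <- ifelse(id1 <= id2, id2, id1)
  paste(lo, hi, sep = ":")
}

#' Enumerate all distinct unordered tRNA pairs
#'
#' For an n-isoacceptor set there are (n^2 - n)/2 + n distinct unordered pairs
#' (heterotypic pairs plus the n homotypic ones).
#'
#' @param set An [isoacceptor_set()].
#' @return Object of class `trna_pairs`: a data frame with columns `first_id`,
#'   `second_id` (lexicographically ordered within each row), `pair_id` and
#'   `homotypic`, in canonical lexicographic order.
#' @examples
#' iso <- isoacceptor_set(c("Ile", "Gly", "Pro"), c("UAU", "CCC", "AGG"))
#' nrow(enumerate_pairs(iso))  # (9 - 3)/2 + 3 = 6
#' @export
enumerate_pairs <- function(set) {
  stopifnot(inherits(set, "isoacceptor_set"))
  ids <- sort(set$id)
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- data.frame(
    first_id = ids[idx[, 1L]],
    second_id = ids[idx[, 2L]],
    stringsAsFactors = FALSE
  )
  out$pair_id <- paste(out$first_id, out$second_id, sep = ":")
  out$homotypic <- out$first_id == out$second_id
  structure(out, class = c("trna_pairs", "data.frame"))
}

#' Decoding rules for codon -> isoacceptor assignment
#'
#' Watson-Crick reading at the codon 3rd / anticodon 34 position is always
#' allowed; the wobble matrix adds the extra 3rd-position bases each anticodon
#' 34 base can read. The defaults follow the classical wobble scheme with A34
#' interpreted as inosine: G34 -> {C, U}, U34 -> {A, G}, C34 -> {G},
#' A34 (I34) -> {U, C, A}.
#'
#' @param wobble Named list mapping anticodon-34 base to the codon 3rd bases it
#'   reads (Watson-Crick partners are added automatically).
#' @param overrides Optional data frame with columns `codon`, `isoacceptor_id`;
#'   overrides take absolute precedence over rule-based assignment.
#' @param require_amino_acid_match If `TRUE` (default) an isoacceptor only
#'   decodes codons of its own amino acid, so wobble can never cross into a
#'   different residue (e.g. U34 of Ile-UAU never reads the Met codon AUG).
#' @return Object of class `decoding_rules`.
#' @export
decoding_rules <- function(wobble = list(G = c("C", "U"), U = c("A", "G"),
                                         C = "G", A = c("U", "C", "A")),
                           overrides = NULL,
                           require_amino_acid_match = TRUE) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  reading <- lapply(rna_bases, function(b) {
    extra <- if (b %in% names(wobble)) wobble[[b]] else character(0)
    unique(c(wc[[b]], extra))
  })
  names(reading) <- rna_bases
  if (!is.null(overrides)) {
    if (!all(c("codon", "isoacceptor_id") %in% names(overrides)))
      stop("overrides must have columns codon, isoacceptor_id")
    overrides$codon <- normalize_rna(overrides$codon)
  }
  structure(list(reading = reading, overrides = overrides,
                 require_amino_acid_match = require_amino_acid_match),
            class = "decoding_rules")
}

#' Parse a codon -> isoacceptor override table
#'
#' @param file TSV with header `codon`, `isoacceptor_id`.
#' @return Data frame usable as the `overrides` argument of [decoding_rules()].
#' @export
parse_override_table <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("codon", "isoacceptor_id") %in% names(tab)))
    stop("override table must have columns: codon, isoacceptor_id")
  tab$codon <- normalize_rna(tab$codon)
  tab
}

#' Assign a decoding isoacceptor to every sense codon
#'
#' Builds a deterministic total mapping from the 61 sense codons to a single
#' isoacceptor id each (or marks the codon unassignable when no member of the
#' set can decode it). Candidate decoders must pair Watson-Crick at codon
#' positions 1-2 (anticodon 36-35); the codon 3rd position may be read
#' Watson-Crick or by wobble per the rules. When several candidates remain the
#' priority is: explicit override > exact Watson-Crick > wobble; remaining ties
#' are broken by higher gene count, then lexicographic anticodon.
#'
#' @param set An [isoacceptor_set()].
#' @param rules A [decoding_rules()] object.
#' @return Object of class `codon_assignment`: list with `table` (named
#'   character vector codon -> isoacceptor id over assigned codons),
#'   `unassignable` (character vector of sense codons with no decoder) and
#'   `log` (data frame with the mechanism and candidate count per codon).
#' @examples
#' iso <- isoacceptor_set(c("Ile", "Ile"), c("UAU", "AAU"))
#' a <- build_codon_assignment(iso)
#' a$table[["AUA"]]  # Watson-Crick decoder wins: "Ile-UAU"
#' @export
build_codon_assignment <- function(set, rules = decoding_rules()) {
  stopifnot(inherits(set, "isoacceptor_set"), inherits(rules, "decoding_rules"))
  codons <- sense_codons()
  wc_codon <- rna_revcomp(set$anticodon)    # codon each anticodon reads WC
  aa_of_codon <- codon_amino_acid(codons)
  base34 <- substr(set$anticodon, 1L, 1L)

  ov <- rules$overrides
  if (!is.null(ov)) {
    missing_ids <- setdiff(ov$isoacceptor_id, set$id)
    if (length(missing_ids))
      stop("override names unknown isoacceptor: ",
           paste(missing_ids, collapse = ", "))
    bad_codon <- setdiff(ov$codon, codons)
    if (length(bad_codon))
      stop("override names non-sense codon: ", paste(bad_codon, collapse = ", "))
  }

  assigned <- character(0)
  unassignable <- character(0)
  log <- vector("list", length(codons))
  for (k in seq_along(codons)) {
    codon <- codons[k]
    if (!is.null(ov) && codon %in% ov$codon) {
      id <- ov$isoacceptor_id[match(codon, ov$codon)]
      assigned[codon] <- id
      log[[k]] <- data.frame(codon = codon, isoacceptor_id = id,
                             mechanism = "override", n_candidates = 1L,
                             stringsAsFactors = FALSE)
      next
    }
    head2_ok <- substr(wc_codon, 1L, 2L) == substr(codon, 1L, 2L)
    third_ok <- vapply(seq_len(nrow(set)), function(i)
      substr(codon, 3L, 3L) %in% rules$reading[[base34[i]]], logical(1))
    cand <- head2_ok & third_ok
    if (rules$require_amino_acid_match)
      cand <- cand & set$amino_acid == aa_of_codon[k]
    if (!any(cand)) {
      unassignable <- c(unassignable, codon)
      log[[k]] <- data.frame(codon = codon, isoacceptor_id = NA_character_,
                             mechanism = "unassignable", n_candidates = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    idx <- which(cand)
    is_wc <- wc_codon[idx] == codon
    ord <- order(!is_wc, -set$gene_count[idx], set$anticodon[idx])
    pick <- idx[ord[1L]]
    assigned[codon] <- set$id[pick]
    log[[k]] <- data.frame(
      codon = codon, isoacceptor_id = set$id[pick],
      mechanism = if (wc_codon[pick] == codon) "watson_crick" else "wobble",
      n_candidates = length(idx), stringsAsFactors = FALSE)
  }
  structure(list(table = assigned, unassignable = unassignable,
                 log = do.call(rbind, log), set_ids = sort(set$id)),
            class = "codon_assignment")
}

#' Export a codon assignment as TSV
#'
#' Writes one row per sense codon (`codon<TAB>isoacceptor_id`, empty id for
#' unassignable codons), preceded by one comment line per wobble-resolved
#' codon.
#'
#' @param assignment A `codon_assignment`.
#' @param file Output path.
#' @export
write_codon_assignment <- function(assignment, file) {
  stopifnot(inherits(assignment, "codon_assignment"))
  log <- assignment$log
  wob <- log[log$mechanism == "wobble", , drop = FALSE]
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(wob)))
    writeLines(sprintf("# wobble: %s -> %s (%d candidates)",
                       wob$codon[i], wob$isoacceptor_id[i],
                       wob$n_candidates[i]), con)
  writeLines("codon\tisoacceptor_id", con)
  ids <- assignment$table[sense_codons()]
  ids[is.na(ids)] <- ""
  writeLines(paste(sense_codons(), ids, sep = "\t"), con)
  invisible(file)
}

#' @export
print.isoacceptor_set <- function(x, ...) {
  cat(sprintf("Isoacceptor set '%s': %d members\n",
              attr(x, "species_label"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
print.codon_assignment <- function(x, ...) {
  cat(sprintf("Codon assignment: %d assigned, %d unassignable\n",
              length(x$table), length(x$unassignable)))
  mech <- table(x$log$mechanism)
  cat(paste(sprintf("  %s: %d", names(mech), mech), collapse = "\n"), "\n")
  invisible(x)
}
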