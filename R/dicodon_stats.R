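# Dicodon counting and conversion to unordered isoacceptor-pair frequencies.
#
# A dicodon is an ordered pair of adjacent codons; during elongation its two
# codons occupy the ribosome's P and A sites simultaneously, so the two
# decoding tRNAs are present on the ribosome together. Pair statistics are
# therefore accumulated over unordered isoacceptor pairs.

dicodon_keys <- function(codons) {
  a <- codons[-length(codons)]
  b <- codons[-1L]
  ok <- !is.na(a) & !is.na(b)
  paste(a[ok], b[ok], sep = ":")
}

#' Count overlapping dicodons
#'
#' Slides a window of width 2 codons, step 1, over each record's codon list.
#' Windows never span record boundaries, and windows overlapping a masked
#' (ambiguous) codon are excluded.
#'
#' @param x A `coding_sequence` or a `transcriptome`.
#' @return Object of class `dicodon_counts`: list with `counts` (named integer
#'   vector keyed `"<codon1>:<codon2>"`) and `total` (sum of counts).
#' @examples
#' cs <- coding_sequence("x", "AUGAUAAUAUAA")
#' count_dicodons(cs)$counts   # AUG:AUA and AUA:AUA, once each
#' @export
count_dicodons <- function(x) {
  keys <- if (inherits(x, "coding_sequence")) {
    dicodon_keys(x$codons)
  } else if (inherits(x, "transcriptome")) {
    unlist(lapply(x$records, function(r) dicodon_keys(r$codons)),
           use.names = FALSE)
  } else stop("x must be a coding_sequence or transcriptome")
  if (length(keys) == 0L) {
    counts <- integer(0)
  } else {
    tab <- table(keys)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(list(counts = counts, total = sum(counts)),
            class = "dicodon_counts")
}

#' Aggregate dicodon counts into unordered tRNA-pair counts
#'
#' Each ordered dicodon (x, y) contributes its count to the unordered pair
#' {assign(x), assign(y)}; dicodons containing a codon the assignment cannot
#' decode are tallied in `dropped`.
#'
#' @param d A `dicodon_counts` object.
#' @param assignment A `codon_assignment`.
#' @return Object of class `pair_counts`: list with `counts` (named integer
#'   keyed by [pair_id()]), `total` and `dropped`;
#'   `total + dropped == d$total` always.
#' @export
aggregate_pair_counts <- function(d, assignment) {
  stopifnot(inherits(d, "dicodon_counts"), inherits(assignment, "codon_assignment"))
  if (length(d$counts) == 0L)
    return(structure(list(counts = integer(0), total = 0L, dropped = 0L),
                     class = "pair_counts"))
  parts <- strsplit(names(d$counts), ":", fixed = TRUE)
  c1 <- vapply(parts, `[`, character(1), 1L)
  c2 <- vapply(parts, `[`, character(1), 2L)
  id1 <- unname(assignment$table[c1])
  id2 <- unname(assignment$table[c2])
  ok <- !is.na(id1) & !is.na(id2)
  dropped <- sum(d$counts[!ok])
  if (!any(ok))
    return(structure(list(counts = integer(0), total = 0L,
                          dropped = as.integer(dropped)),
                     class = "pair_counts"))
  keys <- pair_id(id1[ok], id2[ok])
  agg <- rowsum(as.numeric(d$counts[ok]), keys)
  counts <- as.integer(agg[, 1L])
  names(counts) <- rownames(agg)
  counts <- counts[sort(names(counts))]
  structure(list(counts = counts, total = sum(counts),
                 dropped = as.integer(dropped)),
            class = "pair_counts")
}

pair_freqs_from_counts <- function(pc, mode, label) {
  if (pc$total == 0L) stop("no usable dicodons (total is 0)")
  structure(list(freqs = pc$counts / pc$total,
                 support_total = pc$total,
                 dropped = pc$dropped,
                 mode = mode, label = label),
            class = "pair_freqs")
}

#' Pair frequencies of a single protein of interest
#'
#' @param p A `coding_sequence` with at least two codons.
#' @param assignment A `codon_assignment`.
#' @return Object of class `pair_freqs`: `freqs` (named frequency vector
#'   summing to 1 over observed pairs; absent pairs have frequency 0),
#'   `support_total` (dicodon denominator), `dropped`, `mode`, `label`.
#' @export
poi_frequencies <- function(p, assignment) {
  stopifnot(inherits(p, "coding_sequence"))
  if (length(p$codons) < 2L) stop("POI too short for dicodon analysis")
  pc <- aggregate_pair_counts(count_dicodons(p), assignment)
  pair_freqs_from_counts(pc, mode = "single", label = p$id)
}

#' Background pair frequencies of a pooled transcriptome
#'
#' Under the simplifying assumption of uniform transcript and translation
#' levels, the background frequency of a tRNA pair is estimated from the
#' dicodons of all coding sequences. Two readings of "average frequency" are
#' supported: `"pooled"` (default) pools dicodon counts over all records and
#' normalizes once; `"mean"` averages per-record frequency vectors with equal
#' weight per transcript. The mode is stamped into the result and every
#' export.
#'
#' @param t A `transcriptome`.
#' @param assignment A `codon_assignment`.
#' @param mode `"pooled"` or `"mean"`.
#' @return A `pair_freqs` object.
#' @export
pooled_background_frequencies <- function(t, assignment,
                                          mode = c("pooled", "mean")) {
  stopifnot(inherits(t, "transcriptome"))
  mode <- match.arg(mode)
  if (mode == "pooled") {
    pc <- aggregate_pair_counts(count_dicodons(t), assignment)
    if (pc$total == 0L) stop("transcriptome has no usable dicodons")
    return(pair_freqs_from_counts(pc, mode = "pooled", label = t$label))
  }
  per <- lapply(t$records, function(r) {
    pc <- aggregate_pair_counts(count_dicodons(r), assignment)
    if (pc$total == 0L) return(NULL)
    pc$counts / pc$total
  })
  dropped <- sum(vapply(t$records, function(r) {
    pc <- aggregate_pair_counts(count_dicodons(r), assignment)
    pc$dropped
  }, integer(1)))
  per <- Filter(Negate(is.null), per)
  if (length(per) == 0L) stop("transcriptome has no usable dicodons")
  keys <- sort(unique(unlist(lapply(per, names))))
  acc <- stats::setNames(numeric(length(keys)), keys)
  for (f in per) acc[names(f)] <- acc[names(f)] + f
  freqs <- acc / length(per)
  structure(list(freqs = freqs,
                 support_total = length(per),
                 dropped = dropped,
                 mode = "mean", label = t$label),
            class = "pair_freqs")
}

# Frequency lookup tolerant of absent pairs (absent == exactly 0).
freq_of <- function(pf, pair_ids) {
  out <- pf$freqs[pair_ids]
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), pair_ids)
}

#' Export pair frequencies as TSV
#'
#' Writes `pair_id<TAB>count<TAB>frequency` with metadata comment lines
#' (`# mode=`, `# dropped=`, `# support_total=`).
#'
#' @param pf A `pair_freqs` object.
#' @param file Output path.
#' @export
write_pair_frequencies <- function(pf, file) {
  stopifnot(inherits(pf, "pair_freqs"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", pf$label),
               sprintf("# mode=%s", pf$mode),
               sprintf("# support_total=%d", pf$support_total),
               sprintf("# dropped=%d", pf$dropped),
               "pair_id\tcount\tfrequency"), con)
  counts <- if (pf$mode == "mean") rep(NA_integer_, length(pf$freqs))
            else round(pf$freqs * pf$support_total)
  writeLines(sprintf("%s\t%s\t%s", names(pf$freqs),
                     ifelse(is.na(counts), "", as.character(counts)),
                     formatC(pf$freqs, digits = 6, format = "g")), con)
  invisible(file)
}

#' @export
print.pair_freqs <- function(x, ...) {
  cat(sprintf("Pair frequencies '%s' (mode=%s): %d pairs observed, support=%d, dropped=%d\n",
              x$label, x$mode, length(x$freqs), x$support_total, x$dropped))
  top <- utils::head(sort(x$freqs, decreasing = TRUE), 5L)
  for (i in seq_along(top))
    cat(sprintf("  %-28s %.5f\n", names(top)[i], top[i]))
  invisible(x)
}
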